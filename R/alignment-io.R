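#' Parse a structured sequence header into taxon, gene and strain identity
#'
#' Headers follow the convention `>[Taxon ID]<delim>[Target gene ID]<delim>[Strain ID]`
#' or the two-field form `>[Taxon ID]<delim>[Strain ID]`. Strains sharing a
#' taxon ID belong to the same group; everything else about the header text is
#' free-form. The default delimiter is the em-dash, as used in that
#' convention; real-world headers vary, so the delimiter is configurable. No
#' automatic fallback to a plain hyphen is attempted: silently mis-splitting
#' an accession that contains hyphens would be worse than an explicit error.
#'
#' @param header Character vector of header lines; a leading `>` is optional.
#' @param delimiter Single string used to split the header (default em-dash
#'   `"—"`).
#' @return A tibble with one row per header and columns `taxon_id`, `gene_id`
#'   (`NA` for two-field headers), `strain_id`, `raw_header`.
#' @examples
#' parse_header(">Dickeya_solani—hisC—IPO2222")
#' parse_header(">PVY_N—Oz")
#' @export
parse_header <- function(header, delimiter = "—") {
  stopifnot(is.character(header), length(header) >= 1)
  if (!is.character(delimiter) || length(delimiter) != 1 || nchar(delimiter) == 0) {
    tm_abort("`delimiter` must be a non-empty string", "parameter")
  }
  raw <- header
  stripped <- sub("^>", "", trimws(header))
  parts <- strsplit(stripped, delimiter, fixed = TRUE)
  purrr::map2(parts, raw, function(p, h) {
    p <- trimws(p)
    if (length(p) < 2 || length(p) > 3 || any(!nzchar(p))) {
      tm_abort(sprintf(
        "malformed header '%s': expected 2 or 3 fields separated by '%s', got %d",
        h, delimiter, sum(nzchar(p))), "malformed_header")
    }
    if (length(p) == 2) p <- c(p[1], NA_character_, p[2])
    p
  }) -> fields
  tibble::tibble(
    taxon_id = purrr::map_chr(fields, 1),
    gene_id = purrr::map_chr(fields, 2),
    strain_id = purrr::map_chr(fields, 3),
    raw_header = sub("^>", "", trimws(raw))
  )
}

#' Construct a grouped alignment from a records table
#'
#' The central container: an ordered set of aligned sequences partitioned into
#' taxon groups by their `taxon_id`. Record order follows the input; group
#' order follows first appearance (the order in which taxa first occur among
#' the records). Sequences are uppercased and `U` is transliterated to `T`.
#'
#' @param records A data frame with columns `taxon_id`, `strain_id`,
#'   `sequence`, and optionally `gene_id` and `raw_header`.
#' @return An object of class `grouped_alignment`: a list with `records`
#'   (tibble), `n_columns`, and `groups` (named list of record indices, one
#'   element per taxon in order of first appearance).
#' @export
grouped_alignment <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("taxon_id", "strain_id", "sequence")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    tm_abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")),
             "parameter")
  }
  if (!"gene_id" %in% names(records)) records$gene_id <- NA_character_
  if (!"raw_header" %in% names(records)) {
    records$raw_header <- ifelse(
      is.na(records$gene_id),
      paste(records$taxon_id, records$strain_id, sep = "—"),
      paste(records$taxon_id, records$gene_id, records$strain_id, sep = "—"))
  }
  if (any(!nzchar(records$taxon_id)) || any(!nzchar(records$strain_id))) {
    tm_abort("taxon_id and strain_id must be non-empty", "malformed_header")
  }

  seqs <- toupper(records$sequence)
  if (any(grepl("U", seqs, fixed = TRUE))) {
    tm_log("info", "transliterating RNA 'U' to 'T' on ingest")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  lens <- nchar(seqs)
  if (any(lens == 0)) tm_abort("empty sequence in records", "alignment_shape")
  if (length(unique(lens)) != 1) {
    tm_abort(sprintf(
      "ragged alignment: sequence lengths differ (%s)",
      paste(unique(lens), collapse = ", ")), "alignment_shape")
  }
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), ALLOWED_CHARS)
  if (length(bad)) {
    tm_abort(paste0("alignment contains characters outside the nucleotide ",
                    "alphabet: ", paste(sQuote(bad), collapse = ", ")),
             "alphabet")
  }
  records$sequence <- seqs

  taxa <- unique(records$taxon_id)
  if (length(taxa) < 2) {
    tm_abort(paste0("alignment defines a single taxon group ('", taxa,
                    "'); at least two groups are required to call ",
                    "taxon-specific mutations"), "insufficient_groups")
  }
  groups <- lapply(taxa, function(t) which(records$taxon_id == t))
  names(groups) <- taxa

  structure(list(records = records, n_columns = lens[[1]], groups = groups),
            class = "grouped_alignment")
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat(sprintf("<grouped_alignment> %d records, %d columns, %d groups\n",
              nrow(x$records), x$n_columns, length(x$groups)))
  sizes <- lengths(x$groups)
  cat(paste0("  ", names(sizes), ": ", sizes, " strain(s)", collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as_tibble.grouped_alignment <- function(x, ...) x$records

#' Group sizes and member indices of a grouped alignment
#' @param aln A `grouped_alignment`.
#' @return Named list of integer record indices, in group order.
#' @export
taxon_groups <- function(aln) {
  stopifnot(inherits(aln, "grouped_alignment"))
  aln$groups
}

# Parse Clustal text (both dialects) into (name, sequence) pairs.
# Dialect 1: plain Clustal/Clustal Omega.  Dialect 2: ClustalW "with
# nucleotide counts", where each sequence line ends in a cumulative residue
# count; trailing all-digit tokens are stripped.
parse_clustal_lines <- function(lines) {
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[[1]], ignore.case = TRUE)) {
    tm_abort("not a Clustal file: missing CLUSTAL header line", "format")
  }
  body <- lines[-1]
  seqs <- list()
  order_names <- character()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation line
    tokens <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tokens) < 2) next
    # strip trailing cumulative-count tokens (counts dialect)
    while (length(tokens) > 2 && grepl("^[0-9]+$", tokens[[length(tokens)]])) {
      tokens <- tokens[-length(tokens)]
    }
    if (length(tokens) == 3 && grepl("^[0-9]+$", tokens[[3]])) tokens <- tokens[1:2]
    name <- tokens[[1]]
    chunk <- paste(tokens[-1], collapse = "")
    if (!name %in% order_names) {
      order_names <- c(order_names, name)
      seqs[[name]] <- chunk
    } else {
      seqs[[name]] <- paste0(seqs[[name]], chunk)
    }
  }
  if (!length(order_names)) tm_abort("Clustal file contains no sequences", "format")
  list(names = order_names, sequences = unlist(seqs[order_names], use.names = FALSE))
}

#' Read a multiple sequence alignment with grouped headers
#'
#' Accepts Clustal (plain, or the ClustalW dialect that appends cumulative
#' residue counts to each sequence line) and aligned multi-FASTA. Headers are
#' parsed with [parse_header()] to assign each strain to its taxon group.
#'
#' @param input Path to an alignment file, or the alignment text itself (a
#'   string containing newlines, or a character vector of lines).
#' @param format `"auto"` (sniffed from the first line), `"clustal"` or
#'   `"fasta"`.
#' @param delimiter Header field delimiter passed to [parse_header()].
#' @return A [grouped_alignment()].
#' @export
read_alignment <- function(input, format = c("auto", "clustal", "fasta"),
                           delimiter = "—") {
  format <- match.arg(format)
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(input, collapse = "\n"), "\r?\n"))
  }
  lines <- sub("\r$", "", lines)
  first <- lines[nzchar(trimws(lines))][1]
  if (is.na(first)) tm_abort("empty alignment input", "format")
  if (format == "auto") {
    format <- if (grepl("^>", first)) "fasta"
              else if (grepl("^(CLUSTAL|MUSCLE)", first, ignore.case = TRUE)) "clustal"
              else tm_abort("cannot determine alignment format from input", "format")
  }

  if (format == "clustal") {
    parsed <- parse_clustal_lines(lines)
    headers <- parsed$names
    sequences <- parsed$sequences
  } else {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(lines, tf)
    set <- Biostrings::readBStringSet(tf)
    if (!length(set)) tm_abort("FASTA input contains no sequences", "format")
    headers <- names(set)
    sequences <- as.character(set)
  }

  meta <- parse_header(headers, delimiter = delimiter)
  meta$sequence <- unname(sequences)
  grouped_alignment(meta)
}

#' Write a grouped alignment to FASTA or Clustal
#'
#' The Clustal writer can reproduce either dialect: plain, or with trailing
#' cumulative residue counts (`counts = TRUE`), which is also the dialect the
#' reader must accept. Used by the fixture generator to exercise all input
#' paths.
#'
#' @param aln A `grouped_alignment`.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @param counts For Clustal output, append cumulative residue counts.
#' @param line_endings `"unix"` (LF) or `"windows"` (CRLF).
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal"),
                            counts = FALSE, line_endings = "unix") {
  stopifnot(inherits(aln, "grouped_alignment"))
  format <- match.arg(format)
  rec <- aln$records
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", rec$raw_header), rec$sequence))
    return(invisible(write_text(lines, path, line_endings)))
  }
  width <- 60L
  name_field <- formatC(rec$raw_header, width = max(nchar(rec$raw_header)) + 3,
                        flag = "-")
  starts <- seq(1L, aln$n_columns, by = width)
  lines <- c("CLUSTAL multiple sequence alignment", "")
  for (s in starts) {
    e <- min(s + width - 1L, aln$n_columns)
    chunk <- substr(rec$sequence, s, e)
    block <- paste0(name_field, chunk)
    if (counts) {
      # cumulative residue count = non-gap characters emitted so far
      cum <- vapply(seq_len(nrow(rec)), function(i) {
        sum(strsplit(substr(rec$sequence[i], 1, e), "")[[1]] != GAP_CHAR)
      }, integer(1))
      block <- paste0(block, " ", cum)
    }
    lines <- c(lines, block, "")
  }
  invisible(write_text(lines, path, line_endings))
}

#' Write the processed alignment with highlighted taxon-specific mutations
#'
#' Emits a Clustal-style block layout. Beneath each 60-column sequence block,
#' one annotation line per taxon group marks that group's taxon-specific
#' columns with `*`, followed by a count line giving the number of that
#' group's taxon-specific mutations in each `fragment_len`-column fragment
#' overlapping the block. Coordinates in the file header are 1-based
#' inclusive.
#'
#' @param aln A `grouped_alignment`.
#' @param verdicts Column classification from [classify_alignment()].
#' @param path Output file path.
#' @param fragment_len Fragment width for the per-block counts (default 20).
#' @param line_endings `"unix"` or `"windows"`.
#' @return The path, invisibly.
#' @export
write_processed_alignment <- function(aln, verdicts, path, fragment_len = 20,
                                      line_endings = "unix") {
  stopifnot(inherits(aln, "grouped_alignment"))
  if (nrow(verdicts) != aln$n_columns) {
    tm_abort("verdict table length does not match alignment columns",
             "alignment_shape")
  }
  spec <- specific_matrix(verdicts)
  rec <- aln$records
  group_names <- names(aln$groups)
  labels <- c(rec$raw_header, paste0(group_names, " [specific]"),
              paste0(group_names, sprintf(" [count/%dnt]", fragment_len)))
  pad <- max(nchar(labels)) + 3L
  field <- function(x) formatC(x, width = pad, flag = "-")

  width <- 60L
  starts <- seq(1L, aln$n_columns, by = width)
  lines <- c("Processed alignment: taxon-specific mutations per group",
             "Coordinates: 1-based inclusive alignment columns",
             sprintf("Fragment length: %d columns", fragment_len), "")
  frag_of <- function(col) (col - 1L) %/% fragment_len + 1L
  for (s in starts) {
    e <- min(s + width - 1L, aln$n_columns)
    lines <- c(lines, sprintf("Columns %d-%d", s, e))
    lines <- c(lines, paste0(field(rec$raw_header), substr(rec$sequence, s, e)))
    cols <- s:e
    frags <- unique(frag_of(cols))
    for (g in group_names) {
      marks <- ifelse(spec[g, cols], "*", ".")
      lines <- c(lines, paste0(field(paste0(g, " [specific]")),
                               paste(marks, collapse = "")))
      cnt <- vapply(frags, function(f) {
        fc <- intersect(((f - 1L) * fragment_len + 1L):(f * fragment_len), cols)
        sum(spec[g, fc])
      }, integer(1))
      lines <- c(lines, paste0(
        field(paste0(g, sprintf(" [count/%dnt]", fragment_len))),
        paste(cnt, collapse = " ")))
    }
    lines <- c(lines, "")
  }
  invisible(write_text(lines, path, line_endings))
}
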