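#' Majority consensus of the focal group over a region, with coordinate map
#'
#' For each alignment column in the region, takes the focal group's majority
#' unambiguous base (ties broken alphabetically A<C<G<T and logged). Columns
#' whose focal majority is the gap character are dropped — they do not exist
#' on the ungapped target — and columns where the focal group offers no
#' unambiguous base at all (ambiguity codes with a gap minority) are dropped
#' with a warning, never silently substituted. The consensus represents the
#' taxon deterministically, unlike exporting an arbitrary first strain.
#'
#' @param aln A `grouped_alignment`.
#' @param group Focal taxon ID.
#' @param region Integer vector `c(start, end)` (1-based inclusive alignment
#'   columns) or a one-row region tibble from [select_target_region()].
#' @return Tibble with `target_pos` (1-based position on the ungapped
#'   consensus), `column` (source alignment column), `base`.
#' @export
build_focal_consensus <- function(aln, group, region) {
  stopifnot(inherits(aln, "grouped_alignment"))
  if (is.data.frame(region)) region <- c(region$start[1], region$end[1])
  region <- as.integer(region)
  if (length(region) != 2 || region[1] < 1 || region[2] > aln$n_columns ||
      region[1] > region[2]) {
    tm_abort(sprintf("region [%s] outside alignment bounds 1-%d",
                     paste(region, collapse = ", "), aln$n_columns),
             "parameter")
  }
  if (!group %in% names(aln$groups)) {
    tm_abort(sprintf("unknown group '%s'", group), "unknown_group")
  }
  rows <- aln$groups[[group]]
  X <- do.call(rbind, strsplit(substr(aln$records$sequence[rows],
                                      region[1], region[2]), "", fixed = TRUE))
  cols <- region[1]:region[2]
  base_counts <- vapply(DNA_BASES,
                        function(b) colSums(X == b, na.rm = TRUE),
                        numeric(ncol(X)))
  base_counts <- matrix(base_counts, ncol = 4, dimnames = list(NULL, DNA_BASES))
  gap_counts <- colSums(X == GAP_CHAR)
  amb_codes <- setdiff(ALLOWED_CHARS, c(DNA_BASES, GAP_CHAR))
  amb_max <- Reduce(pmax, lapply(amb_codes, function(a) colSums(X == a)),
                    accumulate = FALSE)
  best_idx <- apply(base_counts, 1, which.max)  # alphabetical tie-break
  best_n <- base_counts[cbind(seq_along(cols), best_idx)]
  tied <- rowSums(base_counts == best_n) > 1 & best_n > 0
  if (any(tied)) {
    tm_log("info", sprintf(
      "consensus tie at column(s) %s for group '%s'; alphabetical tie-break applied",
      paste(cols[tied], collapse = ", "), group))
  }
  no_base <- best_n == 0
  # gap is dropped silently only when it is the strict plurality character;
  # a baseless column that is not gap-dominated is dropped with a warning
  gap_major <- gap_counts > best_n & gap_counts > amb_max
  if (any(no_base & !gap_major)) {
    warning(sprintf(
      "group '%s' offers no unambiguous base at column(s) %s; dropped from the target",
      group, paste(cols[no_base & !gap_major], collapse = ", ")),
      call. = FALSE)
  }
  if (any(gap_major)) {
    tm_log("info", sprintf(
      "%d gap-majority column(s) dropped from the ungapped '%s' target",
      sum(gap_major), group))
  }
  keep <- !no_base & !gap_major
  tibble::tibble(
    target_pos = seq_len(sum(keep)),
    column = cols[keep],
    base = DNA_BASES[best_idx[keep]]
  )
}

#' Build (and optionally write) the masked target for specific primer design
#'
#' Produces the ungapped focal-group consensus over the region together with
#' a parallel annotation string: `*` under conserved-common columns, `-`
#' under the focal group's taxon-specific columns, spaces elsewhere — the
#' symbol convention of the downstream primer-design service's region
#' selection format. Taxon-specific columns whose signature is a conserved
#' deletion have no position on the ungapped target; they contribute to
#' counts and plots but are necessarily absent from the mask (logged).
#'
#' The file layout is: a header line naming the group and region (1-based
#' inclusive alignment columns), then the sequence wrapped at 60 characters,
#' each sequence line followed immediately by its annotation line, vertically
#' aligned character-for-character.
#'
#' @param aln A `grouped_alignment`.
#' @param verdicts Column classification from [classify_alignment()].
#' @param group Focal taxon ID.
#' @param region `c(start, end)` or a one-row tibble from
#'   [select_target_region()].
#' @param path Optional output file path; if `NULL` nothing is written.
#' @param line_endings `"unix"` or `"windows"`.
#' @param wrap Characters per sequence line (default 60).
#' @return A `masked_target`: list with `group`, `region` (length-2 integer),
#'   `sequence`, `annotation`, `map` (the consensus tibble).
#' @export
make_primerexplorer_input <- function(aln, verdicts, group, region,
                                      path = NULL, line_endings = "unix",
                                      wrap = 60) {
  cons <- build_focal_consensus(aln, group, region)
  if (is.data.frame(region)) region <- c(region$start[1], region$end[1])
  region <- as.integer(region)
  if (nrow(cons) > 2000) {
    tm_abort(sprintf(
      paste0("ungapped target is %d nt, above the 2000 nt primer-design input ",
             "limit; narrow the region (currently columns %d-%d)"),
      nrow(cons), region[1], region[2]), "size")
  }
  spec <- specific_matrix(verdicts)
  spec_cols <- which(spec[group, ])
  dropped_gap_sig <- setdiff(intersect(spec_cols, region[1]:region[2]),
                             cons$column)
  if (length(dropped_gap_sig)) {
    tm_log("info", sprintf(
      "%d taxon-specific column(s) for '%s' are conserved deletions; reported in the profile but absent from the ungapped mask",
      length(dropped_gap_sig), group))
  }
  ann <- rep(" ", nrow(cons))
  ann[cons$column %in% spec_cols] <- "-"
  ann[verdicts$conserved_common[cons$column]] <- "*"

  target <- structure(list(
    group = group, region = region,
    sequence = paste(cons$base, collapse = ""),
    annotation = paste(ann, collapse = ""),
    map = cons
  ), class = "masked_target")

  if (!is.null(path)) {
    header <- sprintf(
      ">%s | alignment columns %d-%d (1-based inclusive) | ungapped length %d",
      group, region[1], region[2], nrow(cons))
    starts <- seq(1L, max(nrow(cons), 1L), by = wrap)
    lines <- header
    for (s in starts) {
      e <- min(s + wrap - 1L, nrow(cons))
      lines <- c(lines, substr(target$sequence, s, e),
                 substr(target$annotation, s, e))
    }
    write_text(lines, path, line_endings)
  }
  target
}

#' @export
print.masked_target <- function(x, ...) {
  cat(sprintf("<masked_target> group '%s', columns %d-%d, %d nt (%d '-' marks, %d '*' positions)\n",
              x$group, x$region[1], x$region[2], nchar(x$sequence),
              stringr::str_count(x$annotation, stringr::fixed("-")),
              stringr::str_count(x$annotation, stringr::fixed("*"))))
  invisible(x)
}

#' Read a masked target file back
#'
#' Inverse of the file written by [make_primerexplorer_input()]; used for
#' round-trip verification.
#'
#' @param path File path.
#' @return A list with `group`, `region`, `sequence`, `annotation`.
#' @export
read_masked_target <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  header <- lines[[1]]
  m <- regmatches(header,
                  regexec("^>(.+?) \\| alignment columns (\\d+)-(\\d+)", header))[[1]]
  if (length(m) != 4) tm_abort("not a masked target file", "format")
  body <- lines[-1]
  seq_lines <- body[seq(1, length(body), by = 2)]
  ann_lines <- body[seq(2, length(body), by = 2)]
  list(group = m[[2]],
       region = as.integer(m[3:4]),
       sequence = paste(seq_lines, collapse = ""),
       annotation = paste(ann_lines, collapse = ""))
}

#' Bundle run outputs into a project directory or ZIP archive
#'
#' Collects output files under `out_dir/project_id`; refuses to clobber an
#' existing project directory unless `overwrite = TRUE`. With `zip = TRUE`
#' the directory is additionally packed into `project_id.zip` (standard
#' deflate) next to it.
#'
#' @param files Character vector of existing file paths to bundle.
#' @param out_dir Parent output directory (created if needed).
#' @param project_id Name of the bundle.
#' @param zip Also produce a ZIP archive.
#' @param overwrite Allow replacing an existing project directory/archive.
#' @return Path of the project directory (attribute `zip` holds the archive
#'   path if one was written).
#' @export
bundle_outputs <- function(files, out_dir, project_id, zip = FALSE,
                           overwrite = FALSE) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    tm_abort(paste0("missing output file(s): ", paste(missing, collapse = ", ")),
             "write")
  }
  dest <- file.path(out_dir, project_id)
  if (file.exists(dest) && !overwrite) {
    tm_abort(sprintf(
      "project '%s' already exists under '%s'; use overwrite to replace it",
      project_id, out_dir), "collision")
  }
  if (file.exists(dest)) unlink(dest, recursive = TRUE)
  dir.create(dest, recursive = TRUE)
  ok <- file.copy(files, dest)
  if (!all(ok)) tm_abort("failed to copy outputs into the project directory", "write")
  if (zip) {
    zip_path <- file.path(out_dir, paste0(project_id, ".zip"))
    if (file.exists(zip_path) && !overwrite) {
      tm_abort(sprintf("archive '%s' already exists", zip_path), "collision")
    }
    write_zip_archive(zip_path, dir = dest, root = project_id)
    attr(dest, "zip") <- zip_path
  }
  dest
}
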