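# Independent brute-force oracles, written as naive per-column loops so they
# share no code path with the package internals.

oracle_iupac <- list(
  A = c("A", "R", "W", "M", "D", "H", "V", "N"),
  C = c("C", "Y", "S", "M", "B", "H", "V", "N"),
  G = c("G", "R", "S", "K", "B", "D", "V", "N"),
  T = c("T", "Y", "W", "K", "B", "D", "H", "N")
)

# Specific groups for one column of characters, given a named list of record
# indices. Returns a character vector of group names.
oracle_specific <- function(chars, groups) {
  out <- character()
  for (g in names(groups)) {
    mem <- chars[groups[[g]]]
    rest <- chars[-groups[[g]]]
    if (length(unique(mem)) != 1) next           # strain polymorphism
    c0 <- mem[[1]]
    if (c0 %in% c("A", "C", "G", "T")) {
      clash <- FALSE
      for (r in rest) if (r %in% oracle_iupac[[c0]]) clash <- TRUE
      if (!clash) out <- c(out, g)
    } else if (c0 == "-") {
      if (all(rest %in% c("A", "C", "G", "T"))) out <- c(out, g)
    }
  }
  out
}

oracle_conserved <- function(chars) {
  length(unique(chars)) == 1 && chars[[1]] %in% c("A", "C", "G", "T")
}

# Long (taxon_id, column) table of specific calls for a whole alignment.
oracle_specific_table <- function(aln) {
  X <- do.call(rbind, strsplit(aln$records$sequence, ""))
  rows <- list()
  for (j in seq_len(ncol(X))) {
    for (g in oracle_specific(X[, j], aln$groups)) {
      rows[[length(rows) + 1]] <- data.frame(taxon_id = g, column = j)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(taxon_id = character(), column = integer()))
  }
  out <- dplyr::bind_rows(rows)
  tibble::as_tibble(out[order(out$taxon_id, out$column), ])
}

# Build a small alignment directly from per-record sequences.
make_aln <- function(taxa, seqs, strains = NULL) {
  strains <- strains %||% paste0("s", seq_along(seqs))
  taxamark::grouped_alignment(tibble::tibble(
    taxon_id = taxa, strain_id = strains, sequence = seqs))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_same_calls <- function(verdicts, truth) {
  got <- dplyr::arrange(specific_columns(verdicts), taxon_id, column)
  want <- dplyr::arrange(dplyr::distinct(truth[, c("taxon_id", "column")]),
                         taxon_id, column)
  expect_equal(got$taxon_id, want$taxon_id)
  expect_equal(got$column, want$column)
}
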