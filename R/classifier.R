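#' Classify every alignment column per taxon group
#'
#' A column is *conserved-common* when every record carries the same single
#' unambiguous base (no gaps, no ambiguity codes) — the Clustal `*`
#' convention. A column is *taxon-specific* for group G when all members of G
#' carry the same character `c`, `c` is an unambiguous base or the gap
#' character, and `c` occurs in no record outside G; a gap signature
#' additionally requires every non-G record to carry an unambiguous base, so
#' the conserved deletion itself is the group's mark. Columns where G is
#' internally polymorphic are never specific for G — that is the exclusion of
#' strain-specific polymorphisms. Ambiguity codes are disqualifying within G,
#' and an outgroup ambiguity code that could stand for the signature base
#' (by IUPAC expansion) also disqualifies the column, conservatively: a
#' primer 3'-end mismatch is only guaranteed when the signature is absent
#' from every off-target record.
#'
#' @param aln A [grouped_alignment()].
#' @return A tibble of class `column_verdicts` with one row per column:
#'   `column` (1-based), `conserved_common` (logical), `specific_for`
#'   (list-column of taxon IDs). Carries the group-by-column specificity
#'   matrix as an attribute for fast downstream counting.
#' @export
classify_alignment <- function(aln) {
  stopifnot(inherits(aln, "grouped_alignment"))
  X <- do.call(rbind, strsplit(aln$records$sequence, "", fixed = TRUE))
  classify_matrix(X, aln$groups)
}

#' Classify a single alignment column
#'
#' @param column Character vector, one character per record, in record order.
#' @param groups Named list of record indices (as from [taxon_groups()]).
#' @return One-row `column_verdicts` tibble.
#' @export
classify_column <- function(column, groups) {
  n <- sum(lengths(groups))
  if (length(column) != n) {
    tm_abort(sprintf("column has %d characters but the grouping covers %d records",
                     length(column), n), "alignment_shape")
  }
  classify_matrix(matrix(toupper(column), ncol = 1), groups)
}

# Vectorised core over a records-by-columns character matrix.
classify_matrix <- function(X, groups) {
  n_rec <- nrow(X)
  n_col <- ncol(X)
  group_names <- names(groups)

  is_base <- matrix(X %in% DNA_BASES, n_rec, n_col)
  # contains[[b]][i, j]: record i at column j could be base b under IUPAC
  contains <- lapply(DNA_BASES, function(b) {
    matrix(X %in% IUPAC_CONTAINS[[b]], n_rec, n_col)
  })
  names(contains) <- DNA_BASES
  tot_contains <- lapply(contains, colSums)
  tot_base <- colSums(is_base)

  spec <- matrix(FALSE, length(groups), n_col,
                 dimnames = list(group_names, NULL))
  for (g in group_names) {
    rows <- groups[[g]]
    sub <- X[rows, , drop = FALSE]
    first <- sub[1, ]
    mono <- colSums(sub == matrix(first, length(rows), n_col, byrow = TRUE)) ==
      length(rows)
    sig_ok <- first %in% c(DNA_BASES, GAP_CHAR)
    # exclusion: signature base absent (even as ambiguity) outside the group
    out_has_sig <- rep(TRUE, n_col)
    for (b in DNA_BASES) {
      idx <- which(first == b)
      if (length(idx)) {
        out_has_sig[idx] <- (tot_contains[[b]][idx] -
                               colSums(contains[[b]][rows, idx, drop = FALSE])) > 0
      }
    }
    idx <- which(first == GAP_CHAR)
    if (length(idx)) {
      # gap signature: every outgroup record must carry an unambiguous base
      out_all_base <- (tot_base[idx] -
                         colSums(is_base[rows, idx, drop = FALSE])) ==
        (n_rec - length(rows))
      out_has_sig[idx] <- !out_all_base
    }
    spec[g, ] <- mono & sig_ok & !out_has_sig
  }

  first_all <- X[1, ]
  conserved <- (colSums(X == matrix(first_all, n_rec, n_col, byrow = TRUE)) ==
                  n_rec) & first_all %in% DNA_BASES

  out <- tibble::tibble(
    column = seq_len(n_col),
    conserved_common = conserved,
    specific_for = lapply(seq_len(n_col), function(j) group_names[spec[, j]])
  )
  attr(out, "specific_matrix") <- spec
  attr(out, "group_names") <- group_names
  class(out) <- c("column_verdicts", class(out))
  out
}

# Recover the group-by-column logical matrix from a verdict tibble, falling
# back to the list-column if the attribute was dropped by subsetting.
specific_matrix <- function(verdicts) {
  m <- attr(verdicts, "specific_matrix")
  if (!is.null(m) && ncol(m) == nrow(verdicts)) return(m)
  group_names <- attr(verdicts, "group_names") %||%
    sort(unique(unlist(verdicts$specific_for)))
  m <- matrix(FALSE, length(group_names), nrow(verdicts),
              dimnames = list(group_names, NULL))
  for (j in seq_len(nrow(verdicts))) {
    m[verdicts$specific_for[[j]], j] <- TRUE
  }
  m
}

#' Columns called taxon-specific, in long form
#'
#' @param verdicts A `column_verdicts` tibble.
#' @return Tibble with columns `taxon_id`, `column`, one row per
#'   (group, specific column) pair.
#' @export
specific_columns <- function(verdicts) {
  spec <- specific_matrix(verdicts)
  idx <- which(spec, arr.ind = TRUE)
  tibble::tibble(taxon_id = rownames(spec)[idx[, 1]],
                 column = as.integer(idx[, 2])) |>
    dplyr::arrange(.data$taxon_id, .data$column)
}

#' Count taxon-specific mutations per fragment
#'
#' Tiles the alignment into consecutive non-overlapping fragments of
#' `fragment_len` columns (default 20, the length of a primer annealing site)
#' and counts, per fragment, the columns specific for `group`. A trailing
#' fragment shorter than `fragment_len` is counted but flagged `partial`.
#'
#' @param verdicts A `column_verdicts` tibble covering the whole alignment.
#' @param group Taxon ID to count for.
#' @param fragment_len Fragment width in columns (>= 1).
#' @return Tibble with `fragment` (1-based index), `start`, `end` (1-based
#'   inclusive columns), `n_cols`, `partial`, `m` (mutation count).
#' @export
count_fragment_mutations <- function(verdicts, group, fragment_len = 20) {
  if (!is.numeric(fragment_len) || fragment_len < 1) {
    tm_abort("`fragment_len` must be a positive integer", "parameter")
  }
  fragment_len <- as.integer(fragment_len)
  spec <- specific_matrix(verdicts)
  if (!group %in% rownames(spec)) {
    tm_abort(sprintf("unknown group '%s'; alignment groups are: %s", group,
                     paste(rownames(spec), collapse = ", ")), "unknown_group")
  }
  n_col <- ncol(spec)
  n_frag <- as.integer(ceiling(n_col / fragment_len))
  frag_of <- (seq_len(n_col) - 1L) %/% fragment_len + 1L
  m <- vapply(seq_len(n_frag), function(f) sum(spec[group, frag_of == f]),
              integer(1))
  start <- (seq_len(n_frag) - 1L) * fragment_len + 1L
  end <- pmin(start + fragment_len - 1L, n_col)
  tibble::tibble(
    fragment = seq_len(n_frag),
    start = start, end = end,
    n_cols = end - start + 1L,
    partial = (end - start + 1L) < fragment_len,
    m = m
  )
}
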