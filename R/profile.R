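#' Simple moving average of fragment mutation counts (direct form)
#'
#' The average mutation index for a window of `w` fragments is
#' \deqn{\bar S_f = \frac{1}{w}\sum_{i=0}^{w-1} M_{f-i}}
#' i.e. the mean of `w` consecutive per-fragment mutation counts. Each value
#' is anchored to the *central* fragment of its window — hence `w` must be
#' odd — not to an abstract alignment locus.
#'
#' @param m Integer vector of per-fragment mutation counts.
#' @param w Odd positive window size in fragments; `w <= length(m)`.
#' @return Numeric vector of length `length(m) - w + 1`; element `j` is the
#'   mean of `m[j..j+w-1]`, anchored to fragment `j + (w-1)/2`.
#' @export
sma_direct <- function(m, w) {
  check_window(m, w)
  n_win <- length(m) - w + 1L
  vapply(seq_len(n_win), function(j) sum(m[j:(j + w - 1L)]) / w, numeric(1))
}

#' Simple moving average via the sliding-window recurrence
#'
#' Computes the first window by direct summation, then each subsequent value
#' as \deqn{\bar S_f = \bar S_{f-1} - M_{f-w}/w + M_f/w,} dropping the
#' fragment that leaves the window and adding the one that enters as the
#' window shifts right by one fragment. Numerically equivalent to
#' [sma_direct()]; O(n) instead of O(nw).
#'
#' @inheritParams sma_direct
#' @return As [sma_direct()].
#' @export
sma_recurrent <- function(m, w) {
  check_window(m, w)
  n_win <- length(m) - w + 1L
  out <- numeric(n_win)
  out[1] <- sum(m[1:w]) / w
  if (n_win > 1) {
    for (j in 2:n_win) {
      out[j] <- out[j - 1] - m[j - 1] / w + m[j + w - 1] / w
    }
  }
  out
}

check_window <- function(m, w) {
  if (!is.numeric(m) || !length(m)) {
    tm_abort("`m` must be a non-empty numeric vector", "parameter")
  }
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w %% 2 != 1) {
    tm_abort("window size `w` must be an odd positive integer", "parameter")
  }
  if (w > length(m)) {
    tm_abort(sprintf("window size %d exceeds the %d available fragments",
                     w, length(m)), "parameter")
  }
  invisible(TRUE)
}

#' Build a sliding-window mutation-density profile for one taxon group
#'
#' Counts taxon-specific mutations per `fragment_len`-column fragment and
#' smooths them with a simple moving average over `window_bp / fragment_len`
#' fragments (defaults 20 nt and 300 bp, i.e. a 15-fragment window — an
#' amplicon-scale window, since LAMP amplicons are most efficient below
#' 300 bp). The window must span an odd number of fragments so each value is
#' anchored to its central fragment. No edge padding: the SMA is undefined
#' (NA) for the first and last `(w-1)/2` full fragments, and a trailing
#' partial fragment is reported in `m` but excluded from the SMA.
#'
#' @param verdicts A `column_verdicts` tibble from [classify_alignment()].
#' @param group Taxon ID to profile.
#' @param fragment_len Fragment width in columns (default 20).
#' @param window_bp Window span in columns; must be divisible by
#'   `fragment_len` with an odd quotient (default 300).
#' @return A `mutation_profile`: the fragment tibble from
#'   [count_fragment_mutations()] plus an `sma` column (NA where undefined),
#'   with attributes `group`, `fragment_len`, `window_fragments`.
#' @export
build_profile <- function(verdicts, group, fragment_len = 20, window_bp = 300) {
  if (window_bp %% fragment_len != 0) {
    tm_abort(sprintf("window_bp (%d) must be divisible by fragment_len (%d)",
                     window_bp, fragment_len), "parameter")
  }
  w <- as.integer(window_bp / fragment_len)
  if (w %% 2 != 1) {
    tm_abort(sprintf(paste0("window_bp/fragment_len = %d fragments; the window ",
                            "must span an odd number of fragments so the SMA ",
                            "anchors to a central fragment"), w), "parameter")
  }
  frags <- count_fragment_mutations(verdicts, group, fragment_len)
  full <- !frags$partial
  n_full <- sum(full)
  if (n_full < w) {
    tm_abort(sprintf(
      paste0("alignment too short for a %d-fragment window: %d full fragments ",
             "available; at least %d columns are required"),
      w, n_full, w * fragment_len), "too_short")
  }
  sma <- rep(NA_real_, nrow(frags))
  vals <- sma_recurrent(frags$m[full], w)
  sma[which(full)[seq_along(vals) + (w - 1L) %/% 2L]] <- vals
  frags$sma <- sma
  structure(frags,
            group = group, fragment_len = fragment_len,
            window_fragments = w,
            n_columns = max(frags$end),
            class = c("mutation_profile", class(frags)))
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("<mutation_profile> group '%s': %d fragments of %d columns, window %d fragments\n",
              attr(x, "group"), nrow(x), attr(x, "fragment_len"),
              attr(x, "window_fragments")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutation profile
#'
#' @param x A `mutation_profile`.
#' @param ... Unused.
#' @return A plain tibble with the group as a column: `group`, `fragment`,
#'   `start`, `end`, `n_cols`, `partial`, `m`, `sma`.
#' @export
tidy.mutation_profile <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(group = attr(x, "group")),
                   tibble::as_tibble(x))
}

#' One-row summary of a mutation profile
#'
#' @param x A `mutation_profile`.
#' @param ... Unused.
#' @return Tibble with `group`, `n_fragments`, `n_windows`, `total_specific`,
#'   `peak_sma`, `peak_fragment` (leftmost on ties).
#' @export
glance.mutation_profile <- function(x, ...) {
  defined <- which(!is.na(x$sma))
  peak <- if (length(defined)) defined[which.max(x$sma[defined])] else NA_integer_
  tibble::tibble(
    group = attr(x, "group"),
    n_fragments = nrow(x),
    n_windows = length(defined),
    total_specific = sum(x$m),
    peak_sma = if (length(defined)) max(x$sma[defined]) else NA_real_,
    peak_fragment = peak
  )
}

#' Export a profile as a tab-separated table
#'
#' Columns: group, fragment index, 1-based inclusive column range, mutation
#' count, SMA (empty when undefined), partial flag.
#'
#' @param profile A `mutation_profile`.
#' @param path Output path.
#' @param line_endings `"unix"` or `"windows"`.
#' @return The path, invisibly.
#' @export
write_profile_table <- function(profile, path, line_endings = "unix") {
  header <- paste("group", "fragment", "start", "end", "m", "sma", "partial",
                  sep = "\t")
  rows <- paste(attr(profile, "group"), profile$fragment, profile$start,
                profile$end, profile$m,
                ifelse(is.na(profile$sma), "",
                       formatC(profile$sma, digits = 10, format = "g")),
                ifelse(profile$partial, "yes", "no"), sep = "\t")
  invisible(write_text(
    c("# sliding-window mutation density profile (columns 1-based inclusive)",
      header, rows), path, line_endings))
}

#' Select the candidate target region around the density peak
#'
#' If no SMA value reaches `threshold` (default 2, the recommended minimum
#' average mutation index for a specific design), no region is returned.
#' Otherwise the region is a window of at most `max_len` alignment columns
#' (default 2000, the downstream primer-design input size limit) centred on
#' the fragment with the maximum SMA — leftmost on ties — and clamped to the
#' alignment bounds.
#'
#' @param profile A `mutation_profile`.
#' @param threshold Minimum average mutation index (default 2).
#' @param max_len Maximum region length in columns (default 2000); must be at
#'   least the window span.
#' @return A tibble with zero rows (no qualifying peak) or one row: `group`,
#'   `start`, `end` (1-based inclusive alignment columns), `peak_sma`,
#'   `peak_fragment`, `peak_start`, `peak_end`.
#' @export
select_target_region <- function(profile, threshold = 2, max_len = 2000) {
  stopifnot(inherits(profile, "mutation_profile"))
  w <- attr(profile, "window_fragments")
  flen <- attr(profile, "fragment_len")
  if (max_len < w * flen) {
    tm_abort(sprintf("max_len (%d) is smaller than the window span (%d columns)",
                     max_len, w * flen), "parameter")
  }
  empty <- tibble::tibble(group = character(), start = integer(),
                          end = integer(), peak_sma = numeric(),
                          peak_fragment = integer(), peak_start = integer(),
                          peak_end = integer())
  defined <- which(!is.na(profile$sma))
  if (!length(defined) || max(profile$sma[defined]) < threshold) return(empty)
  peak <- defined[which.max(profile$sma[defined])]  # which.max: leftmost tie
  n_col <- attr(profile, "n_columns")
  len <- min(as.integer(max_len), n_col)
  center <- (profile$start[peak] + profile$end[peak]) %/% 2L
  start <- center - (len - 1L) %/% 2L
  start <- max(1L, min(start, n_col - len + 1L))
  tibble::tibble(
    group = attr(profile, "group"),
    start = start, end = start + len - 1L,
    peak_sma = profile$sma[peak],
    peak_fragment = profile$fragment[peak],
    peak_start = profile$start[peak],
    peak_end = profile$end[peak]
  )
}
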