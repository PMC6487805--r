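#' Specify a synthetic alignment with planted taxon-specific structure
#'
#' Defines a seeded plan for generating a grouped alignment whose
#' taxon-specific columns are known exactly by construction: a random
#' unambiguous backbone shared by all records, per-group planted signature
#' columns (a base guaranteed absent outside the group), optional conserved
#' deletion blocks, per-strain private noise that creates within-group
#' polymorphisms without ever recreating a signature, and an adversarial
#' `spoiled` mode that deliberately leaks a would-be signature into one
#' outgroup strain so the classifier must reject the column.
#'
#' Planted column sets must be disjoint across groups. Noise is only applied
#' to groups with at least two strains, at columns carrying no planted,
#' deleted or spoiled structure, and at most one strain per group is flipped
#' at any column — so noise columns are always group-polymorphic and the
#' planted truth stays exact rather than statistical.
#'
#' @param n_groups Number of taxon groups (>= 2).
#' @param strains_per_group Integer, recycled to `n_groups`.
#' @param n_columns Alignment length.
#' @param planted_specific Named list (`G1`, `G2`, ...) of 1-based column
#'   vectors to plant as taxon-specific; or a single integer to plant that
#'   many random columns per group.
#' @param strain_noise Per-column probability of a private strain mutation at
#'   eligible columns (default 0).
#' @param gap_blocks Named list of `c(start, end)` ranges planted as
#'   conserved deletions for that group.
#' @param spoiled Named list of column vectors: signature planted in the
#'   group but leaked to one outgroup strain (must never be called specific).
#' @param seed Integer seed; fully determines the output.
#' @return A `plant_plan` object.
#' @export
plant_plan <- function(n_groups, strains_per_group, n_columns,
                       planted_specific = NULL, strain_noise = 0,
                       gap_blocks = NULL, spoiled = NULL, seed = 1L) {
  if (n_groups < 2) tm_abort("a plan needs at least 2 groups", "plan")
  sizes <- rep_len(as.integer(strains_per_group), n_groups)
  if (any(sizes < 1)) tm_abort("every group needs at least 1 strain", "plan")
  group_names <- paste0("G", seq_len(n_groups))

  if (is.numeric(planted_specific) && length(planted_specific) == 1) {
    k <- as.integer(planted_specific)
    if (k * n_groups > n_columns) {
      tm_abort("cannot plant disjoint column sets: too few columns", "plan")
    }
    if (k == 0) {
      planted_specific <- NULL
    } else {
      set.seed(seed)
      pool <- sample.int(n_columns, k * n_groups)
      planted_specific <- split(pool, rep(group_names, each = k))[group_names]
    }
  }
  planted_specific <- planted_specific %||% stats::setNames(
    rep(list(integer()), n_groups), group_names)
  gap_blocks <- gap_blocks %||% list()
  spoiled <- spoiled %||% list()

  for (nm in names(planted_specific)) {
    if (!nm %in% group_names) tm_abort(sprintf("unknown group '%s' in planted_specific", nm), "plan")
  }
  for (nm in names(gap_blocks)) {
    if (!nm %in% group_names) tm_abort(sprintf("unknown group '%s' in gap_blocks", nm), "plan")
  }
  gap_cols <- lapply(gap_blocks, function(r) seq.int(r[1], r[2]))
  all_struct <- c(unname(lapply(planted_specific, as.integer)),
                  unname(gap_cols),
                  unname(lapply(spoiled, as.integer)))
  flat <- unlist(all_struct)
  if (length(flat)) {
    if (any(flat < 1 | flat > n_columns)) {
      tm_abort("planted structure outside alignment columns", "plan")
    }
    if (anyDuplicated(flat)) {
      tm_abort(paste0("planted column sets (including gap blocks and spoiled ",
                      "columns) must be disjoint across groups"), "plan")
    }
  }
  if (strain_noise < 0 || strain_noise >= 1) {
    tm_abort("strain_noise must be in [0, 1)", "plan")
  }
  if (strain_noise > 0 && all(sizes < 2)) {
    tm_abort(paste0("strain_noise requires at least one group with 2+ strains ",
                    "(a private mutation in a singleton group would itself be ",
                    "taxon-specific)"), "plan")
  }
  structure(list(
    n_groups = n_groups, sizes = sizes, group_names = group_names,
    n_columns = as.integer(n_columns),
    planted_specific = lapply(planted_specific, as.integer),
    strain_noise = strain_noise,
    gap_blocks = gap_blocks, spoiled = lapply(spoiled, as.integer),
    seed = as.integer(seed)
  ), class = "plant_plan")
}

#' Generate the alignment and exact ground truth from a plan
#'
#' @param plan A [plant_plan()].
#' @return List with `alignment` (a [grouped_alignment()]) and `truth`, a
#'   tibble of (`taxon_id`, `column`, `kind`) rows enumerating every column
#'   the classifier must call taxon-specific. With exactly two groups a
#'   column planted for one group is, by definition, also specific for the
#'   other (its conserved backbone base occurs nowhere outside it); such
#'   forced reciprocal calls are included with `kind = "reciprocal"`.
#' @export
generate_alignment <- function(plan) {
  stopifnot(inherits(plan, "plant_plan"))
  set.seed(plan$seed)
  n <- sum(plan$sizes)
  backbone <- sample(DNA_BASES, plan$n_columns, replace = TRUE)
  X <- matrix(rep(backbone, each = n), nrow = n)
  group_rows <- split(seq_len(n), rep(seq_len(plan$n_groups), plan$sizes))
  names(group_rows) <- plan$group_names

  truth <- list()
  add_truth <- function(g, cols, kind) {
    if (length(cols)) {
      truth[[length(truth) + 1]] <<- tibble::tibble(
        taxon_id = g, column = as.integer(cols), kind = kind)
    }
  }

  for (g in names(plan$planted_specific)) {
    for (j in plan$planted_specific[[g]]) {
      sig <- sample(setdiff(DNA_BASES, backbone[j]), 1)
      X[group_rows[[g]], j] <- sig
    }
    add_truth(g, plan$planted_specific[[g]], "planted")
    if (plan$n_groups == 2) {
      other <- setdiff(plan$group_names, g)
      add_truth(other, plan$planted_specific[[g]], "reciprocal")
    }
  }
  for (g in names(plan$gap_blocks)) {
    cols <- seq.int(plan$gap_blocks[[g]][1], plan$gap_blocks[[g]][2])
    X[group_rows[[g]], cols] <- GAP_CHAR
    add_truth(g, cols, "gap")
    if (plan$n_groups == 2) {
      add_truth(setdiff(plan$group_names, g), cols, "reciprocal")
    }
  }
  for (g in names(plan$spoiled)) {
    # The leak recipient must leave the backbone base represented outside the
    # focal group, or a third group could become specific by accident: with 3+
    # groups, leak into a group that keeps another strain on the backbone.
    other <- setdiff(plan$group_names, g)
    multi <- other[plan$sizes[match(other, plan$group_names)] >= 2]
    if (plan$n_groups >= 3 && !length(multi)) {
      tm_abort(paste0("spoiled columns with 3+ groups require an outgroup ",
                      "with 2+ strains to absorb the leak"), "plan")
    }
    candidate_rows <- if (length(multi)) unlist(group_rows[multi])
                      else unlist(group_rows[other])
    for (j in plan$spoiled[[g]]) {
      sig <- sample(setdiff(DNA_BASES, backbone[j]), 1)
      X[group_rows[[g]], j] <- sig
      leak <- candidate_rows[sample.int(length(candidate_rows), 1)]
      X[leak, j] <- sig  # leak: must disqualify the column
    }
  }

  if (plan$strain_noise > 0) {
    structured <- unlist(c(plan$planted_specific,
                           lapply(plan$gap_blocks, function(r) seq.int(r[1], r[2])),
                           plan$spoiled))
    eligible <- setdiff(seq_len(plan$n_columns), structured)
    for (g in plan$group_names[plan$sizes >= 2]) {
      rows <- group_rows[[g]]
      hit <- eligible[stats::runif(length(eligible)) < plan$strain_noise]
      for (j in hit) {
        r <- sample(rows, 1)  # one strain per group per column: stays polymorphic
        X[r, j] <- sample(setdiff(DNA_BASES, X[r, j]), 1)
      }
    }
  }

  records <- tibble::tibble(
    taxon_id = rep(plan$group_names, plan$sizes),
    gene_id = "gene1",
    strain_id = unlist(lapply(plan$sizes, function(k) paste0("S", seq_len(k)))),
    sequence = apply(X, 1, paste, collapse = "")
  )
  truth <- if (length(truth)) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$taxon_id, .data$column)
  } else {
    tibble::tibble(taxon_id = character(), column = integer(), kind = character())
  }
  list(alignment = grouped_alignment(records), truth = truth)
}
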