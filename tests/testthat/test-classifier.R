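groups22 <- list(G1 = 1:2, G2 = 3:4)

test_that("single columns classify by strict exclusion of the signature", {
  # mutually exclusive bases: specific for both groups
  v <- classify_column(c("A", "A", "C", "C"), groups22)
  expect_false(v$conserved_common)
  expect_setequal(v$specific_for[[1]], c("G1", "G2"))

  # identical everywhere: conserved common, specific for nobody
  v <- classify_column(c("A", "A", "A", "A"), groups22)
  expect_true(v$conserved_common)
  expect_length(v$specific_for[[1]], 0)

  # G1 strain-polymorphic: only G2 qualifies
  v <- classify_column(c("A", "G", "C", "C"), groups22)
  expect_equal(v$specific_for[[1]], "G2")

  # signature occurs outside G1; G2 polymorphic: nobody
  v <- classify_column(c("A", "A", "A", "C"), groups22)
  expect_length(v$specific_for[[1]], 0)

  # conserved deletion is a signature; the shared base outside is not
  v <- classify_column(c("-", "-", "C", "C", "C", "C"),
                       list(G1 = 1:2, G2 = 3:4, G3 = 5:6))
  expect_equal(v$specific_for[[1]], "G1")

  expect_error(classify_column(c("A", "A", "C"), groups22),
               class = "taxamark_error_alignment_shape")
})

test_that("ambiguity codes disqualify conservatively", {
  # N inside the focal group: never specific
  v <- classify_column(c("N", "N", "C", "C"), groups22)
  expect_false("G1" %in% v$specific_for[[1]])
  # outgroup R could be the signature A: disqualifies G1; R also spoils G2's C? no
  v <- classify_column(c("A", "A", "R", "R"), groups22)
  expect_length(v$specific_for[[1]], 0)
  # outgroup Y cannot be A: G1 stays specific
  v <- classify_column(c("A", "A", "Y", "Y"), groups22)
  expect_equal(v$specific_for[[1]], "G1")
  # gap signature requires unambiguous bases outside
  v <- classify_column(c("-", "-", "N", "C"), groups22)
  expect_length(v$specific_for[[1]], 0)
  # conserved-common requires zero gaps and zero ambiguity codes
  v <- classify_column(c("N", "N", "N", "N"), groups22)
  expect_false(v$conserved_common)
})

test_that("whole-alignment classification matches the brute-force oracle", {
  set.seed(11)
  for (k in 1:10) {
    n_strains <- sample(1:4, 1)
    plan <- plant_plan(n_groups = sample(2:4, 1),
                       strains_per_group = n_strains,
                       n_columns = 300,
                       planted_specific = sample(0:5, 1),
                       strain_noise = if (n_strains >= 2) sample(c(0, 0.02), 1) else 0,
                       gap_blocks = if (k %% 2) list(G1 = c(101, 110)),
                       seed = 100 + k)
    fx <- generate_alignment(plan)
    v <- classify_alignment(fx$alignment)
    oracle <- oracle_specific_table(fx$alignment)
    got <- dplyr::arrange(specific_columns(v), taxon_id, column)
    expect_equal(got$taxon_id, oracle$taxon_id)
    expect_equal(got$column, oracle$column)
    # and the oracle agrees with the generator's planted truth
    expect_same_calls(v, fx$truth)
  }
})

test_that("fully identical alignment is conserved-common everywhere", {
  aln <- make_aln(c("A", "A", "B"), rep(strrep("ACGT", 10), 3))
  v <- classify_alignment(aln)
  expect_true(all(v$conserved_common))
  expect_equal(nrow(specific_columns(v)), 0)
})

test_that("classification is invariant to non-focal group order and redundant members", {
  plan <- plant_plan(3, 2, 120, planted_specific = 3, seed = 5)
  fx <- generate_alignment(plan)
  v1 <- specific_columns(classify_alignment(fx$alignment))

  # permute whole groups (G3 first)
  rec <- fx$alignment$records
  perm <- grouped_alignment(rec[c(5, 6, 1, 2, 3, 4), ])
  v2 <- specific_columns(classify_alignment(perm))
  expect_equal(dplyr::arrange(v1, taxon_id, column),
               dplyr::arrange(v2, taxon_id, column))

  # add a strain identical to a G1 member: idempotent under redundancy
  aug <- dplyr::bind_rows(rec, dplyr::mutate(rec[1, ], strain_id = "extra"))
  v3 <- specific_columns(classify_alignment(grouped_alignment(aug)))
  expect_equal(dplyr::arrange(v1, taxon_id, column),
               dplyr::arrange(v3, taxon_id, column))
})

test_that("an outgroup strain carrying the signature removes only that call", {
  aln <- make_aln(c("G1", "G1", "G2", "G2", "G3"),
                  c("AATT", "AATT", "CCTT", "CCTT", "GGTA"))
  before <- specific_columns(classify_alignment(aln))
  # G1 signature at columns 1,2 is A; give the G3 strain an A at column 1
  spoiled <- make_aln(c("G1", "G1", "G2", "G2", "G3"),
                      c("AATT", "AATT", "CCTT", "CCTT", "AGTA"))
  after <- specific_columns(classify_alignment(spoiled))
  expect_true(all(before$column[before$taxon_id == "G1"] == c(1, 2)))
  expect_equal(after$column[after$taxon_id == "G1"], 2L)
  # G2's calls at those columns are untouched
  expect_equal(before$column[before$taxon_id == "G2"],
               after$column[after$taxon_id == "G2"])
})

test_that("fragment counts tile the alignment and sum to the total", {
  plan <- plant_plan(2, 2, 60,
                     planted_specific = list(G1 = c(5L, 18L, 25L)), seed = 1)
  fx <- generate_alignment(plan)
  v <- classify_alignment(fx$alignment)
  frags <- count_fragment_mutations(v, "G1", 20)
  expect_equal(frags$m, c(2L, 1L, 0L))
  expect_false(any(frags$partial))

  # trailing partial fragment is counted and flagged
  plan50 <- plant_plan(2, 2, 50, planted_specific = list(G1 = c(45L, 49L)),
                       seed = 2)
  fx50 <- generate_alignment(plan50)
  f50 <- count_fragment_mutations(classify_alignment(fx50$alignment), "G1", 20)
  expect_equal(nrow(f50), 3)
  expect_equal(f50$partial, c(FALSE, FALSE, TRUE))
  expect_equal(f50$n_cols[3], 10L)
  expect_equal(f50$m[3], 2L)

  # sum over fragments equals the total number of specific columns
  spec <- specific_columns(v)
  expect_equal(sum(frags$m), sum(spec$taxon_id == "G1"))
  expect_true(all(frags$m >= 0 & frags$m <= 20))

  expect_error(count_fragment_mutations(v, "nope", 20),
               class = "taxamark_error_unknown_group")
  expect_error(count_fragment_mutations(v, "G1", 0),
               class = "taxamark_error_parameter")
})
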