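fixture_with_gaps <- function(seed = 21) {
  generate_alignment(plant_plan(
    3, 3, 600,
    planted_specific = list(G1 = as.integer(c(41:44, 305L, 422L)),
                            G2 = c(90L, 91L)),
    gap_blocks = list(G1 = c(201, 210)),
    strain_noise = 0.01, seed = seed))
}

test_that("focal consensus maps alignment columns onto the ungapped target", {
  # single-strain focal group: consensus is that strain's degapped subsequence
  aln <- make_aln(c("A", "B", "B"), c("AC-GT", "ACCGT", "ACCGA"))
  cons <- build_focal_consensus(aln, "A", c(1, 5))
  expect_equal(paste(cons$base, collapse = ""), "ACGT")
  expect_equal(cons$column, c(1L, 2L, 4L, 5L))

  # group-wide gap column dropped from map
  aln2 <- make_aln(c("A", "A", "B"), c("ACGT-", "ACGT-", "ACGTG"))
  cons2 <- build_focal_consensus(aln2, "A", c(1, 5))
  expect_equal(paste(cons2$base, collapse = ""), "ACGT")
  expect_equal(cons2$column, 1:4)

  # majority base wins; alphabetical on ties
  aln3 <- make_aln(c("A", "A", "A", "B"), c("AAT", "AGT", "AGT", "CCC"))
  cons3 <- build_focal_consensus(aln3, "A", c(1, 3))
  expect_equal(paste(cons3$base, collapse = ""), "AGT")
  aln4 <- make_aln(c("A", "A", "B"), c("GT", "CT", "AA"))
  expect_equal(build_focal_consensus(aln4, "A", c(1, 2))$base[1], "C")

  # no unambiguous base at a column: dropped with a warning
  aln5 <- make_aln(c("A", "A", "A", "B"), c("NT", "NT", "-T", "CT"))
  expect_warning(cons5 <- build_focal_consensus(aln5, "A", c(1, 2)),
                 "no unambiguous base")
  expect_equal(cons5$column, 2L)

  expect_error(build_focal_consensus(aln, "A", c(0, 5)),
               class = "taxamark_error_parameter")
  expect_error(build_focal_consensus(aln, "Z", c(1, 5)),
               class = "taxamark_error_unknown_group")
})

test_that("masked target marks exactly the focal-specific and conserved columns", {
  fx <- fixture_with_gaps()
  v <- classify_alignment(fx$alignment)
  path <- tempfile()
  mt <- make_primerexplorer_input(fx$alignment, v, "G1", c(1, 600),
                                  path = path)
  expect_equal(nchar(mt$sequence), nchar(mt$annotation))

  # '-' positions are exactly the mapped G1-specific columns (gap signatures
  # have no position on the degapped target and are excluded)
  dash_cols <- mt$map$column[strsplit(mt$annotation, "")[[1]] == "-"]
  truth_cols <- fx$truth$column[fx$truth$taxon_id == "G1" &
                                  fx$truth$kind != "gap"]
  expect_setequal(dash_cols, truth_cols)

  # '*' positions are exactly the mapped conserved-common columns; disjoint
  star_cols <- mt$map$column[strsplit(mt$annotation, "")[[1]] == "*"]
  expect_setequal(star_cols,
                  intersect(v$column[v$conserved_common], mt$map$column))
  expect_length(intersect(dash_cols, star_cols), 0)

  # column map strictly increasing
  expect_true(all(diff(mt$map$column) > 0))

  # dash count equals fragment-count sum minus focal-gap signature columns
  frags <- count_fragment_mutations(v, "G1", 20)
  n_gap_sig <- sum(fx$truth$taxon_id == "G1" & fx$truth$kind == "gap")
  expect_equal(sum(strsplit(mt$annotation, "")[[1]] == "-"),
               sum(frags$m) - n_gap_sig)

  # file round-trips and block lines are length-matched
  back <- read_masked_target(path)
  expect_equal(back$sequence, mt$sequence)
  expect_equal(back$annotation, mt$annotation)
  expect_equal(back$group, "G1")
  lines <- readLines(path)[-1]
  seq_lines <- lines[seq(1, length(lines), 2)]
  ann_lines <- lines[seq(2, length(lines), 2)]
  expect_equal(nchar(seq_lines), nchar(ann_lines))
  expect_true(all(nchar(seq_lines) <= 60))
})

test_that("fully conserved region annotates as all asterisks", {
  aln <- make_aln(c("A", "A", "B"), rep(strrep("ACGT", 5), 3))
  v <- classify_alignment(aln)
  mt <- make_primerexplorer_input(aln, v, "A", c(1, 20))
  expect_equal(mt$annotation, strrep("*", 20))
})

test_that("line-ending modes differ only in terminators; size limit enforced", {
  fx <- fixture_with_gaps(seed = 22)
  v <- classify_alignment(fx$alignment)
  pu <- tempfile(); pw <- tempfile()
  make_primerexplorer_input(fx$alignment, v, "G2", c(1, 600), path = pu)
  make_primerexplorer_input(fx$alignment, v, "G2", c(1, 600), path = pw,
                            line_endings = "windows")
  raw_w <- readBin(pw, "raw", file.info(pw)$size)
  nl <- which(raw_w == as.raw(0x0a))
  expect_true(all(raw_w[nl - 1] == as.raw(0x0d)))
  expect_equal(gsub("\r", "", rawToChar(raw_w)),
               rawToChar(readBin(pu, "raw", file.info(pu)$size)))

  big <- generate_alignment(plant_plan(2, 1, 2300, seed = 1))
  vb <- classify_alignment(big$alignment)
  expect_error(
    make_primerexplorer_input(big$alignment, vb, "G1", c(1, 2300)),
    class = "taxamark_error_size")
})

test_that("bundling collects outputs, zips them, and refuses collisions", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt"); writeLines(c("alpha", "beta"), f1)
  f2 <- file.path(dir, "b.tsv"); writeLines("x\ty", f2)

  dest <- bundle_outputs(c(f1, f2), dir, "proj1", zip = TRUE)
  expect_true(file.exists(file.path(dest, "a.txt")))
  zp <- attr(dest, "zip")
  expect_true(file.exists(zp))

  # archive is standard: readable by utils::unzip, contents identical
  listing <- utils::unzip(zp, list = TRUE)
  expect_setequal(listing$Name, c("proj1/a.txt", "proj1/b.tsv"))
  ex <- file.path(dir, "extract")
  utils::unzip(zp, exdir = ex)
  expect_identical(readLines(file.path(ex, "proj1", "a.txt")),
                   c("alpha", "beta"))

  expect_error(bundle_outputs(c(f1, f2), dir, "proj1"),
               class = "taxamark_error_collision")
  expect_silent(bundle_outputs(c(f1, f2), dir, "proj1", zip = FALSE,
                               overwrite = TRUE))
  expect_error(bundle_outputs(file.path(dir, "missing.txt"), dir, "proj2"),
               class = "taxamark_error_write")
})
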