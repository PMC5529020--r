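# Fixture epitope bundles mimic the pipeline's segment/core/similar output.
fixture_epitope <- function(acc, win_start, win_end, s, matched = TRUE) {
  list(
    core = structure(list(core = strrep("A", win_end - win_start + 1),
                          accession = acc, start = win_start, end = win_end),
                     class = "core_motif"),
    similar = data.frame(accession = acc, core_seq = "", distance = 0L,
                         matched = matched, win_start = win_start,
                         win_end = win_end, n_peptides = 1L, sum = s,
                         stringsAsFactors = FALSE)
  )
}

test_that("residue scores paint cores, default to zero, and resolve overlaps by max", {
  expect_equal(as.numeric(residue_scores(list(), "T1", 30)), rep(0, 30))

  one <- residue_scores(list(fixture_epitope("T1", 10, 17, 420)), "T1", 30)
  expect_equal(sum(one == 420), 8L)
  expect_equal(which(one > 0), 10:17)

  two <- residue_scores(list(fixture_epitope("T1", 10, 17, 100),
                             fixture_epitope("T1", 14, 20, 250)), "T1", 30)
  expect_equal(as.numeric(two[14:17]), rep(250, 4))  # overlap takes the max
  expect_equal(as.numeric(two[10:13]), rep(100, 4))
  expect_equal(as.numeric(two[18:20]), rep(250, 3))

  # unmatched toxins and other accessions stay at zero
  zero <- residue_scores(list(fixture_epitope("T9", 10, 17, 100)), "T1", 30)
  expect_true(all(zero == 0))
})

test_that("B-factor painting rescales to 99.99 and preserves all other bytes", {
  pdb <- make_synthetic_pdb(tempfile(fileext = ".pdb"), n_res = 20)
  before <- readLines(pdb)

  scores <- numeric(20)
  scores[5:8] <- 200
  scores[12] <- 400
  out <- tempfile(fileext = ".pdb")
  write_scored_structure(pdb, scores, out)
  after <- readLines(out)

  expect_equal(length(after), length(before))
  atom <- startsWith(before, "ATOM  ")
  expect_identical(after[!atom], before[!atom])
  # only columns 61-66 of ATOM records may change
  expect_identical(substr(after[atom], 1, 60), substr(before[atom], 1, 60))
  expect_identical(substr(after[atom], 67, 80), substr(before[atom], 67, 80))

  b <- as.numeric(substr(after[atom], 61, 66))
  expect_equal(b[12], 99.99)
  expect_equal(b[5:8], rep(round(200 / 400 * 99.99, 2), 4))
  expect_true(all(b[-c(5:8, 12)] == 0))
})

test_that("painted structures stay parseable with coordinates intact", {
  skip_if_not_installed("bio3d")
  pdb <- make_synthetic_pdb(tempfile(fileext = ".pdb"), n_res = 12)
  scores <- seq(0, 55, length.out = 12)
  out <- tempfile(fileext = ".pdb")
  write_scored_structure(pdb, scores, out)
  p0 <- bio3d::read.pdb(pdb)
  p1 <- bio3d::read.pdb(out)
  expect_equal(nrow(p1$atom), nrow(p0$atom))
  expect_equal(p1$atom$x, p0$atom$x)
  expect_equal(p1$atom$y, p0$atom$y)
  expect_equal(p1$atom$z, p0$atom$z)
  # round-trip read-back equals the rescaled scores to 2 decimals
  expect_equal(p1$atom$b, round(scores / max(scores) * 99.99, 2))
})

test_that("offsets, unmapped residues and malformed files are handled", {
  pdb <- make_synthetic_pdb(tempfile(fileext = ".pdb"), n_res = 10,
                            first_res = 101L)
  scores <- numeric(10); scores[3] <- 10
  out <- tempfile(fileext = ".pdb")
  # toxin_position = resseq + offset: residues 101..110 -> positions 1..10
  write_scored_structure(pdb, scores, out, offset = -100L)
  b <- as.numeric(substr(grep("^ATOM", readLines(out), value = TRUE), 61, 66))
  expect_equal(which(b > 0), 3L)

  # an all-zero map writes zero B-factors everywhere
  write_scored_structure(pdb, numeric(10), out, offset = -100L)
  b0 <- as.numeric(substr(grep("^ATOM", readLines(out), value = TRUE), 61, 66))
  expect_true(all(b0 == 0))

  # residues outside the map warn and stay zero
  expect_warning(write_scored_structure(pdb, scores[1:5], out, offset = -100L),
                 "outside")

  # other chains untouched
  write_scored_structure(pdb, scores, out, chain = "B", offset = -100L)
  expect_identical(readLines(out), readLines(pdb))

  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1"), bad)
  expect_error(write_scored_structure(bad, scores, out), "malformed|66")
  empty <- tempfile(fileext = ".pdb")
  writeLines("HEADER ONLY", empty)
  expect_error(write_scored_structure(empty, scores, out), "no ATOM")
})
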