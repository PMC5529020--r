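test_that("replicate medians are robust to outlier fields and exclude corners", {
  tox <- toxin_set("T1", random_aa(15, seed = 61))
  pep <- tox$sequence
  lib <- build_library(tox)
  lay <- assign_layout(lib, replicates = 5, corner_field_count = 3, seed = 1)
  reps <- which(!lay$is_corner_control)
  bg <- data.frame(field_id = lay$field_id, peptide = lay$peptide, intensity = 0)
  bg$intensity[reps] <- c(1, 2, 3, 4, 100)
  bg$intensity[lay$is_corner_control] <- c(7, 8, 9)
  av <- bg
  med <- replicate_median(bg, av, lay)
  expect_equal(med$signal$background_median, 3)
  expect_equal(sort(med$corner_background), c(7, 8, 9))
})

test_that("replicate medians handle single and even replicate counts", {
  tox <- toxin_set("T1", random_aa(15, seed = 62))
  lib <- build_library(tox)
  lay1 <- assign_layout(lib, replicates = 1, corner_field_count = 0, seed = 1)
  bg1 <- data.frame(field_id = lay1$field_id, peptide = lay1$peptide, intensity = 7)
  expect_equal(replicate_median(bg1, bg1, lay1)$signal$background_median, 7)

  # a lost replicate leaves an even count: median averages the middle pair
  lay4 <- assign_layout(lib, replicates = 5, corner_field_count = 0, seed = 1)
  bg4 <- data.frame(field_id = lay4$field_id, peptide = lay4$peptide,
                    intensity = c(1, 2, 3, 4, 99))
  bg4 <- bg4[1:4, ]
  expect_equal(replicate_median(bg4, bg4, lay4)$signal$background_median, 2.5)
})

test_that("a peptide absent from the table is rejected by name", {
  tox <- toxin_set("T1", random_aa(16, seed = 63))  # 2 peptides
  lib <- build_library(tox)
  lay <- assign_layout(lib, replicates = 2, corner_field_count = 0, seed = 1)
  bg <- data.frame(field_id = lay$field_id, peptide = lay$peptide, intensity = 1)
  drop <- lib$peptides[2]
  bad <- bg[bg$peptide != drop, ]
  expect_error(replicate_median(bad, bad, lay), drop, fixed = TRUE)
})

test_that("re-incubation factor is the ratio of corner medians", {
  expect_equal(estimate_reincubation(rep(50, 11), rep(215, 11)), 4.3)
  x <- rlnorm(100, 3, 0.5)
  expect_equal(estimate_reincubation(x, x), 1.0)
  expect_error(estimate_reincubation(numeric(0), 1), "non-empty")
  expect_error(estimate_reincubation(rep(0, 5), rep(1, 5)), "positive")
})

test_that("re-incubation estimation is scale-equivariant", {
  set.seed(71)
  bg <- rlnorm(200, 4, 0.5)
  av <- rlnorm(200, 5, 0.5)
  f <- estimate_reincubation(bg, av)
  expect_equal(estimate_reincubation(bg, 3 * av), 3 * f)
  expect_equal(estimate_reincubation(2 * bg, av), f / 2)
})

test_that("signal correction subtracts the scaled background without clamping", {
  expect_equal(correct_signal(100, 10, 4.3), 57)
  expect_equal(correct_signal(43, 10, 4.3), 0)
  expect_equal(correct_signal(10, 10, 4.3), -33)
  expect_equal(correct_signal(c(100, 43), c(10, 10), 4.3), c(57, 0))
})

test_that("running median matches hand-computed windows and terminal rule", {
  expect_equal(running_median(c(10, 50, 20)), c(30, 20, 35))
  expect_equal(running_median(rep(3.5, 4)), rep(3.5, 4))
  expect_equal(running_median(7), 7)
  expect_equal(running_median(c(2, 10)), c(6, 6))
  expect_equal(running_median(numeric(0)), numeric(0))
})

test_that("running median equals the brute-force windowed oracle", {
  set.seed(81)
  for (rep in 1:100) {
    x <- rnorm(sample(1:40, 1), sd = 50)
    expect_equal(running_median(x), oracle_running_median(x))
  }
})

test_that("profiles map shared peptides to every origin and smooth correctly", {
  s <- random_aa(29, seed = 91)
  tox <- toxin_set(c("T1", "T2"), c(s, s))
  tiles <- tile_sequence(s)
  sig <- data.frame(peptide = unique(tiles),
                    corrected = seq_along(unique(tiles)) * 10)
  prof <- map_to_toxins(sig, tox)
  expect_length(prof$T1$score, 15L)
  expect_identical(prof$T1$score, prof$T2$score)

  # hand-built 5-peptide toxin with known scores
  s19 <- random_aa(19, seed = 92)
  tox5 <- toxin_set("H1", s19)
  sig5 <- data.frame(peptide = tile_sequence(s19),
                     corrected = c(10, 50, 20, 5, 0))
  p5 <- map_to_toxins(sig5, tox5)$H1
  expect_equal(p5$raw, c(10, 50, 20, 5, 0))
  expect_equal(p5$score, c(30, 20, 20, 5, 2.5))
})

test_that("corrected scores under the null generator have mean near zero", {
  arr <- make_array(n_toxins = 100, len = 34, n_epitopes = 0, seed = 100)
  med <- replicate_median(arr$background, arr$antivenom, arr$layout)
  # with the generator's true factor the corrected null scores are symmetric
  # around zero; an estimated factor adds a common shift shared by all
  # peptides, which the independent-SE bound does not cover
  corrected <- correct_signal(med$signal$antivenom_median,
                              med$signal$background_median, 4.3)
  se <- sd(corrected) / sqrt(length(corrected))
  expect_lt(abs(mean(corrected)), 3 * se + 1e-9)
})
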