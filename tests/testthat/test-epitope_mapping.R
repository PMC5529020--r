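test_that("aligned FASTA and Clustal inputs parse to the same alignment", {
  seqs <- c(S1 = "ACDEF-GHIKL", S2 = "ACD--WGHIKL")
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">S1", seqs[["S1"]], ">S2", seqs[["S2"]]), fa)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               paste0("S1              ", seqs[["S1"]]),
               paste0("S2              ", seqs[["S2"]]),
               "                ***    ****"), cl)
  m1 <- read_msa(fa)
  m2 <- read_msa(cl)
  expect_identical(unname(m1[c("S1", "S2")]), unname(seqs))
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("profiles anchor to alignment columns; gaps shift and truncate", {
  # gap-free identical sequences: columns equal positions
  s <- random_aa(20, seed = 131)
  tox <- toxin_set(c("T1", "T2"), c(s, s))
  prof <- list(T1 = make_profile("T1", 1:6), T2 = make_profile("T2", 11:16))
  msa <- setNames(c(s, s), c("T1", "T2"))
  al <- map_profiles_to_msa(prof, msa, toxins = tox)
  expect_equal(al$scores["T1", 1:6], 1:6)
  expect_true(all(is.na(al$scores["T1", 7:20])))  # last 14 residues: no score

  # a 3-column gap in one row shifts that row's scores right by 3 columns
  s1 <- random_aa(20, seed = 132)
  s2 <- random_aa(20, seed = 133)
  msa2 <- c(A = paste0(substr(s1, 1, 20), "---"),
            B = paste0(substr(s2, 1, 4), "---", substr(s2, 5, 20)))
  prof2 <- list(A = make_profile("A", 1:6), B = make_profile("B", 101:106))
  al2 <- map_profiles_to_msa(prof2, msa2)
  expect_equal(al2$scores["A", 1:6], 1:6)
  expect_equal(al2$scores["B", 1:4], 101:104)
  expect_true(all(is.na(al2$scores["B", 5:7])))
  expect_equal(al2$scores["B", 8:9], 105:106)
})

test_that("sequence/alignment mismatches are rejected by accession", {
  s <- random_aa(20, seed = 134)
  tox <- toxin_set("T1", s)
  wrong <- c(T1 = random_aa(20, seed = 135))
  expect_error(
    map_profiles_to_msa(list(T1 = make_profile("T1", 1:6)), wrong, toxins = tox),
    "T1")
  expect_error(
    map_profiles_to_msa(list(T9 = make_profile("T9", 1:6)), wrong),
    "T9")
})

test_that("shared segments require min_share toxins above threshold per column", {
  # 12 toxins with a common elevated window, 8 without
  base <- random_aa(40, seed = 141)
  accs <- sprintf("T%02d", 1:20)
  msa <- setNames(rep(base, 20), accs)
  profs <- lapply(accs, function(a) {
    sc <- rep(0, 26)
    if (a <= "T12") sc[10:14] <- 100
    make_profile(a, sc)
  })
  names(profs) <- accs
  al <- map_profiles_to_msa(profs, msa)
  segs <- find_shared_segments(al, threshold = 50, min_share = 10)
  expect_length(segs, 1L)
  expect_equal(c(segs[[1]]$start, segs[[1]]$end), c(10, 14))
  expect_length(segs[[1]]$members, 12L)

  # boundary: 12 sharing toxins never qualify at min_share 13
  segs9 <- find_shared_segments(al, threshold = 50, min_share = 13)
  expect_length(segs9, 0L)
  expect_length(find_shared_segments(al, threshold = 1e9), 0L)
})

test_that("core length obeys 15 - run + 1 including the 13-peptide case", {
  base <- random_aa(50, seed = 151)
  msa <- setNames(base, "T1")
  for (run in c(1L, 8L, 13L)) {
    sc <- rep(0, 36)
    sc[5:(5 + run - 1L)] <- 100
    prof <- list(T1 = make_profile("T1", sc))
    al <- map_profiles_to_msa(prof, msa)
    seg <- find_shared_segments(al, threshold = 50, min_share = 1)[[1]]
    core <- extract_core_motif(seg, al, prof, threshold = 50)
    expect_equal(core$run_length, run)
    expect_equal(nchar(core$core), 15L - run + 1L)
    expect_identical(core$core, substr(base, 5 + run - 1L, 5 + 14L))
  }
})

test_that("the anchor toxin is the member with the highest peak", {
  base <- random_aa(40, seed = 152)
  accs <- c("T1", "T2", "T3")
  msa <- setNames(rep(base, 3), accs)
  mk <- function(a, peak) {
    sc <- rep(0, 26); sc[8:10] <- peak; make_profile(a, sc)
  }
  profs <- list(T1 = mk("T1", 80), T2 = mk("T2", 300), T3 = mk("T3", 80))
  al <- map_profiles_to_msa(profs, msa)
  seg <- find_shared_segments(al, 50, min_share = 3)[[1]]
  core <- extract_core_motif(seg, al, profs, 50)
  expect_identical(core$accession, "T2")
  # tie on peak breaks by accession order
  profs$T2 <- mk("T2", 80)
  al2 <- map_profiles_to_msa(profs, msa)
  core2 <- extract_core_motif(find_shared_segments(al2, 50, 3)[[1]], al2, profs, 50)
  expect_identical(core2$accession, "T1")
})

test_that("collect_similar anchors at core columns and bounds mismatches", {
  base <- random_aa(40, seed = 161)
  # identical toxin, a 4-substitution variant, and an exact-core variant
  mutate <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (i in at) ch[i] <- setdiff(AA20, ch[i])[1]
    paste(ch, collapse = "")
  }
  core_span <- 12:19  # 8-residue core from run of 8 starting at 5
  s_top <- base
  s_same <- base
  s_far <- mutate(base, core_span[1:4])
  accs <- c("TOP", "SAME", "FAR")
  msa <- setNames(c(s_top, s_same, s_far), accs)
  sc <- rep(0, 26); sc[5:12] <- 100
  sc_top <- rep(0, 26); sc_top[5:12] <- 150  # TOP carries the highest peak
  profs <- list(TOP = make_profile("TOP", sc_top),
                SAME = make_profile("SAME", sc),
                FAR = make_profile("FAR", sc))
  al <- map_profiles_to_msa(profs, msa)
  seg <- find_shared_segments(al, 50, min_share = 2)[[1]]
  core <- extract_core_motif(seg, al, profs, 50)
  expect_equal(nchar(core$core), 8L)
  sim <- collect_similar(core, al, profs, max_mismatch = 3)
  expect_identical(sim$matched, c(TRUE, TRUE, FALSE))
  # the 8 peptides covering the core span (starts 5..12) are summed
  expect_equal(sim$sum[sim$accession == "TOP"], 8 * 150)
  expect_equal(sim$sum[sim$accession == "SAME"], 8 * 100)
  expect_equal(sim$n_peptides[sim$matched], c(8L, 8L))
  expect_equal(sim$distance[sim$accession == "FAR"], 4L)
  # max_mismatch = 0 reduces to exact containment
  sim0 <- collect_similar(core, al, profs, max_mismatch = 0)
  expect_identical(sim0$matched, c(TRUE, TRUE, FALSE))
})

test_that("collect_similar sums equal an exhaustive Hamming scan", {
  set.seed(171)
  for (rep in 1:10) {
    n <- 6
    L <- 40
    base <- random_aa(L)
    seqs <- vapply(1:n, function(i) {
      ch <- strsplit(base, "")[[1]]
      nmut <- sample(0:6, 1)
      at <- sample(L, nmut)
      for (j in at) ch[j] <- sample(AA20, 1)
      paste(ch, collapse = "")
    }, character(1))
    accs <- sprintf("S%d", 1:n)
    msa <- setNames(seqs, accs)
    profs <- lapply(1:n, function(i) {
      make_profile(accs[i], round(rnorm(L - 14, 0, 60), 3))
    })
    names(profs) <- accs
    # force a clean anchor run in S1
    profs$S1$score[7:11] <- 200
    al <- map_profiles_to_msa(profs, msa)
    seg <- find_shared_segments(al, 150, min_share = 1)[[1]]
    core <- extract_core_motif(seg, al, profs, 150)
    sim <- collect_similar(core, al, profs, max_mismatch = 3)
    # oracle: scan all 15-mers of each toxin; those covering the core span
    # whose residues there are within Hamming 3 of the core contribute
    cs <- core$start; ce <- core$end
    for (i in 1:n) {
      sub <- substr(seqs[i], cs, ce)
      d <- sum(strsplit(sub, "")[[1]] != strsplit(core$core, "")[[1]])
      row <- sim[sim$accession == accs[i], ]
      expect_equal(row$distance, d)
      if (d <= 3) {
        starts <- Filter(function(st) st <= cs && st + 14 >= ce, 1:(L - 14))
        expect_equal(row$sum, sum(profs[[i]]$score[starts]))
      } else {
        expect_false(row$matched)
      }
    }
  }
})
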