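test_that("packaged ground truth matches the documented signature structure", {
  cfg <- ground_truth_profiles()
  P <- cfg$profiles
  expect_identical(nrow(P), 5L)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(P >= 0))
  # flagship substitutions
  expect_true(names(which.max(P["AAS3", ])) %in%
                c("R>H", "R>C", "R>Q", "R>W"))
  expect_true(names(which.max(P["AAS5", ])) %in% c("E>K", "E>Q"))
  expect_true(names(which.max(P["AAS2", ])) %in% c("P>S", "D>N"))
  # well separated
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(cosine_similarity(P[i, ], P[j, ]), 0.5)
  # deterministic construction
  expect_identical(ground_truth_profiles()$profiles, P)
})

test_that("cohort generation is seeded and concentrates at small Dirichlet mass", {
  cfg <- ground_truth_profiles()
  c1 <- simulate_cohort(cfg, 30, seed = 77, mutations = 150)
  c2 <- simulate_cohort(cfg, 30, seed = 77, mutations = 150)
  expect_identical(c1$fractions, c2$fractions)
  expect_identical(c1$truth$weights, c2$truth$weights)
  c3 <- simulate_cohort(cfg, 30, seed = 78, mutations = 150)
  expect_false(identical(c1$fractions, c3$fractions))
  # near-pure samples in the small-concentration limit
  cfg$concentration <- 0.005
  pure <- simulate_cohort(cfg, 40, seed = 79, mutations = 150)
  expect_gt(mean(apply(pure$truth$weights, 1, max) > 0.95), 0.8)
})

test_that("mean cohort fractions converge to the mean mixture profile", {
  cfg <- ground_truth_profiles()
  cohort <- simulate_cohort(cfg, 400, seed = 80, mutations = 400)
  # symmetric Dirichlet: expected mixture is the average planted profile
  expected <- colMeans(cfg$profiles)
  got <- colMeans(cohort$fractions)
  expect_lt(tv_distance(got, expected), 0.03)
})

test_that("generated CDS records honour the coding-sequence contract", {
  cds <- simulate_cds(n_records = 8, length = 250, gc_fraction = 0.6,
                      seed = 44)
  expect_length(cds, 8)
  expect_true(all(nchar(cds) %% 3 == 0))
  expect_false(any(grepl("[^ACGT]", cds)))
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # no internal stops in frame
  for (s in cds) {
    codons <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 1, 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  expect_identical(simulate_cds(3, 120, seed = 5), simulate_cds(3, 120, seed = 5))
})

test_that("generated peptidomes carry the planted anchor at the stated purity", {
  peps <- simulate_peptidome(c("2" = "P"), n = 400, purity = 1, seed = 9)
  expect_true(all(substr(peps, 2, 2) == "P"))
  half <- simulate_peptidome(c("2" = "P"), n = 2000, purity = 0.5, seed = 10)
  frac <- mean(substr(half, 2, 2) == "P")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.62)  # 0.5 planted + ~1/20 background
  expect_identical(simulate_peptidome(c("2" = "P"), 50, seed = 3),
                   simulate_peptidome(c("2" = "P"), 50, seed = 3))
})

test_that("generated inputs round-trip through their readers", {
  # CDS through FASTA
  cds <- simulate_cds(4, 150, seed = 21)
  fa <- tempfile(fileext = ".fa")
  write_cds(cds, fa)
  back <- read_cds(fa)
  expect_identical(as.character(back), as.character(cds))
  expect_identical(names(back), names(cds))
  # peptides through TSV
  peps <- list(A1 = simulate_peptidome(c("2" = "L"), 50, seed = 1),
               B1 = simulate_peptidome(c("2" = "P"), 50, seed = 2))
  tsv <- tempfile(fileext = ".tsv")
  write_peptides(peps, tsv)
  expect_identical(read_peptides(tsv), peps)
})

test_that("detection generation is seeded and responds to the slope", {
  fit <- fx_model()
  d1 <- simulate_detection(fit, n_samples = 6, slope = 10, seed = 3)
  d2 <- simulate_detection(fit, n_samples = 6, slope = 10, seed = 3)
  expect_identical(d1$detected, d2$detected)
  # higher slope concentrates detections on high-association substitutions
  d0 <- simulate_detection(fit, n_samples = 6, slope = 0, intercept = -1,
                           seed = 3)
  hi <- simulate_detection(fit, n_samples = 6, slope = 40, intercept = -1,
                           seed = 3)
  gap <- function(d) mean(d$A[d$detected]) - mean(d$A[!d$detected])
  expect_gt(gap(hi), gap(d0) + 0.01)
})
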