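test_that("planted anchors give zero entropy and maximal weight at the anchor position", {
  peps <- simulate_peptidome(anchor = c("2" = "P"), n = 450, lengths = 9,
                             purity = 1, seed = 3)
  mod <- positional_model(peps, allele = "B0702")
  sub <- mod$subsets[["9"]]
  expect_equal(unname(sub$entropy[2]), 0, tolerance = 1e-12)
  expect_identical(which.max(sub$weights), 2L)
  spec <- allele_specificity(mod)
  expect_identical(names(which.max(spec)), "P")
  expect_equal(sum(spec), 1, tolerance = 1e-9)
})

test_that("length subsets below the peptide-count filters are excluded", {
  peps <- c(simulate_peptidome(c("2" = "P"), n = 150, lengths = 9, seed = 1),
            simulate_peptidome(c("2" = "P"), n = 50, lengths = 10, seed = 2))
  mod <- positional_model(peps, min_peptides = 100, min_subset = 100)
  expect_identical(names(mod$subsets), "9")
  expect_error(positional_model(peps[1:50], min_peptides = 400),
               "insufficient data")
  short <- simulate_peptidome(c("1" = "A"), n = 500, lengths = 9, seed = 5)
  expect_error(positional_model(short, min_subset = 600),
               "insufficient data")
})

test_that("a single-residue peptidome yields delta specificity", {
  peps <- rep(strrep("P", 9), 450)
  spec <- allele_specificity(positional_model(peps))
  expect_equal(unname(spec["P"]), 1, tolerance = 1e-12)
  expect_true(all(spec[names(spec) != "P"] == 0))
})

test_that("allele specificity averages subsets weighted by their sizes", {
  # hand-built model: two subsets with delta weights on position 1
  mk_subset <- function(freq_row1, n) {
    L <- 9
    freqs <- matrix(1 / 20, L, 20, dimnames = list(NULL, sort(unique(c(
      "A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
      "Q", "R", "S", "T", "V", "W", "Y")))))
    freqs[1, ] <- freq_row1
    list(frequencies = freqs, entropy = rep(0, L),
         weights = c(1, rep(0, L - 1)), n = n)
  }
  aa <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y"))
  f1 <- setNames(rep(0, 20), aa); f1["P"] <- 1
  f2 <- setNames(rep(0, 20), aa); f2["E"] <- 1
  mod <- structure(list(allele = "X",
                        subsets = list(`9` = mk_subset(f1, 300),
                                       `10` = mk_subset(f2, 100))),
                   class = "hla_positional_model")
  spec <- allele_specificity(mod)
  expect_equal(unname(spec["P"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(spec["E"]), 0.25, tolerance = 1e-12)
})

test_that("signature affinity is the mutated-residue aggregate dotted with specificity", {
  model <- toy_model()  # AAS1: S>P 0.6, L>P 0.4 -> m(P) = 1
  aa <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y"))
  spec <- setNames(rep(0, 20), aa)
  spec["P"] <- 0.8
  spec["K"] <- 0.2
  expect_equal(aas_affinity(spec, model, 1), 0.8, tolerance = 1e-12)
  # AAS2: L>P 0.5, E>K 0.5 -> 0.5*0.8 + 0.5*0.2
  expect_equal(aas_affinity(spec, model, "AAS2"), 0.5, tolerance = 1e-12)
  uniform <- setNames(rep(1 / 20, 20), aa)
  expect_equal(aas_affinity(uniform, model, 1),
               sum(model$coefficients[1, ]) / 20, tolerance = 1e-12)
  expect_error(aas_affinity(spec, model, 9), "index error")
})

test_that("patient affinity is the genotype mean", {
  model <- toy_model()
  aa <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y"))
  pA <- setNames(rep(0, 20), aa); pA["P"] <- 0.2; pA["A"] <- 0.8
  pB <- setNames(rep(0, 20), aa); pB["P"] <- 0.4; pB["A"] <- 0.6
  expect_equal(patient_affinity(rep(list(pA), 6), model, 1), 0.2,
               tolerance = 1e-12)
  expect_equal(patient_affinity(c(rep(list(pA), 3), rep(list(pB), 3)),
                                model, 1), 0.3, tolerance = 1e-12)
  genotype <- list(pA, pB, pA, pB)
  brute <- mean(vapply(genotype, aas_affinity, numeric(1), model, 1))
  expect_equal(patient_affinity(genotype, model, 1), brute)
  expect_error(patient_affinity(list(), model, 1), "empty genotype")
  expect_error(patient_affinity(rep(list(pA), 7), model, 1), "at most 6")
})

test_that("9-mer scoring follows the entropy-weighted positional specificity", {
  all_p <- positional_model(rep(strrep("P", 9), 450))
  expect_gt(score_9mer(strrep("P", 9), all_p), 0)
  expect_equal(score_9mer(strrep("A", 9), all_p), 0)
  expect_error(score_9mer("PPPP", all_p), "9-mer")
  # uniform model scores every peptide equally
  unif <- simulate_peptidome(anchor = character(0), n = 3000, lengths = 9,
                             seed = 7)
  mod_u <- positional_model(unif)
  s1 <- score_9mer("ACDEFGHIK", mod_u)
  s2 <- score_9mer("LMNPQRSTV", mod_u)
  expect_equal(s1, s2, tolerance = 0.1)
  # max contract across a genotype
  anchored <- positional_model(simulate_peptidome(c("2" = "P"), 450,
                                                  seed = 8))
  models <- list(u = mod_u, a = anchored)
  pep <- "APAAAAAAA"
  best <- best_allele_score(pep, models)
  expect_equal(best$score, max(score_9mer(pep, mod_u),
                               score_9mer(pep, anchored)))
})

test_that("raising a residue's positional specificity never lowers a 9-mer score", {
  mod <- positional_model(simulate_peptidome(c("2" = "P", "9" = "L"),
                                             n = 600, purity = 0.8,
                                             seed = 12))
  sub <- mod$subsets[["9"]]
  pep <- strsplit("AAAAAAAAA", "")[[1]]
  base_score <- score_9mer(paste(pep, collapse = ""), mod)
  for (pos in c(2, 5, 9)) {
    f <- sub$frequencies[pos, ]
    better <- names(f)[f > f["A"]]
    for (b in better) {
      p2 <- pep; p2[pos] <- b
      expect_gte(score_9mer(paste(p2, collapse = ""), mod), base_score)
    }
  }
})

test_that("enrichment odds ratio and exact p-value match the oracles", {
  sym <- enrichment_or(c(10, 10, 10, 10))
  expect_equal(sym$odds_ratio, 1)
  res <- enrichment_or(c(20, 10, 10, 20))
  expect_equal(res$odds_ratio, 4)
  expect_false(res$continuity_corrected)
  # independent hypergeometric enumeration of the two-sided exact p
  a <- 20; b <- 10; c <- 10; d <- 20
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  zero <- enrichment_or(c(5, 0, 3, 4))
  expect_true(zero$continuity_corrected)
  expect_equal(zero$odds_ratio, (5.5 * 4.5) / (0.5 * 3.5))
  expect_error(enrichment_or(c(0, 0, 0, 0)), "all-zero")
})

test_that("best-allele scores separate presented 9-mers from uniform decoys", {
  genotype <- list(
    A = positional_model(simulate_peptidome(c("2" = "L", "9" = "V"),
                                            n = 500, purity = 0.9, seed = 31)),
    B = positional_model(simulate_peptidome(c("2" = "P", "9" = "K"),
                                            n = 500, purity = 0.9, seed = 32)))
  presented <- c(simulate_peptidome(c("2" = "L", "9" = "V"), n = 100,
                                    purity = 0.9, seed = 33),
                 simulate_peptidome(c("2" = "P", "9" = "K"), n = 100,
                                    purity = 0.9, seed = 34))
  decoys <- simulate_peptidome(anchor = character(0), n = 200, seed = 35)
  scores <- vapply(c(presented, decoys), function(p)
    best_allele_score(p, genotype)$score, numeric(1))
  labels <- rep(c(TRUE, FALSE), each = 200)
  expect_gt(roc_auc(scores, labels), 0.7)
})
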