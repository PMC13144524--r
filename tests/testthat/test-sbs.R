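# independent exhaustive site scan used as the oracle, built on the
# Biostrings genetic code rather than the package's tables
oracle_sites <- function(seqs) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (r in seq_along(seqs)) {
    s <- seqs[[r]]
    for (p in 2:(nchar(s) - 1)) {
      ref <- substr(s, p, p)
      cs <- p - ((p - 1) %% 3)
      codon <- substr(s, cs, cs + 2)
      for (alt in setdiff(bases, ref)) {
        mutated <- codon
        substr(mutated, p - cs + 1, p - cs + 1) <- alt
        wt <- oracle_translate(codon)
        mut <- oracle_translate(mutated)
        type <- if (wt == "*") "stop_context"
          else if (mut == "*") "nonsense"
          else if (mut == wt) "synonymous" else "missense"
        out[[length(out) + 1]] <- data.frame(
          channel = paste0(substr(s, p - 1, p - 1), "[", ref, ">", alt, "]",
                           substr(s, p + 1, p + 1)),
          type = type,
          substitution = if (type == "missense") paste0(wt, ">", mut)
            else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

test_that("site catalogue matches hand-worked and brute-force expectations", {
  sites <- site_catalogue(c(x = "ATGCCATAA"))
  hit <- sites[sites$channel == "G[C>T]C" & sites$type == "missense", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$substitution, "P>S")
  expect_identical(hit$pos, 4L)

  none <- site_catalogue(c(x = "ATGAAATAA"))
  expect_identical(nrow(none[none$channel == "G[C>T]C", ]), 0L)

  cds <- simulate_cds(n_records = 1, length = 300, seed = 3)
  got <- site_catalogue(cds)
  want <- oracle_sites(cds)
  expect_identical(nrow(got), nrow(want))
  expect_identical(table(got$channel, got$type), table(want$channel, want$type))
  m_got <- sort(table(got$substitution[got$type == "missense"]))
  m_want <- sort(table(want$substitution[want$type == "missense"]))
  expect_identical(m_got, m_want)
})

test_that("a degenerate signature on a single-site CDS yields a point spectrum", {
  sig <- sbs_signature(setNames(1, "G[C>T]C"), name = "point")
  spec <- simulate_missense(sig, c(x = "ATGCCATAA"), n = 10, seed = 1)
  expect_identical(unname(spec$counts["P>S"]), 10L)
  expect_equal(unname(spec$fractions["P>S"]), 1)
  expect_true(all(spec$counts[names(spec$counts) != "P>S"] == 0L))
})

test_that("n = 0 gives an empty spectrum with undefined fractions", {
  sig <- simulate_sbs_signature(seed = 2)
  spec <- simulate_missense(sig, simulate_cds(2, 120, seed = 2), n = 0)
  expect_true(all(spec$counts == 0L))
  expect_true(all(is.na(spec$fractions)))
})

test_that("signatures with no eligible site raise a no-opportunity error", {
  # CDS whose only missense channels never include this context
  sig <- sbs_signature(setNames(1, "G[C>T]C"), name = "point")
  expect_error(simulate_missense(sig, c(x = "ATGAAATAA"), n = 5),
               "no opportunity")
})

test_that("simulated spectra converge to the exact site-weighted expectation", {
  cds <- simulate_cds(n_records = 5, length = 900, seed = 13)
  sig <- simulate_sbs_signature(sparsity = 0.2, seed = 13)
  exact <- expected_spectrum(sig, cds)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  tv_small <- tv_distance(simulate_missense(sig, cds, n = 2000,
                                            seed = 4)$fractions, exact)
  tv_large <- tv_distance(simulate_missense(sig, cds, n = 50000,
                                            seed = 4)$fractions, exact)
  expect_lt(tv_large, tv_small)
  expect_lt(tv_large, 0.02)
})

test_that("simulation never emits synonymous or nonsense outcomes", {
  cds <- simulate_cds(3, 600, seed = 8)
  sites <- site_catalogue(cds)
  sig <- simulate_sbs_signature(sparsity = 0.5, seed = 8)
  spec <- simulate_missense(sig, cds, n = 5000, seed = 8)
  # every emitted substitution is a missense outcome present in the catalogue
  emitted <- names(spec$counts)[spec$counts > 0]
  expect_true(all(emitted %in%
                    sites$substitution[sites$type == "missense"]))
})

test_that("channel opportunity counts map through reverse complement", {
  cds <- simulate_cds(2, 300, seed = 17)
  rc <- vapply(cds, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  tab_fwd <- table(site_catalogue(cds)$channel)
  tab_rc <- table(site_catalogue(rc)$channel)
  shared <- names(tab_fwd)
  expect_identical(as.vector(tab_fwd[shared]),
                   as.vector(tab_rc[revcomp_channel(shared)]))
})

test_that("stranded signatures weight template- and coding-strand sites separately", {
  # untranscribed-only mass hits coding-strand pyrimidine sites only
  sigU <- sbs_signature(setNames(1, "U:G[C>T]C"), stranded = TRUE)
  specU <- simulate_missense(sigU, c(x = "ATGCCATAA"), n = 5, seed = 1)
  expect_identical(unname(specU$counts["P>S"]), 5L)
  # transcribed mass for the same channel applies to coding-strand purine
  # sites (G[G>A]C on the coding strand); none exist here
  sigT <- sbs_signature(setNames(1, "T:G[C>T]C"), stranded = TRUE)
  expect_error(simulate_missense(sigT, c(x = "ATGCCATAA"), n = 5),
               "no opportunity")
})

test_that("spectrum cosines flag associations above the 0.7 cutoff", {
  fit <- fx_model()
  spec <- fit$coefficients[1, ]
  cs <- spectrum_cosine(spec, fit)
  expect_equal(cs$cosine[1], 1, tolerance = 1e-12)
  expect_true(cs$associated[1])
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("motif information content spans the degenerate extremes", {
  # toy model: P>S loads only on AAS1; the L>P column is uniform across the
  # five signatures (rows already sum to 1, padded by R>H)
  alpha <- c("P>S", "L>P", "R>H")
  H <- rbind(AAS1 = c(0.6, 0.2, 0.2), AAS2 = c(0, 0.2, 0.8),
             AAS3 = c(0, 0.2, 0.8), AAS4 = c(0, 0.2, 0.8),
             AAS5 = c(0, 0.2, 0.8))
  colnames(H) <- alpha
  model <- toy_model(H)
  # ATGCCATAA: G[C>T]C -> P>S only; ATGCTGTAA: C[T>C]G at pos 5 -> L>P
  motif <- context_aas_motif(model, c(a = "ATGCCATAA", b = "ATGCTGTAA"),
                             exact = TRUE)
  expect_equal(unname(motif$ic["G[C>T]C"]), log2(5), tolerance = 1e-9)
  expect_equal(unname(motif$fractions["G[C>T]C", "AAS1"]), 1)
  expect_equal(unname(motif$ic["C[T>C]G"]), 0, tolerance = 1e-9)
  expect_true(all(motif$ic >= -1e-12 & motif$ic <= log2(5) + 1e-12,
                  na.rm = TRUE))
  expect_true(length(motif$absent) > 0)
})

test_that("sampled motif fractions approach the analytic mixture", {
  fit <- fx_model()
  cds <- simulate_cds(4, 600, seed = 19)
  exact <- context_aas_motif(fit, cds, exact = TRUE)
  mc <- context_aas_motif(fit, cds, n_per_profile = 5000, seed = 19)
  present <- setdiff(rownames(exact$fractions),
                     union(exact$absent, mc$absent))
  tv <- vapply(present, function(pr)
    tv_distance(exact$fractions[pr, ], mc$fractions[pr, ]), numeric(1))
  expect_lt(max(tv), 0.06)
  rs <- rowSums(mc$fractions[present, ])
  expect_equal(unname(rs), rep(1, length(present)), tolerance = 1e-9)
})

test_that("COSMIC-format signature tables round-trip", {
  sigs <- list(S1 = simulate_sbs_signature(seed = 1, name = "S1"),
               S2 = simulate_sbs_signature(seed = 2, name = "S2"))
  path <- tempfile(fileext = ".tsv")
  write_sbs_signatures(sigs, path)
  back <- read_sbs_signatures(path)
  expect_equal(back$S1$probs, sigs$S1$probs, tolerance = 1e-9)
  expect_equal(back$S2$probs, sigs$S2$probs, tolerance = 1e-9)
  # stranded dialect
  st <- list(T1 = simulate_sbs_signature(seed = 3, stranded = TRUE,
                                         name = "T1"))
  path2 <- tempfile(fileext = ".tsv")
  write_sbs_signatures(st, path2)
  back2 <- read_sbs_signatures(path2)
  expect_true(back2$T1$stranded)
  expect_equal(back2$T1$probs, st$T1$probs, tolerance = 1e-9)
})
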