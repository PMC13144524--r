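# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# mid-sized cohort with planted ground truth (fixed mutations per sample)
fx_cohort <- function() fx_cache("cohort", {
  simulate_cohort(ground_truth_profiles(), n_samples = 150, seed = 42,
                  mutations = 300)
})

# rank-5 fit of fx_cohort
fx_model <- function() fx_cache("model", {
  aas_nmf(fx_cohort(), rank = 5, nrun = 5, seed = 42)
})

# study-scale cohort: 600 samples, 200 mutations each, root seed 1
fx_acc_cohort <- function() fx_cache("acc_cohort", {
  simulate_cohort(ground_truth_profiles(), n_samples = 600, seed = 1,
                  mutations = 200)
})

# hand-built tiny model on a 3-substitution alphabet for exact arithmetic
toy_model <- function(H = NULL) {
  if (is.null(H)) {
    H <- rbind(AAS1 = c(0.6, 0.4, 0.0),
               AAS2 = c(0.0, 0.5, 0.5))
    colnames(H) <- c("S>P", "L>P", "E>K")
  }
  W <- matrix(1 / nrow(H), 2, nrow(H),
              dimnames = list(c("s1", "s2"), rownames(H)))
  structure(list(coefficients = H, exposures = W, rank = nrow(H),
                 objective = 0, x = NULL, meta = list(nrun = 1, seed = 1)),
            class = "aas_model")
}

# independent genetic-code oracle for code-table tests (Biostrings, not the
# package's own table)
oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

tv_distance <- function(p, q) sum(abs(p - q)) / 2
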