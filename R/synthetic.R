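## Seeded generators for every input the pipeline consumes, with planted
## ground truth for recovery tests

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Packaged ground-truth signature profiles
#'
#' Five sparse, well-separated simplex profiles over the single-nucleotide
#' reachable substitution alphabet, emulating the qualitative structure of
#' the five cancer substitution signatures: profile 1 carries C>A-type
#' replacements (e.g. G>V, A>D), profile 2 C>T-type replacements led by
#' P>S and D>N, profile 3 is the arginine signature (R>H, R>C, R>Q, R>W),
#' profile 4 T>C-type replacements (I>V, L>P, ...), and profile 5 is led by
#' E>K and E>Q. Eighty percent of each profile's mass sits on its dominant
#' substitutions; the remainder is a fixed low-level filler spread over the
#' rest of the alphabet. Deterministic.
#'
#' @param concentration Dirichlet concentration of per-sample mixing weights
#'   (default 0.3: sparse mixtures, most samples near-pure).
#' @param mutations Mutations per sample: a single number for a fixed count,
#'   or a length-2 range sampled log-uniformly (default `c(10, 1000)`).
#' @return Object of class `aas_ground_truth` with elements `profiles`
#'   (5 x alphabet matrix, rows sum to 1), `concentration`, `mutations`.
#' @export
ground_truth_profiles <- function(concentration = 0.3,
                                  mutations = c(10, 1000)) {
  alphabet <- enumerate_reachable_substitutions()
  dominants <- list(
    AAS1 = c("G>V" = 0.22, "A>D" = 0.18, "P>T" = 0.14, "Q>K" = 0.10,
             "S>I" = 0.08, "R>L" = 0.08),
    AAS2 = c("P>S" = 0.25, "D>N" = 0.20, "G>E" = 0.15, "E>K" = 0.08,
             "S>F" = 0.07, "A>V" = 0.05),
    AAS3 = c("R>H" = 0.28, "R>C" = 0.20, "R>Q" = 0.18, "R>W" = 0.14),
    AAS4 = c("I>V" = 0.20, "L>P" = 0.16, "S>P" = 0.12, "I>T" = 0.12,
             "Y>H" = 0.10, "F>L" = 0.10),
    AAS5 = c("E>K" = 0.35, "E>Q" = 0.25, "A>G" = 0.10, "D>H" = 0.10))
  profiles <- matrix(0, 5, length(alphabet),
                     dimnames = list(names(dominants), alphabet))
  for (k in seq_along(dominants)) {
    dom <- dominants[[k]]
    stopifnot(all(names(dom) %in% alphabet))
    profiles[k, names(dom)] <- dom
    rest <- setdiff(alphabet, names(dom))
    filler <- .with_seed(920 + k, rgamma(length(rest), shape = 1))
    profiles[k, rest] <- (1 - sum(dom)) * filler / sum(filler)
  }
  structure(list(profiles = profiles, concentration = concentration,
                 mutations = mutations),
            class = "aas_ground_truth")
}

#' @export
print.aas_ground_truth <- function(x, ...) {
  cat("Ground-truth configuration:", nrow(x$profiles),
      "planted signature profiles over", ncol(x$profiles),
      "substitutions\n")
  cat("  Dirichlet concentration:", x$concentration,
      " mutations/sample:", paste(x$mutations, collapse = "-"), "\n")
  invisible(x)
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a cohort from planted signature profiles
#'
#' Each sample draws mixing weights from a symmetric Dirichlet over the
#' planted profiles and a substitution count vector from the multinomial of
#' the mixture profile.
#'
#' @param cfg An `aas_ground_truth` (e.g. [ground_truth_profiles()]).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @param mutations Override of the config's mutations-per-sample setting.
#' @return An `aas_cohort` with an extra element `truth` holding the true
#'   per-sample mixing weights and the planted profiles.
#' @export
simulate_cohort <- function(cfg, n_samples, seed = 1,
                            mutations = cfg$mutations) {
  stopifnot(inherits(cfg, "aas_ground_truth") ||
              (is.list(cfg) && !is.null(cfg$profiles)))
  P <- cfg$profiles
  k <- nrow(P)
  set.seed(seed)
  W <- .rdirichlet(n_samples, rep(cfg$concentration, k))
  nmut <- if (length(mutations) == 1) rep(mutations, n_samples)
          else round(exp(runif(n_samples, log(mutations[1]),
                               log(mutations[2]))))
  counts <- matrix(0L, n_samples, ncol(P),
                   dimnames = list(sprintf("S%04d", seq_len(n_samples)),
                                   colnames(P)))
  for (s in seq_len(n_samples)) {
    mix <- as.numeric(W[s, ] %*% P)
    counts[s, ] <- as.integer(rmultinom(1, nmut[s], mix))
  }
  fractions <- counts / rowSums(counts)
  rownames(W) <- rownames(counts)
  colnames(W) <- rownames(P)
  structure(list(fractions = fractions, counts = counts,
                 alphabet = colnames(P), sample_ids = rownames(counts),
                 min_mutations = 1,
                 truth = list(weights = W, profiles = P, seed = seed),
                 report = list()),
            class = "aas_cohort")
}

#' Simulate a sparse SBS signature
#'
#' Channel probabilities are drawn from a symmetric Dirichlet; small
#' `sparsity` concentrates the mass on few channels.
#'
#' @param sparsity Dirichlet concentration per channel (default 0.05).
#' @param seed Integer seed.
#' @param stranded If `TRUE`, a 192-channel stranded signature.
#' @param name Signature name.
#' @return An `sbs_signature`.
#' @export
simulate_sbs_signature <- function(sparsity = 0.05, seed = 1,
                                   stranded = FALSE, name = NULL) {
  if (sparsity <= 0) stop("`sparsity` must be positive")
  keys <- if (stranded) {
    c(paste0("T:", trinuc_channels("pyrimidine")),
      paste0("U:", trinuc_channels("pyrimidine")))
  } else trinuc_channels("pyrimidine")
  set.seed(seed)
  p <- rgamma(length(keys), shape = sparsity)
  if (sum(p) == 0) p[1] <- 1
  if (is.null(name)) name <- paste0("synthSBS", seed)
  sbs_signature(setNames(p / sum(p), keys), name = name, stranded = stranded)
}

#' Simulate an in-frame coding sequence set
#'
#' Each record starts with ATG, ends with a stop codon, and has interior
#' codons drawn from the sense codons with base composition biased by
#' `gc_fraction`.
#'
#' @param n_records Number of CDS records.
#' @param length Total record length in nucleotides (rounded up to a
#'   multiple of 3, minimum 9).
#' @param gc_fraction Target G+C fraction of interior codons.
#' @param seed Integer seed.
#' @return Named character vector of CDS strings.
#' @export
simulate_cds <- function(n_records = 10, length = 300, gc_fraction = 0.5,
                         seed = 1) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("`gc_fraction` must be in (0, 1)")
  length <- max(9, 3 * ceiling(length / 3))
  n_inner <- length / 3 - 2
  pbase <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  stops <- c("TAA", "TAG", "TGA")
  set.seed(seed)
  out <- vapply(seq_len(n_records), function(r) {
    inner <- character(n_inner)
    for (i in seq_len(n_inner)) {
      repeat {
        cod <- paste(sample(BASES, 3, replace = TRUE, prob = pbase),
                     collapse = "")
        if (!cod %in% stops) break
      }
      inner[i] <- cod
    }
    paste0("ATG", paste(inner, collapse = ""), sample(stops, 1))
  }, character(1))
  setNames(out, sprintf("synthCDS%03d", seq_len(n_records)))
}

#' Simulate an anchor-motif immunopeptidome
#'
#' Peptides have uniform random residues except at anchor positions, which
#' carry the anchor residue with probability `purity`.
#'
#' @param anchor Named character vector: names are positions, values are
#'   residues, e.g. `c("2" = "P")`.
#' @param n Number of peptides.
#' @param lengths Peptide lengths to draw from (uniformly).
#' @param purity Probability that an anchor position carries its residue.
#' @param seed Integer seed.
#' @return Character vector of peptides.
#' @export
simulate_peptidome <- function(anchor = c("2" = "P"), n = 500, lengths = 9,
                               purity = 1, seed = 1) {
  if (purity < 0 || purity > 1) stop("`purity` must be in [0, 1]")
  pos <- as.integer(names(anchor))
  if (any(is.na(pos)) || any(pos < 1))
    stop("anchor names must be positive integer positions")
  if (any(!anchor %in% AA20)) stop("anchor residues must be standard")
  set.seed(seed)
  L <- sample(rep(lengths, length.out = max(2, length(lengths))), n,
              replace = TRUE)
  vapply(seq_len(n), function(i) {
    aa <- sample(AA20, L[i], replace = TRUE)
    for (j in seq_along(pos)) {
      if (pos[j] <= L[i] && runif(1) <= purity) aa[pos[j]] <- anchor[[j]]
    }
    paste(aa, collapse = "")
  }, character(1))
}

#' Simulate a substitution-detection dataset
#'
#' Generates a cohort of samples as Dirichlet mixtures of the model's
#' signature profiles, computes each sample's weighted-sum association
#' strength A_{s,i}, and draws per-substitution detection flags with
#' probability `plogis(intercept + slope * A)`. With `slope = 0` detection
#' is independent of the association strength (the null); the default
#' strong slope produces clearly detectable enrichment.
#'
#' @param model An `aas_model` (its coefficient rows are the mixing
#'   profiles).
#' @param n_samples Number of samples (default 17).
#' @param slope Logistic slope on the A scale (default 25).
#' @param intercept Logistic intercept (default -3).
#' @param mutations Mutations per sample (default 200).
#' @param concentration Dirichlet concentration (default 0.3).
#' @param seed Integer seed.
#' @return List with matrices `fractions`, `detected` (logical) and `A`
#'   (association strengths), samples x substitutions.
#' @export
simulate_detection <- function(model, n_samples = 17, slope = 25,
                               intercept = -3, mutations = 200,
                               concentration = 0.3, seed = 1) {
  cfg <- structure(list(profiles = model$coefficients,
                        concentration = concentration,
                        mutations = mutations),
                   class = "aas_ground_truth")
  cohort <- simulate_cohort(cfg, n_samples, seed = seed)
  fr <- cohort$fractions
  A <- matrix(NA_real_, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  for (s in seq_len(nrow(fr))) {
    cs <- sample_similarity(fr[s, ], model)
    A[s, ] <- weighted_association(cs, model)[colnames(fr)]
  }
  set.seed(seed + 1L)
  p <- stats::plogis(intercept + slope * A)
  det <- matrix(rbinom(length(p), 1, p) == 1, nrow(p), ncol(p),
                dimnames = dimnames(p))
  list(fractions = fr, detected = det, A = A,
       meta = list(slope = slope, intercept = intercept, seed = seed))
}

#' Simulate a CFSE generation histogram
#'
#' Each founder's clone divides synchronously: in each generation the clone
#' divides with probability `division_prob`, up to `max_gen` rounds; a clone
#' stopping after g rounds contributes `2^g` cells to generation g.
#'
#' @param founders Number of founder cells.
#' @param division_prob Per-round division probability.
#' @param max_gen Maximum resolvable generation.
#' @param seed Integer seed.
#' @return Integer vector of cell counts for generations `0..max_gen`.
#' @export
simulate_cfse <- function(founders = 1000, division_prob = 0.5, max_gen = 6,
                          seed = 1) {
  if (division_prob < 0 || division_prob > 1)
    stop("`division_prob` must be in [0, 1]")
  set.seed(seed)
  g <- if (division_prob == 1) {
    rep(max_gen, founders)
  } else {
    # rounds of successful division before the first failure, capped
    pmin(stats::rgeom(founders, prob = 1 - division_prob), max_gen)
  }
  counts <- integer(max_gen + 1)
  for (i in 0:max_gen) counts[i + 1] <- as.integer(sum(g == i) * 2^i)
  counts
}
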