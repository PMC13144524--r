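## Amino acid substitution signature extraction by KL-NMF

.as_fraction_matrix <- function(x) {
  if (inherits(x, "aas_cohort")) return(x$fractions)
  if (is.matrix(x)) {
    if (is.null(colnames(x)))
      stop("fraction matrix must have substitution column names")
    return(x)
  }
  stop("`x` must be an `aas_cohort` or a samples x substitutions matrix")
}

.one_nmf_run <- function(V, rank, seed, max_iter, tol) {
  set.seed(seed)
  n <- nrow(V); m <- ncol(V)
  scale0 <- sqrt(mean(V) / rank)
  W0 <- matrix(runif(n * rank, min = .Machine$double.eps, max = 1), n, rank) * scale0
  H0 <- matrix(runif(rank * m, min = .Machine$double.eps, max = 1), rank, m) * scale0
  nmf_kl_update(V, W0, H0, as.integer(max_iter), tol)
}

# draw one RNG substream seed per restart, reproducibly from the root seed
.restart_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Fit an amino acid substitution signature model by NMF
#'
#' Factorises the samples x substitutions fraction matrix `V` as `W H` with
#' `rank` non-negative signatures, minimising the generalised
#' Kullback-Leibler divergence by multiplicative updates. The best fit over
#' `nrun` random restarts is returned. Coefficient rows (signature profiles)
#' are L1-normalised to sum to one, with the scale pushed into the exposures,
#' so that for a fraction matrix the per-sample exposures sum to
#' approximately one and the 0.6 dominance threshold is interpretable.
#' Signatures are reported in decreasing order of total exposure.
#'
#' @param x An `aas_cohort` from [build_cohort()], or a non-negative
#'   samples x substitutions matrix with column names.
#' @param rank Number of signatures (k >= 1; k = 1 permitted for degenerate
#'   checks, the survey starts at 2).
#' @param nrun Random restarts; the best-objective fit is kept (default 30).
#' @param seed Integer seed controlling all restarts.
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   objective-change tolerance.
#' @return An object of class `aas_model` with elements `coefficients`
#'   (rank x substitutions, rows sum to 1), `exposures`
#'   (samples x rank), `rank`, `objective`, `meta` and the training matrix
#'   `x`.
#' @examples
#' cfg <- ground_truth_profiles()
#' cohort <- simulate_cohort(cfg, n_samples = 40, mutations = 200, seed = 1)
#' fit <- aas_nmf(cohort, rank = 5, nrun = 5, seed = 1)
#' fit
#' @export
aas_nmf <- function(x, rank, nrun = 30, seed = 1,
                    max_iter = 2000, tol = 1e-5) {
  V <- .as_fraction_matrix(x)
  if (any(V < 0)) stop("input matrix must be non-negative")
  if (rank < 1) stop("`rank` must be >= 1")
  if (rank >= min(dim(V)))
    stop("rank error: `rank` must be smaller than min(n_samples, alphabet size)")
  if (nrun < 1) stop("`nrun` must be >= 1")
  rank <- as.integer(rank)
  seeds <- .restart_seeds(seed, nrun)
  best <- NULL
  for (s in seeds) {
    fit <- .one_nmf_run(V, rank, s, max_iter, tol)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  W <- best$W
  H <- best$H
  # push coefficient-row scale into exposures
  rs <- rowSums(H)
  H <- H / rs
  W <- sweep(W, 2, rs, "*")
  # order signatures by decreasing total exposure
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  labels <- paste0("AAS", seq_len(rank))
  dimnames(H) <- list(labels, colnames(V))
  dimnames(W) <- list(rownames(V), labels)
  structure(list(coefficients = H,
                 exposures = W,
                 rank = rank,
                 objective = best$objective,
                 x = V,
                 meta = list(seed = seed, nrun = nrun,
                             iterations = best$iterations,
                             max_iter = max_iter, tol = tol,
                             objective = "KL divergence")),
            class = "aas_model")
}

#' @export
print.aas_model <- function(x, ...) {
  cat("Amino acid substitution signature model (KL-NMF)\n")
  cat("  rank:      ", x$rank, "\n")
  cat("  samples:   ", nrow(x$exposures), "\n")
  cat("  alphabet:  ", ncol(x$coefficients), "substitutions\n")
  cat("  objective: ", format(x$objective, digits = 6),
      "(best of", x$meta$nrun, "restarts)\n")
  invisible(x)
}

#' @export
summary.aas_model <- function(object, threshold = 0.6, top = 5, ...) {
  dom <- classify_dominance(object, threshold = threshold)
  tops <- apply(object$coefficients, 1, function(r)
    paste(names(sort(r, decreasing = TRUE))[seq_len(top)], collapse = " "))
  out <- list(rank = object$rank,
              top_substitutions = tops,
              dominance = table(dom$label),
              objective = object$objective)
  class(out) <- "summary.aas_model"
  out
}

#' @export
print.summary.aas_model <- function(x, ...) {
  cat("AAS model, rank", x$rank, "\n\nTop substitutions per signature:\n")
  for (k in names(x$top_substitutions))
    cat(" ", k, ":", x$top_substitutions[[k]], "\n")
  cat("\nSample dominance (exposure > threshold):\n")
  print(x$dominance)
  invisible(x)
}

#' @export
coef.aas_model <- function(object, ...) object$coefficients

#' @export
fitted.aas_model <- function(object, ...)
  object$exposures %*% object$coefficients

#' @export
residuals.aas_model <- function(object, ...) object$x - fitted(object)

#' Project new samples onto a fitted signature model
#'
#' @param object An `aas_model`.
#' @param newdata Samples x substitutions fraction matrix (or a single named
#'   vector) on the model's alphabet.
#' @param type `"prevalence"` gives the Pearson correlation between each
#'   sample's substitution fractions and each signature's coefficient row
#'   (the prevalence measure used for external cohorts); `"cosine"` gives
#'   the cosine similarity c_{s,k}.
#' @param ... Unused.
#' @return Samples x signatures matrix of correlations or cosines.
#' @export
predict.aas_model <- function(object, newdata,
                              type = c("prevalence", "cosine"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- rbind(sample1 = newdata)
  newdata <- .align_alphabet(newdata, object)
  if (type == "prevalence") {
    t(apply(newdata, 1, pearson_prevalence, model = object))
  } else {
    t(apply(newdata, 1, sample_similarity, model = object))
  }
}

#' @export
plot.aas_model <- function(x, n_top = 15, ...) {
  op <- graphics::par(mfrow = c(x$rank, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(x$rank)) {
    r <- sort(x$coefficients[k, ], decreasing = TRUE)[seq_len(n_top)]
    graphics::barplot(r, las = 2, ylab = "coefficient",
                      main = rownames(x$coefficients)[k], ...)
  }
  invisible(x)
}

#' Simulate cohorts from a fitted model
#'
#' Draws new synthetic cohorts whose samples are Dirichlet mixtures of the
#' fitted signature profiles (the same generative scheme as
#' [simulate_cohort()]).
#'
#' @param object An `aas_model`.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param n_samples,mutations,concentration Passed to the cohort generator.
#' @param ... Unused.
#' @return A list of `aas_cohort` objects (length `nsim`).
#' @export
simulate.aas_model <- function(object, nsim = 1, seed = 1, n_samples = 100,
                               mutations = 200, concentration = 0.3, ...) {
  cfg <- list(profiles = object$coefficients,
              concentration = concentration,
              mutations = mutations)
  class(cfg) <- "aas_ground_truth"
  lapply(seq_len(nsim), function(i)
    simulate_cohort(cfg, n_samples = n_samples, mutations = mutations,
                    seed = seed + i - 1L))
}

.align_alphabet <- function(v, model) {
  alpha <- colnames(model$coefficients)
  if (is.null(dim(v))) {
    if (is.null(names(v))) {
      if (length(v) != length(alpha))
        stop("unnamed vector length does not match the model alphabet")
      names(v) <- alpha
    }
    missing <- setdiff(alpha, names(v))
    out <- setNames(numeric(length(alpha)), alpha)
    out[intersect(names(v), alpha)] <- v[intersect(names(v), alpha)]
    if (length(missing) == length(alpha)) stop("no shared substitutions")
    out
  } else {
    out <- matrix(0, nrow(v), length(alpha),
                  dimnames = list(rownames(v), alpha))
    shared <- intersect(colnames(v), alpha)
    if (!length(shared)) stop("no shared substitutions")
    out[, shared] <- v[, shared]
    out
  }
}

#' Pearson-correlation prevalence of each signature in a sample
#'
#' The prevalence measure for samples outside the training cohort: the
#' Pearson correlation between the sample's substitution fractions and each
#' signature's coefficient row.
#'
#' @param fractions Named numeric vector of substitution fractions.
#' @param model An `aas_model`.
#' @return Numeric vector of length `rank`.
#' @export
pearson_prevalence <- function(fractions, model) {
  v <- .align_alphabet(fractions, model)
  if (sd(v) == 0)
    stop("undefined correlation: sample vector has zero variance")
  apply(model$coefficients, 1, function(r) cor(v, r))
}

#' Classify samples as signature-dominated or mixed
#'
#' A sample is dominated by the signature whose exposure exceeds
#' `threshold`; when several exceed it the highest value wins; samples with
#' no exposure above the threshold are `"mixed"`.
#'
#' @param model An `aas_model` (or an exposures matrix).
#' @param threshold Dominance threshold in (0, 1), default 0.6.
#' @return data.frame with columns `sample_id`, `label` plus the exposure
#'   matrix as attribute `exposures`.
#' @export
classify_dominance <- function(model, threshold = 0.6) {
  if (inherits(model, "aas_model")) W <- model$exposures
  else W <- model
  if (threshold <= 0 || threshold >= 1)
    stop("parameter error: `threshold` must lie in (0, 1)")
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("AAS", seq_len(ncol(W)))
  lab <- apply(W, 1, function(e) {
    if (any(e > threshold)) labels[which.max(e)] else "mixed"
  })
  out <- data.frame(sample_id = rownames(W), label = unname(lab),
                    stringsAsFactors = FALSE)
  attr(out, "exposures") <- W
  out
}

## ---- cosine utilities and model comparison -----------------------------

#' Cosine similarity between two non-negative vectors
#' @param a,b Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]` (`[0, 1]` for non-negative input).
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined cosine: zero vector")
  sum(a * b) / (na * nb)
}

# exact maximum-weight bipartite assignment by bitmask dynamic programming
.assign_max <- function(S) {
  k <- nrow(S)
  if (k != ncol(S)) stop("similarity matrix must be square")
  if (k > 20) stop("assignment supported up to k = 20")
  nmask <- bitwShiftL(1L, k)
  best <- rep(-Inf, nmask); best[1] <- 0
  pick <- integer(nmask)
  pop <- integer(nmask)
  for (m in 1:(nmask - 1)) pop[m + 1L] <- pop[bitwShiftR(m, 1) + 1L] + (m %% 2L)
  for (m in 1:(nmask - 1)) {
    i <- pop[m + 1L]            # row being assigned (1-based)
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0L) next
      cand <- best[bitwXor(m, bit) + 1L] + S[i, j]
      if (cand > best[m + 1L]) { best[m + 1L] <- cand; pick[m + 1L] <- j }
    }
  }
  perm <- integer(k)
  m <- nmask - 1L
  for (i in k:1) {
    j <- pick[m + 1L]
    perm[i] <- j
    m <- bitwXor(m, bitwShiftL(1L, j - 1L))
  }
  list(permutation = perm, total = best[nmask])
}

#' Match signatures between two models and report per-signature cosines
#'
#' Aligns the signatures of two models of equal rank on the same alphabet by
#' maximum-weight bipartite matching on pairwise cosine similarity of
#' coefficient rows (used e.g. to check robustness of the factorisation
#' across minimum-mutation cutoffs).
#'
#' @param model_a,model_b `aas_model` objects (or coefficient matrices) of
#'   the same rank and alphabet.
#' @return data.frame with columns `signature_a`, `signature_b`, `cosine`,
#'   in the signature order of `model_a`.
#' @export
robustness_compare <- function(model_a, model_b) {
  A <- if (inherits(model_a, "aas_model")) model_a$coefficients else model_a
  B <- if (inherits(model_b, "aas_model")) model_b$coefficients else model_b
  if (nrow(A) != nrow(B))
    stop("comparison error: models have different ranks")
  if (!identical(colnames(A), colnames(B)))
    stop("comparison error: models are on different alphabets")
  S <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      S[i, j] <- cosine_similarity(A[i, ], B[j, ])
  m <- .assign_max(S)
  data.frame(signature_a = rownames(A),
             signature_b = rownames(B)[m$permutation],
             cosine = S[cbind(seq_len(nrow(A)), m$permutation)],
             stringsAsFactors = FALSE)
}
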