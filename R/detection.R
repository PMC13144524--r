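## Sample-level association statistics and ROC validation of substitution
## detection in immunopeptidomes

#' Cosine similarity of a sample to each signature (c_{s,k})
#'
#' @param fractions Named substitution-fraction vector for one sample.
#' @param model An `aas_model`.
#' @return Numeric vector of cosines, one per signature.
#' @export
sample_similarity <- function(fractions, model) {
  v <- .align_alphabet(fractions, model)
  apply(model$coefficients, 1, cosine_similarity, a = v)
}

#' Weighted-sum association strength A_{s,i}
#'
#' For a sample with signature similarities `c` and coefficient matrix `a`,
#' the association strength of each substitution i is
#' `A_{s,i} = sum_k c_k a_{i,k}`.
#'
#' @param c Numeric vector of per-signature similarities (c_{s,k}).
#' @param model An `aas_model` (or a rank x substitutions coefficient
#'   matrix).
#' @return Named numeric vector over the model's alphabet.
#' @export
weighted_association <- function(c, model) {
  H <- if (inherits(model, "aas_model")) model$coefficients else model
  if (length(c) != nrow(H))
    stop("length of `c` must equal the number of signatures")
  setNames(as.numeric(c %*% H), colnames(H))
}

#' Area under the ROC curve by the Mann-Whitney rank statistic
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — the exact
#' Mann-Whitney formulation rather than trapezoidal integration.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("undefined AUC: both classes must be present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Detection AUC of the weighted association strength
#'
#' Given a detection dataset (per sample: substitution fractions and a
#' detected flag per substitution), computes each sample's c_{s,k}, the
#' association strengths A_{s,i}, and the ROC AUC of A against detection,
#' pooled across samples (default) or per sample.
#'
#' @param dataset A detection dataset: list with `fractions`
#'   (samples x substitutions matrix) and `detected` (samples x
#'   substitutions logical matrix), e.g. from [simulate_detection()].
#' @param model An `aas_model`.
#' @param pooled If `TRUE` (default) one AUC over all (sample, substitution)
#'   pairs; otherwise a per-sample vector.
#' @param restrict_to_mutated If `TRUE`, only substitutions actually present
#'   in a sample's mutation set enter as observations; the default includes
#'   every alphabet member for every sample.
#' @return Scalar AUC, or named per-sample vector.
#' @export
detection_auc <- function(dataset, model, pooled = TRUE,
                          restrict_to_mutated = FALSE) {
  fr <- dataset$fractions
  det <- dataset$detected
  stopifnot(identical(dim(fr), dim(det)))
  A <- matrix(NA_real_, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  for (s in seq_len(nrow(fr))) {
    cs <- sample_similarity(fr[s, ], model)
    A[s, ] <- weighted_association(cs, model)[colnames(fr)]
  }
  keep <- if (restrict_to_mutated) fr > 0 else matrix(TRUE, nrow(fr), ncol(fr))
  if (pooled) {
    roc_auc(A[keep], det[keep])
  } else {
    vapply(seq_len(nrow(fr)), function(s)
      roc_auc(A[s, keep[s, ]], det[s, keep[s, ]]), numeric(1)) |>
      setNames(rownames(fr))
  }
}
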