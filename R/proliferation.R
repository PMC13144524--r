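## CFSE dye-dilution division index

#' Division index of a CFSE generation histogram
#'
#' Given cell counts `N_i` per division generation `i = 0..g`, the division
#' index is `sum(i * N_i / 2^i) / sum(N_i / 2^i)` — the mean number of
#' divisions per founder cell, since `N_i / 2^i` estimates the number of
#' founders that ended in generation i.
#'
#' @param counts Numeric vector of non-negative generation counts; element 1
#'   is generation 0 (undivided cells).
#' @return Division index (>= 0, at most the highest generation).
#' @examples
#' division_index(c(2, 2, 4))  # 0.75
#' division_index(c(0, 4))     # 1
#' @export
division_index <- function(counts) {
  if (any(counts < 0)) stop("generation counts must be non-negative")
  if (all(counts == 0)) stop("all-zero generation histogram")
  i <- seq_along(counts) - 1
  founders <- counts / 2^i
  sum(i * founders) / sum(founders)
}

#' Z-transform division indices within replicate groups
#'
#' Standardises values to mean 0 and sample (n-1) standard deviation 1
#' within each replicate, making indices comparable across replicates.
#'
#' @param values Numeric vector of division indices.
#' @param replicate Grouping vector of the same length.
#' @return Numeric vector of Z-scores in the input order.
#' @export
zscore_by_replicate <- function(values, replicate) {
  if (length(values) != length(replicate)) stop("length mismatch")
  out <- numeric(length(values))
  for (g in unique(replicate)) {
    idx <- replicate == g
    if (sum(idx) < 2)
      stop("replicate group ", g, " has fewer than 2 values")
    s <- sd(values[idx])
    if (s == 0) stop("zero variance within replicate group ", g)
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}
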