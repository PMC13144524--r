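## Consensus-based rank selection for the signature factorisation

# connectivity matrix of a hard clustering (argmax exposure per sample)
.connectivity <- function(cl) {
  outer(cl, cl, "==") * 1
}

.dispersion <- function(C) mean(4 * (C - 0.5)^2)

#' Survey factorisation ranks with consensus clustering
#'
#' For each candidate rank, runs `nrun` randomly-restarted KL-NMF fits,
#' clusters samples by their maximal exposure in each run, and averages the
#' run connectivity matrices into a consensus matrix. Reported per rank:
#' the cophenetic correlation of average-linkage clustering of
#' `1 - consensus`, the mean silhouette width of the k-cluster consensus
#' partition, the dispersion of the consensus matrix, and the residual sum
#' of squares and explained variance of the best-objective fit. The selected
#' rank maximises the mean of cophenetic correlation and mean silhouette
#' width, with ties broken toward the smaller rank.
#'
#' @param x An `aas_cohort` or fraction matrix.
#' @param ranks Integer vector of candidate ranks (default `2:10`).
#' @param nrun Runs per rank (default 30; must be >= 2).
#' @param seed Integer root seed.
#' @param max_iter,tol Passed to the NMF updates.
#' @return An object of class `aas_rank_survey`: data.frame `metrics` (one
#'   row per rank), `selected_rank`, and the per-rank consensus matrices.
#' @export
aas_rank_survey <- function(x, ranks = 2:10, nrun = 30, seed = 1,
                            max_iter = 2000, tol = 1e-5) {
  V <- .as_fraction_matrix(x)
  ranks <- sort(unique(as.integer(ranks)))
  if (any(ranks < 2)) stop("ranks must be >= 2")
  if (any(ranks >= min(dim(V)))) stop("rank error: rank exceeds matrix bounds")
  if (nrun < 2) stop("insufficient runs: `nrun` must be >= 2")
  metrics <- data.frame(rank = ranks, cophenetic = NA_real_,
                        silhouette = NA_real_, dispersion = NA_real_,
                        rss = NA_real_, explained_variance = NA_real_)
  consensus <- list()
  tss <- sum(V^2)
  for (ri in seq_along(ranks)) {
    k <- ranks[ri]
    seeds <- .restart_seeds(seed + k, nrun)
    Cacc <- matrix(0, nrow(V), nrow(V))
    best <- NULL
    for (s in seeds) {
      fit <- .one_nmf_run(V, k, s, max_iter, tol)
      cl <- max.col(fit$W, ties.method = "first")
      Cacc <- Cacc + .connectivity(cl)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    C <- Cacc / nrun
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    coph <- suppressWarnings(cor(d, cophenetic(hc)))
    if (is.na(coph)) coph <- 1  # zero-spread distances: perfectly reproducible
    cl_cons <- cutree(hc, k = k)
    sil <- if (length(unique(cl_cons)) > 1) {
      mean(cluster::silhouette(cl_cons, d)[, "sil_width"])
    } else NA_real_
    rss <- sum((V - best$W %*% best$H)^2)
    metrics$cophenetic[ri] <- coph
    metrics$silhouette[ri] <- sil
    metrics$dispersion[ri] <- .dispersion(C)
    metrics$rss[ri] <- rss
    metrics$explained_variance[ri] <- 1 - rss / tss
    consensus[[as.character(k)]] <- C
  }
  score <- rowMeans(cbind(metrics$cophenetic, metrics$silhouette),
                    na.rm = TRUE)
  sel <- ranks[which.max(score)]  # which.max takes the first: smaller rank wins ties
  structure(list(metrics = metrics, selected_rank = sel,
                 consensus = consensus,
                 meta = list(nrun = nrun, seed = seed)),
            class = "aas_rank_survey")
}

#' @export
print.aas_rank_survey <- function(x, ...) {
  cat("NMF rank survey (", x$meta$nrun, "runs per rank )\n")
  print(x$metrics, digits = 4, row.names = FALSE)
  cat("selected rank:", x$selected_rank, "\n")
  invisible(x)
}

#' @export
plot.aas_rank_survey <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(m$rank, cbind(m$cophenetic, m$silhouette, m$dispersion),
                    type = "b", pch = 1:3, lty = 1, xlab = "rank",
                    ylab = "metric", ...)
  graphics::legend("bottomleft", c("cophenetic", "silhouette", "dispersion"),
                   pch = 1:3, col = 1:3, bty = "n")
  graphics::abline(v = x$selected_rank, lty = 2)
  graphics::plot(m$rank, m$rss, type = "b", xlab = "rank", ylab = "RSS", ...)
  invisible(x)
}

#' Write a rank survey as TSV
#' @param survey An `aas_rank_survey`.
#' @param path Output path.
#' @export
write_rank_survey <- function(survey, path) {
  df <- survey$metrics
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 10) else col)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
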