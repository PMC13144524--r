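## Physicochemical impact of amino acid substitutions

#' Per-substitution property changes
#'
#' For every directed substitution `X>Y`, the change in hydrophobicity and
#' charge is `prop(Y) - prop(X)`, so `delta(X>Y) = -delta(Y>X)`.
#'
#' @param scale A scale from [physchem_scale()].
#' @param alphabet Substitution alphabet.
#' @return data.frame with rownames = substitutions and columns
#'   `delta_hydrophobicity`, `delta_charge`; the `scale_id` attribute is
#'   carried through.
#' @export
delta_table <- function(scale = physchem_scale(),
                        alphabet = enumerate_reachable_substitutions()) {
  p <- parse_substitution(alphabet)
  missing <- setdiff(unique(c(p$wt, p$mut)), rownames(scale))
  if (length(missing))
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  out <- data.frame(
    delta_hydrophobicity = scale[p$mut, "hydrophobicity"] -
      scale[p$wt, "hydrophobicity"],
    delta_charge = scale[p$mut, "charge"] - scale[p$wt, "charge"],
    row.names = alphabet)
  attr(out, "scale_id") <- attr(scale, "scale_id")
  out
}

#' Expected property change of a sample's substitution spectrum
#'
#' The fraction-weighted mean of per-substitution deltas — equal to the mean
#' change over the sample's observed mutations.
#'
#' @param fractions Named substitution-fraction vector (or samples x
#'   substitutions matrix).
#' @param table A [delta_table()].
#' @return Named vector `(delta_hydrophobicity, delta_charge)`, or a
#'   two-column matrix for matrix input.
#' @export
sample_expected_delta <- function(fractions, table = delta_table()) {
  if (is.matrix(fractions)) {
    out <- t(apply(fractions, 1, sample_expected_delta, table = table))
    colnames(out) <- c("delta_hydrophobicity", "delta_charge")
    return(out)
  }
  if (!length(fractions) || all(fractions == 0))
    stop("empty substitution vector")
  shared <- intersect(names(fractions), rownames(table))
  if (!length(shared)) stop("no shared substitutions with the delta table")
  f <- fractions[shared]
  w <- f / sum(f)
  c(delta_hydrophobicity = sum(w * table[shared, "delta_hydrophobicity"]),
    delta_charge = sum(w * table[shared, "delta_charge"]))
}
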