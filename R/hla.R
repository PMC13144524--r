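## Entropy-weighted amino acid specificity of HLA class I alleles

#' Read per-allele peptide lists
#'
#' @param path TSV with columns `allele`, `peptide`.
#' @return Named list of character vectors (peptides per allele).
#' @export
read_peptides <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("allele", "peptide") %in% names(df)))
    stop("peptide table must have columns `allele` and `peptide`")
  split(df$peptide, df$allele)
}

#' Positional residue-frequency model of an allele's immunopeptidome
#'
#' Peptides of different lengths are analysed separately. An allele is
#' modelled only if it carries at least `min_peptides` peptides of length
#' 8-12 in total, and a length subset only if it has at least
#' `min_subset` peptides. Within a subset, the relative frequency of each
#' residue is computed at every position, the Shannon entropy per position,
#' and entropy-derived position weights `w_p` proportional to
#' `log2(20) - H_p` (normalised to sum to one; uniform fallback when every
#' position is maximally entropic).
#'
#' @param peptides Character vector of peptides (residues from the standard
#'   20-letter set, lengths 8-12 considered).
#' @param allele Allele name carried through to outputs.
#' @param min_peptides Minimum total peptides for the allele (default 400).
#' @param min_subset Minimum peptides per length subset (default 100).
#' @param pseudocount Additive pseudocount per residue and position
#'   (default 0 = raw relative frequencies).
#' @return Object of class `hla_positional_model`: per length subset, a
#'   positions x 20 frequency matrix, entropy and weight per position, and
#'   the subset size.
#' @export
positional_model <- function(peptides, allele = "HLA", min_peptides = 400,
                             min_subset = 100, pseudocount = 0) {
  peptides <- toupper(peptides)
  len <- nchar(peptides)
  valid <- len >= 8 & len <= 12 & !grepl(paste0("[^", paste(AA20, collapse = ""), "]"),
                                         peptides)
  peptides <- peptides[valid]
  if (length(peptides) < min_peptides)
    stop("insufficient data: allele ", allele, " has ", length(peptides),
         " usable peptides (< ", min_peptides, ")")
  subsets <- list()
  for (L in sort(unique(nchar(peptides)))) {
    pp <- peptides[nchar(peptides) == L]
    if (length(pp) < min_subset) next
    mat <- matrix(0, L, 20, dimnames = list(NULL, sort(AA20)))
    chars <- do.call(rbind, strsplit(pp, ""))
    for (p in seq_len(L)) {
      tab <- table(factor(chars[, p], levels = sort(AA20)))
      mat[p, ] <- (as.numeric(tab) + pseudocount) /
        (length(pp) + 20 * pseudocount)
    }
    ent <- apply(mat, 1, function(f) {
      f <- f[f > 0]; -sum(f * log2(f))
    })
    info <- log2(20) - ent
    w <- if (sum(info) > 0) info / sum(info) else rep(1 / L, L)
    subsets[[as.character(L)]] <- list(frequencies = mat, entropy = ent,
                                       weights = w, n = length(pp))
  }
  if (!length(subsets))
    stop("insufficient data: no length subset of allele ", allele,
         " has >= ", min_subset, " peptides")
  structure(list(allele = allele, subsets = subsets),
            class = "hla_positional_model")
}

#' @export
print.hla_positional_model <- function(x, ...) {
  cat("Positional model for", x$allele, "\n")
  for (L in names(x$subsets))
    cat("  length", L, ":", x$subsets[[L]]$n, "peptides\n")
  invisible(x)
}

#' Comprehensive amino acid specificity of an allele
#'
#' Per length subset, the specificity of residue `a` is the
#' entropy-weighted positional frequency `sum_p w_p f_p(a)`; the allele
#' value is the mean across subsets weighted by subset size. With weights
#' and frequencies each summing to one, the profile is a simplex vector.
#'
#' @param model An `hla_positional_model` (or a peptide vector, in which
#'   case a model is fitted first).
#' @param ... Passed to [positional_model()] when `model` is raw peptides.
#' @return Named numeric vector of 20 specificity values summing to 1, with
#'   attribute `allele`.
#' @export
allele_specificity <- function(model, ...) {
  if (!inherits(model, "hla_positional_model"))
    model <- positional_model(model, ...)
  vals <- vapply(model$subsets, function(sub) {
    as.numeric(sub$weights %*% sub$frequencies)
  }, numeric(20))
  sizes <- vapply(model$subsets, `[[`, numeric(1), "n")
  spec <- as.numeric(vals %*% (sizes / sum(sizes)))
  names(spec) <- sort(AA20)
  stopifnot(abs(sum(spec) - 1) < 1e-8)
  attr(spec, "allele") <- model$allele
  spec
}

#' Affinity of an allele for the mutated residues of a signature
#'
#' Aggregates the signature's coefficients by mutated residue
#' (`m_k(a) = sum of a_{i,k} over substitutions whose mutant residue is a`)
#' and dots the aggregate with the allele's specificity profile.
#'
#' @param profile Specificity vector from [allele_specificity()].
#' @param model An `aas_model`.
#' @param signature Signature index or name.
#' @return Scalar affinity score.
#' @export
aas_affinity <- function(profile, model, signature) {
  H <- model$coefficients
  if (is.character(signature)) signature <- match(signature, rownames(H))
  if (is.na(signature) || signature < 1 || signature > nrow(H))
    stop("index error: invalid signature index")
  mut <- parse_substitution(colnames(H))$mut
  m <- tapply(H[signature, ], factor(mut, levels = sort(AA20)), sum,
              default = 0)
  sum(as.numeric(m) * profile[sort(AA20)])
}

#' Patient-level signature affinity across an HLA genotype
#'
#' @param profiles List of up to six allele specificity profiles
#'   (homozygosity expressed by repeating an allele).
#' @param model An `aas_model`.
#' @param signature Signature index or name.
#' @return Arithmetic mean of [aas_affinity()] across the genotype.
#' @export
patient_affinity <- function(profiles, model, signature) {
  if (!length(profiles)) stop("empty genotype")
  if (length(profiles) > 6) stop("a class I genotype has at most 6 alleles")
  mean(vapply(profiles, aas_affinity, numeric(1),
              model = model, signature = signature))
}

#' Score a 9-mer against an allele's positional model
#'
#' The score is the mean over the nine positions of the entropy-weighted
#' positional specificity `w_p f_p(residue)` from the allele's 9-mer subset.
#'
#' @param peptide A 9-residue string.
#' @param model An `hla_positional_model` with a 9-mer subset.
#' @return Scalar score.
#' @export
score_9mer <- function(peptide, model) {
  if (nchar(peptide) != 9) stop("peptide must be a 9-mer")
  sub <- model$subsets[["9"]]
  if (is.null(sub)) stop("model has no 9-mer subset")
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (any(!aa %in% AA20)) stop("non-standard residue in peptide")
  mean(sub$weights * sub$frequencies[cbind(1:9, match(aa, sort(AA20)))])
}

#' Best allele score of a 9-mer across a genotype
#'
#' @param peptide A 9-residue string.
#' @param models Named list of `hla_positional_model`s (the genotype).
#' @return List with `allele` (name of the maximising model) and `score`.
#' @export
best_allele_score <- function(peptide, models) {
  scores <- vapply(models, function(m) score_9mer(peptide, m), numeric(1))
  i <- which.max(scores)
  list(allele = names(models)[i], score = unname(scores[i]))
}

#' Odds ratio and exact p-value for a 2x2 enrichment table
#'
#' The odds ratio is the sample `ad/bc` with a 0.5 continuity correction
#' applied to every cell when any cell is zero (flagged); the p-value is the
#' two-sided Fisher exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (rows: group, columns: outcome), or a length-4 vector `(a, b, c, d)`
#'   filled row-wise.
#' @return List with `odds_ratio`, `p_value`, `continuity_corrected`.
#' @export
enrichment_or <- function(table) {
  if (is.vector(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integer counts")
  if (all(table == 0)) stop("all-zero table")
  corrected <- any(table == 0)
  tt <- if (corrected) table + 0.5 else table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  p <- fisher.test(table)$p.value
  list(odds_ratio = unname(or), p_value = p,
       continuity_corrected = corrected)
}

#' Write allele specificity profiles as TSV
#' @param profiles Named list of specificity vectors.
#' @param path Output path.
#' @export
write_specificity <- function(profiles, path) {
  mat <- do.call(rbind, profiles)
  df <- data.frame(allele = names(profiles), signif(mat, 10),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
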