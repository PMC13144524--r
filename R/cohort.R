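## MAF-style ingest and the per-sample substitution-fraction matrix

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

# "p.E123K" / "p.Glu123Lys" / optional parentheses -> "E>K" or NA
.parse_hgvsp <- function(x) {
  x <- sub("^p\\.", "", x)
  x <- gsub("[()]", "", x)
  m1 <- regexec("^([A-Z])([0-9]+)([A-Z])$", x)
  m3 <- regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x)
  out <- rep(NA_character_, length(x))
  g1 <- regmatches(x, m1)
  g3 <- regmatches(x, m3)
  for (i in seq_along(x)) {
    if (length(g1[[i]]) == 4L) {
      wt <- g1[[i]][2]; mut <- g1[[i]][4]
    } else if (length(g3[[i]]) == 4L) {
      wt <- unname(.aa3to1[g3[[i]][2]]); mut <- unname(.aa3to1[g3[[i]][4]])
      if (is.na(wt) || is.na(mut)) next
    } else next
    if (wt %in% AA20 && mut %in% AA20 && wt != mut)
      out[i] <- paste0(wt, ">", mut)
  }
  out
}

#' Read a MAF-style somatic mutation table
#'
#' Retains only rows whose variant classification equals the missense
#' category and whose protein change parses to a directed substitution
#' between two distinct standard residues. Column names default to the GDC
#' MAF dialect but can be overridden. Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to a tab-separated file with a header.
#' @param sample_col,class_col,protein_col Column names for the sample
#'   barcode, variant classification and HGVS-p short protein change.
#' @param missense_label Classification value kept (default
#'   `"Missense_Mutation"`).
#' @return A data.frame with columns `sample_id`, `substitution`, carrying an
#'   `ingest_report` attribute (rows read, dropped by classification,
#'   dropped unparsable).
#' @export
read_maf <- function(path,
                     sample_col = "Tumor_Sample_Barcode",
                     class_col = "Variant_Classification",
                     protein_col = "HGVSp_Short",
                     missense_label = "Missense_Mutation") {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  for (col in c(sample_col, class_col, protein_col))
    if (!col %in% names(df))
      stop("format error: required column not found: ", col)
  n_read <- nrow(df)
  keep <- df[[class_col]] == missense_label
  df <- df[keep, , drop = FALSE]
  subs <- .parse_hgvsp(df[[protein_col]])
  unparsable <- sum(is.na(subs))
  out <- data.frame(sample_id = df[[sample_col]][!is.na(subs)],
                    substitution = subs[!is.na(subs)],
                    stringsAsFactors = FALSE)
  if (any(out$sample_id == "")) stop("empty sample barcode in input")
  attr(out, "ingest_report") <- list(
    rows_read = n_read,
    dropped_non_missense = n_read - sum(keep),
    dropped_unparsable = unparsable,
    rows_kept = nrow(out))
  out
}

#' Build the per-sample substitution-fraction matrix
#'
#' Samples with fewer than `min_mutations` retained missense records are
#' discarded; each retained sample's counts are converted to fractions that
#' sum to one. Every retained record is counted (no deduplication).
#'
#' @param records data.frame with columns `sample_id`, `substitution`
#'   (as returned by [read_maf()]).
#' @param min_mutations Minimum missense mutations per retained sample
#'   (default 10, as used for the main analysis; 25 and 50 serve as
#'   robustness cutoffs).
#' @param alphabet Substitution alphabet (character vector); defaults to
#'   [enumerate_reachable_substitutions()].
#' @param alphabet_policy `"fixed"` drops records outside `alphabet`;
#'   `"extend"` appends observed substitutions to it (sorted).
#' @return An object of class `aas_cohort`: list with `fractions` and
#'   `counts` (samples x substitutions matrices), `alphabet`, `sample_ids`,
#'   `min_mutations` and a `report`.
#' @export
build_cohort <- function(records, min_mutations = 10,
                         alphabet = enumerate_reachable_substitutions(),
                         alphabet_policy = c("fixed", "extend")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (min_mutations < 1) stop("`min_mutations` must be >= 1")
  stopifnot(all(c("sample_id", "substitution") %in% names(records)))
  parse_substitution(unique(records$substitution))  # validate
  extra <- setdiff(records$substitution, alphabet)
  if (length(extra)) {
    if (alphabet_policy == "extend") {
      alphabet <- sort(union(alphabet, extra))
    } else {
      records <- records[records$substitution %in% alphabet, , drop = FALSE]
    }
  }
  counts <- table(factor(records$sample_id),
                  factor(records$substitution, levels = alphabet))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), alphabet))
  # order rows by sample id for input-order invariance
  counts <- counts[order(rownames(counts)), , drop = FALSE]
  tot <- rowSums(counts)
  keep <- tot >= min_mutations
  n_filtered <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L)
    stop("empty cohort: no sample has >= ", min_mutations,
         " missense mutations")
  fractions <- counts / rowSums(counts)
  structure(list(fractions = fractions,
                 counts = counts,
                 alphabet = alphabet,
                 sample_ids = rownames(counts),
                 min_mutations = min_mutations,
                 report = list(samples_filtered = n_filtered,
                               samples_kept = nrow(counts))),
            class = "aas_cohort")
}

#' Re-apply the minimum-mutation filter to a cohort
#'
#' Used for robustness checks: rebuilding at stricter cutoffs (e.g. 25, 50)
#' yields nested sample sets.
#'
#' @param cohort An `aas_cohort` with a counts matrix.
#' @param min_mutations New (stricter) threshold.
#' @return An `aas_cohort` restricted to samples with at least
#'   `min_mutations` mutations.
#' @export
filter_cohort <- function(cohort, min_mutations) {
  if (is.null(cohort$counts)) stop("cohort carries no counts matrix")
  keep <- rowSums(cohort$counts) >= min_mutations
  if (!any(keep)) stop("empty cohort: no sample passes the threshold")
  counts <- cohort$counts[keep, , drop = FALSE]
  out <- cohort
  out$counts <- counts
  out$fractions <- counts / rowSums(counts)
  out$sample_ids <- rownames(counts)
  out$min_mutations <- min_mutations
  if (!is.null(out$truth))
    out$truth$weights <- out$truth$weights[keep, , drop = FALSE]
  out
}

#' @export
print.aas_cohort <- function(x, ...) {
  cat("Substitution-fraction cohort\n")
  cat("  samples:      ", nrow(x$fractions), "\n")
  cat("  alphabet size:", length(x$alphabet), "\n")
  cat("  min mutations:", x$min_mutations, "\n")
  invisible(x)
}

#' Write / read a cohort matrix as TSV
#'
#' The TSV has samples in rows (first column `sample_id`) and one column per
#' substitution; fractions at 10 significant digits so re-reads reproduce the
#' matrix. Counts are stored alongside as `<path>.counts.tsv`.
#'
#' @param cohort An `aas_cohort`.
#' @param path Output TSV path.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample_id = rownames(cohort$fractions),
                   signif(cohort$fractions, 10), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dfc <- data.frame(sample_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE)
  write.table(dfc, paste0(path, ".counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param min_mutations Filter recorded in the restored object.
#' @export
read_cohort <- function(path, min_mutations = 10) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  counts_path <- paste0(path, ".counts.tsv")
  fr <- as.matrix(df[, -1, drop = FALSE])
  rownames(fr) <- df$sample_id
  counts <- NULL
  if (file.exists(counts_path)) {
    dfc <- read.delim(counts_path, stringsAsFactors = FALSE,
                      check.names = FALSE)
    counts <- as.matrix(dfc[, -1, drop = FALSE])
    rownames(counts) <- dfc$sample_id
  }
  structure(list(fractions = fr, counts = counts,
                 alphabet = colnames(fr),
                 sample_ids = rownames(fr),
                 min_mutations = min_mutations,
                 report = list()),
            class = "aas_cohort")
}
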