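## Serialisation and the end-to-end pipeline

#' Serialise / restore a fitted model as JSON
#'
#' @param model An `aas_model`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  obj <- list(alphabet = colnames(model$coefficients),
              signatures = rownames(model$coefficients),
              coefficients = signif(unclass(model$coefficients), 10),
              exposures = signif(unclass(model$exposures), 10),
              sample_ids = rownames(model$exposures),
              rank = model$rank,
              objective = model$objective,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns an `aas_model` (without the training
#'   matrix, so `fitted`/`residuals` are unavailable on restored models).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$rank <- as.integer(obj$rank)
  H <- matrix(obj$coefficients, nrow = obj$rank,
              dimnames = list(obj$signatures, obj$alphabet))
  W <- matrix(obj$exposures, ncol = obj$rank,
              dimnames = list(obj$sample_ids, obj$signatures))
  structure(list(coefficients = H, exposures = W, rank = obj$rank,
                 objective = obj$objective, x = NULL, meta = obj$meta),
            class = "aas_model")
}

#' Write / read SBS signatures in COSMIC-format TSV
#' @param sigs Named list of `sbs_signature` objects (all the same dialect).
#' @param path TSV path.
#' @export
write_sbs_signatures <- function(sigs, path) {
  stranded <- sigs[[1]]$stranded
  keys <- names(sigs[[1]]$probs)
  df <- data.frame(Type = if (stranded) sub("^[TU]:", "", keys) else keys)
  if (stranded) df$Strand <- sub(":.*$", "", keys)
  for (nm in names(sigs)) df[[nm]] <- signif(sigs[[nm]]$probs, 10)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CDS set as FASTA
#' @param cds Named character vector of CDS strings.
#' @param path FASTA path.
#' @export
write_cds <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Write a per-allele peptide table
#' @param peptides Named list of peptide vectors (one element per allele).
#' @param path TSV path.
#' @export
write_peptides <- function(peptides, path) {
  df <- data.frame(
    allele = rep(names(peptides), lengths(peptides)),
    peptide = unlist(peptides, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a detection dataset as TSV
#'
#' Long format: one row per (sample, substitution) with the sample's
#' fraction of the substitution and the detected flag.
#'
#' @param dataset List with `fractions` and `detected` matrices.
#' @param path TSV path.
#' @export
write_detection <- function(dataset, path) {
  fr <- dataset$fractions
  df <- data.frame(
    sample = rep(rownames(fr), times = ncol(fr)),
    substitution = rep(colnames(fr), each = nrow(fr)),
    fraction = signif(as.vector(fr), 10),
    detected = as.integer(as.vector(dataset$detected)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection
#' @export
read_detection <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  samples <- unique(df$sample)
  subs <- unique(df$substitution)
  fr <- matrix(NA_real_, length(samples), length(subs),
               dimnames = list(samples, subs))
  det <- matrix(NA, length(samples), length(subs),
                dimnames = list(samples, subs))
  idx <- cbind(match(df$sample, samples), match(df$substitution, subs))
  fr[idx] <- df$fraction
  det[idx] <- df$detected == 1
  list(fractions = fr, detected = det)
}

#' Write / read CFSE generation histograms
#' @param histograms Named list of generation-count vectors.
#' @param path TSV path (columns: replicate, generation, count).
#' @export
write_cfse <- function(histograms, path) {
  df <- do.call(rbind, lapply(names(histograms), function(nm)
    data.frame(replicate = nm,
               generation = seq_along(histograms[[nm]]) - 1L,
               count = histograms[[nm]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cfse
#' @export
read_cfse <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$replicate), function(d)
    d$count[order(d$generation)])
}

#' Run the signature-extraction pipeline end to end
#'
#' Ingest -> factorisation (at a fixed rank or with a rank survey) ->
#' dominance classification -> physicochemical summary, writing all
#' artefacts and a JSON provenance log to `out_dir`. Deterministic given
#' `seed`; each stage derives its own seed from the root seed, so stages are
#' independently reproducible.
#'
#' @param maf Path to a MAF-style table, or a pre-built `aas_cohort`
#'   (in which case ingest is skipped).
#' @param out_dir Output directory (created if needed).
#' @param rank Fixed factorisation rank, or `NULL` to select by survey.
#' @param ranks Candidate ranks when surveying.
#' @param nrun Restarts per fit / per survey rank.
#' @param min_mutations Sample inclusion filter at ingest.
#' @param threshold Dominance threshold.
#' @param seed Root seed.
#' @return Invisible list with the cohort, model, survey (or NULL),
#'   dominance calls and output paths.
#' @export
run_aas_pipeline <- function(maf, out_dir, rank = NULL, ranks = 2:10,
                             nrun = 30, min_mutations = 10, threshold = 0.6,
                             seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(i) (seed * 101L + i * 7919L) %% 2147483546L + 1L
  cohort <- if (inherits(maf, "aas_cohort")) {
    maf
  } else {
    if (!file.exists(maf)) stop("pipeline stage `ingest`: input file not found: ", maf)
    build_cohort(read_maf(maf), min_mutations = min_mutations)
  }
  write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
  survey <- NULL
  if (is.null(rank)) {
    survey <- tryCatch(
      aas_rank_survey(cohort, ranks = ranks, nrun = nrun,
                      seed = stage_seed(1L)),
      error = function(e) stop("pipeline stage `rank_survey`: ",
                               conditionMessage(e)))
    write_rank_survey(survey, file.path(out_dir, "rank_survey.tsv"))
    rank <- survey$selected_rank
  }
  model <- tryCatch(
    aas_nmf(cohort, rank = rank, nrun = nrun, seed = stage_seed(2L)),
    error = function(e) stop("pipeline stage `fit`: ", conditionMessage(e)))
  write_model(model, file.path(out_dir, "model.json"))
  dom <- classify_dominance(model, threshold = threshold)
  write.table(dom, file.path(out_dir, "dominance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  deltas <- sample_expected_delta(cohort$fractions)
  write.table(data.frame(sample_id = rownames(deltas),
                         signif(deltas, 10)),
              file.path(out_dir, "physchem.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  prov <- list(package = "aasig",
               version = as.character(utils::packageVersion("aasig")),
               seed = seed, rank = rank, nrun = nrun,
               min_mutations = min_mutations, threshold = threshold,
               n_samples = nrow(cohort$fractions),
               alphabet_size = length(cohort$alphabet))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, model = model, survey = survey,
                 dominance = dom,
                 paths = file.path(out_dir,
                                   c("cohort.tsv", "model.json",
                                     "dominance.tsv", "physchem.tsv",
                                     "provenance.json"))))
}
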