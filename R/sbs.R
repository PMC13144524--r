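## Projection of trinucleotide-context SBS signatures onto coding sequence

#' Read COSMIC-format SBS signatures
#'
#' Unstranded dialect: first column of channel strings (`"A[C>A]A"`, 96
#' pyrimidine-centric rows), one column per signature. Stranded dialect: an
#' additional `Strand` column with values `T` (transcribed) / `U`
#' (untranscribed), 192 rows per signature.
#'
#' @param path TSV path.
#' @return A named list of `sbs_signature` objects.
#' @export
read_sbs_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  type_col <- names(df)[1]
  stranded <- "Strand" %in% names(df)
  channels <- df[[type_col]]
  parse_channel(channels)  # validate
  sig_cols <- setdiff(names(df), c(type_col, "Strand"))
  keys <- if (stranded) paste0(df$Strand, ":", channels) else channels
  if (anyDuplicated(keys)) stop("duplicate channel rows in signature file")
  out <- lapply(sig_cols, function(nm) {
    p <- setNames(df[[nm]], keys)
    sbs_signature(p, name = nm, stranded = stranded)
  })
  setNames(out, sig_cols)
}

#' Construct an SBS signature object
#'
#' @param probs Named probability vector. Unstranded: names are the 96
#'   pyrimidine-centric channels. Stranded: names are `"T:<channel>"` /
#'   `"U:<channel>"` over the 96 channels (192 entries).
#' @param name Signature name.
#' @param stranded Logical.
#' @return An `sbs_signature`.
#' @export
sbs_signature <- function(probs, name = "SBS", stranded = FALSE) {
  if (any(probs < 0)) stop("signature probabilities must be non-negative")
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-9) {
    if (tot <= 0) stop("signature has zero total probability")
    probs <- probs / tot
  }
  expect <- if (stranded) {
    c(paste0("T:", trinuc_channels("pyrimidine")),
      paste0("U:", trinuc_channels("pyrimidine")))
  } else trinuc_channels("pyrimidine")
  if (!all(names(probs) %in% expect))
    stop("unexpected channel names in signature: ",
         setdiff(names(probs), expect)[1])
  full <- setNames(numeric(length(expect)), expect)
  full[names(probs)] <- probs
  structure(list(name = name, probs = full, stranded = stranded),
            class = "sbs_signature")
}

#' @export
print.sbs_signature <- function(x, ...) {
  cat("SBS signature", x$name,
      if (x$stranded) "(stranded, 192 channels)" else "(96 channels)", "\n")
  top <- sort(x$probs, decreasing = TRUE)[1:5]
  cat("  top channels:", paste(names(top), collapse = " "), "\n")
  invisible(x)
}

## ---- coding sequence handling ------------------------------------------

#' Read a CDS FASTA into a coding sequence set
#'
#' Records whose length is not a multiple of 3 or that contain non-ACGT
#' characters are dropped and counted in the attached report.
#'
#' @param path FASTA path.
#' @return Named character vector of CDS strings with a `report` attribute.
#' @export
read_cds <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ok <- nchar(seqs) %% 3 == 0 & !grepl("[^ACGT]", seqs)
  dropped <- sum(!ok)
  out <- seqs[ok]
  if (!length(out)) stop("no valid in-frame CDS records in ", path)
  attr(out, "report") <- list(records_read = length(seqs),
                              records_dropped = dropped)
  out
}

#' Catalogue every possible coding SNV with its consequence
#'
#' Enumerates each interior position (having both a 5' and a 3' neighbour
#' within the record) x 3 alternate bases across the CDS set and classifies
#' the consequence. Channels are reported on the coding strand (raw,
#' 192-channel space).
#'
#' @param cds Named character vector of in-frame CDS strings
#'   (see [read_cds()]).
#' @return data.frame with columns `record`, `pos` (1-based), `channel`
#'   (raw coding-strand channel), `type`, `substitution` (NA unless
#'   missense).
#' @export
site_catalogue <- function(cds) {
  if (!length(cds)) stop("empty CDS set")
  if (is.null(names(cds))) names(cds) <- paste0("cds", seq_along(cds))
  res <- vector("list", length(cds))
  for (r in seq_along(cds)) {
    s <- cds[[r]]
    L <- nchar(s)
    if (L < 3) next
    ch <- strsplit(s, "")[[1]]
    p <- 2:(L - 1)
    ref <- ch[p]
    p5 <- ch[p - 1]
    p3 <- ch[p + 1]
    cs <- p - ((p - 1) %% 3)
    codon <- substring(s, cs, cs + 2)
    pic <- p - cs + 1
    wt <- unname(.genetic_code[codon])
    per_alt <- lapply(BASES, function(alt) {
      keep <- ref != alt
      mutc <- codon[keep]
      substr(mutc, pic[keep], pic[keep]) <- alt
      mut <- unname(.genetic_code[mutc])
      wtk <- wt[keep]
      type <- ifelse(wtk == "*", "stop_context",
              ifelse(mut == "*", "nonsense",
              ifelse(mut == wtk, "synonymous", "missense")))
      data.frame(record = names(cds)[r], pos = p[keep],
                 channel = paste0(p5[keep], "[", ref[keep], ">", alt, "]",
                                  p3[keep]),
                 type = type,
                 substitution = ifelse(type == "missense",
                                       paste0(wtk, ">", mut), NA_character_),
                 stringsAsFactors = FALSE)
    })
    res[[r]] <- do.call(rbind, per_alt)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# per-missense-site sampling weight under a signature
.site_weights <- function(sites, sig) {
  raw <- sites$channel
  pyr <- substr(raw, 3, 3) %in% c("C", "T")
  coll <- raw
  coll[!pyr] <- revcomp_channel(raw[!pyr])
  if (!sig$stranded) {
    # strand-collapsed probability split equally between orientations
    sig$probs[coll] / 2
  } else {
    # untranscribed applies to coding-strand pyrimidine sites, transcribed
    # to coding-strand purine sites (pyrimidine on the template strand)
    key <- ifelse(pyr, paste0("U:", coll), paste0("T:", coll))
    sig$probs[key]
  }
}

#' Simulate missense mutations under an SBS signature
#'
#' Draws `n` missense events over the eligible sites of the CDS set, each
#' site weighted by the signature probability of its trinucleotide channel
#' (opportunity-weighted: recurring contexts receive proportionally more
#' mutations). Synonymous and nonsense sites carry zero weight and are never
#' emitted.
#'
#' @param sig An `sbs_signature`.
#' @param cds CDS set (named character vector) or a precomputed
#'   [site_catalogue()] data.frame.
#' @param n Number of simulated mutations (default 1000).
#' @param seed Integer seed.
#' @param alphabet Substitution alphabet for the tally.
#' @return Object of class `sim_spectrum`: `counts` and `fractions` over the
#'   alphabet, `n`, `seed`.
#' @export
simulate_missense <- function(sig, cds, n = 1000, seed = 1,
                              alphabet = enumerate_reachable_substitutions()) {
  sites <- if (is.data.frame(cds)) cds else site_catalogue(cds)
  sites <- sites[sites$type == "missense", , drop = FALSE]
  w <- .site_weights(sites, sig)
  if (!nrow(sites) || sum(w) <= 0)
    stop("no opportunity: the signature has no eligible missense site ",
         "in this CDS set")
  counts <- setNames(integer(length(alphabet)), alphabet)
  if (n > 0) {
    set.seed(seed)
    idx <- sample.int(nrow(sites), n, replace = TRUE, prob = w)
    tab <- table(factor(sites$substitution[idx], levels = alphabet))
    counts <- setNames(as.integer(tab), alphabet)
  }
  fractions <- if (n > 0) counts / n else setNames(rep(NA_real_,
                                                       length(alphabet)),
                                                   alphabet)
  structure(list(counts = counts, fractions = fractions, n = n, seed = seed,
                 signature = sig$name),
            class = "sim_spectrum")
}

#' @export
print.sim_spectrum <- function(x, ...) {
  cat("Simulated missense spectrum (", x$n, "mutations,", x$signature, ")\n")
  top <- sort(x$fractions, decreasing = TRUE)[1:5]
  cat("  top substitutions:",
      paste0(names(top), "=", signif(top, 3), collapse = " "), "\n")
  invisible(x)
}

#' Exact site-weighted expectation of the missense spectrum
#'
#' The analytic limit of [simulate_missense()]: signature-probability
#' weights over eligible missense sites, normalised and summed per directed
#' substitution.
#'
#' @inheritParams simulate_missense
#' @return Named numeric vector over the alphabet, summing to 1.
#' @export
expected_spectrum <- function(sig, cds,
                              alphabet = enumerate_reachable_substitutions()) {
  sites <- if (is.data.frame(cds)) cds else site_catalogue(cds)
  sites <- sites[sites$type == "missense", , drop = FALSE]
  w <- .site_weights(sites, sig)
  if (!nrow(sites) || sum(w) <= 0)
    stop("no opportunity: the signature has no eligible missense site")
  w <- w / sum(w)
  agg <- tapply(w, factor(sites$substitution, levels = alphabet), sum,
                default = 0)
  setNames(as.numeric(agg), alphabet)
}

#' Cosine similarity between a spectrum and each model signature
#'
#' @param spec A `sim_spectrum` or named substitution-fraction vector.
#' @param model An `aas_model`.
#' @param association_cutoff Cosine above which the spectrum is flagged as
#'   associated with the signature (default 0.7).
#' @return data.frame with columns `signature`, `cosine`, `associated`.
#' @export
spectrum_cosine <- function(spec, model, association_cutoff = 0.7) {
  v <- if (inherits(spec, "sim_spectrum")) spec$fractions else spec
  v <- .align_alphabet(v, model)
  cs <- apply(model$coefficients, 1, cosine_similarity, a = v)
  data.frame(signature = rownames(model$coefficients), cosine = cs,
             associated = cs > association_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- context -> signature information motif ----------------------------

#' Information-content motif of mutation contexts against signatures
#'
#' For each of the 192 raw trinucleotide profiles, simulates
#' `n_per_profile` missense mutations uniformly over the profile's eligible
#' sites; each simulated substitution i is assigned a signature k with
#' probability proportional to the coefficient a_{i,k}. The per-profile
#' signature fractions are converted to information content
#' (`log2(rank) - entropy`) and scaled column heights, the standard
#' information-count-matrix semantics.
#'
#' @param model An `aas_model`.
#' @param cds CDS set or site catalogue.
#' @param n_per_profile Simulated mutations per profile (default 1000).
#' @param seed Integer seed.
#' @param exact If `TRUE`, skip simulation and use the analytic mixture
#'   (site enumeration x coefficient rows).
#' @return Object of class `aas_icm`: `fractions` (192 x rank), `ic`
#'   (bits per profile), `heights` (`ic * fractions`), `absent` (profiles
#'   with no eligible site), plus a 96-channel strand-collapsed `collapsed`
#'   view.
#' @export
context_aas_motif <- function(model, cds, n_per_profile = 1000, seed = 1,
                              exact = FALSE) {
  sites <- if (is.data.frame(cds)) cds else site_catalogue(cds)
  sites <- sites[sites$type == "missense", , drop = FALSE]
  profiles <- trinuc_channels("all")
  k <- model$rank
  H <- model$coefficients  # k x m
  alpha <- colnames(H)
  frac <- matrix(0, length(profiles), k,
                 dimnames = list(profiles, rownames(H)))
  absent <- character(0)
  set.seed(seed)
  for (pi in seq_along(profiles)) {
    subs <- sites$substitution[sites$channel == profiles[pi]]
    subs <- subs[subs %in% alpha]
    if (!length(subs)) { absent <- c(absent, profiles[pi]); next }
    if (exact) {
      psub <- table(subs) / length(subs)
      pk <- numeric(k)
      for (s in names(psub)) {
        a <- H[, s]
        if (sum(a) > 0) pk <- pk + as.numeric(psub[[s]]) * a / sum(a)
      }
      frac[pi, ] <- pk / sum(pk)
    } else {
      draw <- sample(subs, n_per_profile, replace = TRUE)
      tallies <- numeric(k)
      for (s in unique(draw)) {
        a <- H[, s]
        nd <- sum(draw == s)
        if (sum(a) == 0) next
        ks <- sample.int(k, nd, replace = TRUE, prob = a)
        tallies <- tallies + tabulate(ks, nbins = k)
      }
      if (sum(tallies) == 0) { absent <- c(absent, profiles[pi]); next }
      frac[pi, ] <- tallies / sum(tallies)
    }
  }
  present <- !(profiles %in% absent)
  ent <- apply(frac, 1, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(NA_real_)
    -sum(p * log2(p))
  })
  ic <- log2(k) - ent
  ic[!present] <- NA_real_
  heights <- frac * ic
  # strand-collapsed 96-channel view: average the two orientations
  pyr <- trinuc_channels("pyrimidine")
  collapsed <- (frac[pyr, , drop = FALSE] +
                frac[revcomp_channel(pyr), , drop = FALSE]) / 2
  rownames(collapsed) <- pyr
  structure(list(fractions = frac, ic = ic, heights = heights,
                 absent = absent, collapsed = collapsed,
                 meta = list(n_per_profile = n_per_profile, seed = seed,
                             exact = exact)),
            class = "aas_icm")
}

#' @export
print.aas_icm <- function(x, ...) {
  cat("Context->signature information motif:",
      nrow(x$fractions), "profiles x", ncol(x$fractions), "signatures\n")
  cat("  absent profiles:", length(x$absent), "\n")
  cat("  information content range:",
      paste(signif(range(x$ic, na.rm = TRUE), 3), collapse = " - "),
      "bits\n")
  invisible(x)
}

#' Write a motif or spectrum as TSV
#' @param x An `aas_icm` or `sim_spectrum`.
#' @param path Output path.
#' @export
write_motif <- function(x, path) {
  if (inherits(x, "aas_icm")) {
    df <- data.frame(profile = rownames(x$fractions),
                     signif(x$heights, 10), ic = signif(x$ic, 10),
                     check.names = FALSE)
  } else {
    df <- data.frame(substitution = names(x$fractions),
                     count = x$counts, fraction = signif(x$fractions, 10))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
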