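#' @useDynLib aasig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist cophenetic cor cutree dist fisher.test hclust
#'   quantile rbinom rgamma rmultinom runif sd setNames simulate
#' @importFrom utils read.delim write.table
"_PACKAGE"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")
BASES <- c("A", "C", "G", "T")

# standard nuclear genetic code, codon -> one-letter residue ("*" = stop)
.genetic_code <- local({
  b <- c("T", "C", "A", "G")
  # first base slowest, third fastest (classic TCAG table order)
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

#' Translate a codon with the standard nuclear genetic code
#'
#' @param codon A 3-character string over A/C/G/T.
#' @return The one-letter amino acid, or `"*"` for a stop codon.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("`codon` must be a single 3-base string")
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon))
    stop("invalid sequence: codon contains non-ACGT character: ", codon)
  unname(.genetic_code[codon])
}

#' Classify a single-nucleotide change within a codon
#'
#' Applies the alternate base at the given codon position and classifies the
#' consequence under the standard genetic code.
#'
#' @param codon Reference codon (3 bases, A/C/G/T).
#' @param pos Position within the codon, 1..3.
#' @param alt Alternate base, must differ from the reference base at `pos`.
#' @return A list with elements `type` (one of `"synonymous"`, `"missense"`,
#'   `"nonsense"`, `"stop_context"`) and, for missense, `substitution`
#'   (string `"X>Y"`), `wt` and `mut`. Changes inside a stop codon are
#'   labelled `"stop_context"`.
#' @export
classify_snv <- function(codon, pos, alt) {
  codon <- toupper(codon)
  alt <- toupper(alt)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon: ", codon)
  if (!pos %in% 1:3) stop("`pos` must be 1, 2 or 3")
  if (!alt %in% BASES) stop("invalid alternate base: ", alt)
  if (substr(codon, pos, pos) == alt)
    stop("alternate base equals the reference base at position ", pos)
  wt <- unname(.genetic_code[codon])
  mutated <- codon
  substr(mutated, pos, pos) <- alt
  mut <- unname(.genetic_code[mutated])
  if (wt == "*") return(list(type = "stop_context"))
  if (mut == "*") return(list(type = "nonsense"))
  if (mut == wt)  return(list(type = "synonymous"))
  list(type = "missense",
       substitution = paste0(wt, ">", mut),
       wt = wt, mut = mut)
}

#' Directed amino acid substitutions reachable by a single nucleotide change
#'
#' Enumerates every directed substitution `X>Y` obtainable by one nucleotide
#' change within a sense codon of the standard genetic code, in lexicographic
#' order (by wild-type then mutant residue). This is the package's default
#' substitution alphabet (150 members); cohort ingest can extend it with
#' observed substitutions that are not single-nucleotide reachable (e.g.
#' arising from multi-nucleotide variants).
#'
#' @return Character vector of substitution strings, e.g. `"E>K"`.
#' @export
enumerate_reachable_substitutions <- function() {
  codons <- names(.genetic_code)[.genetic_code != "*"]
  out <- character(0)
  for (cod in codons) {
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      for (b in BASES[BASES != ref]) {
        cl <- classify_snv(cod, p, b)
        if (cl$type == "missense") out <- c(out, cl$substitution)
      }
    }
  }
  sort(unique(out))
}

#' Parse / format directed substitutions
#'
#' @param x Substitution strings of the form `"X>Y"`.
#' @return `parse_substitution` returns a data.frame with columns `wt`, `mut`.
#' @export
parse_substitution <- function(x) {
  ok <- grepl("^[A-Z]>[A-Z]$", x)
  if (any(!ok)) stop("malformed substitution string: ", x[!ok][1])
  wt <- substr(x, 1, 1)
  mut <- substr(x, 3, 3)
  bad <- !(wt %in% AA20) | !(mut %in% AA20)
  if (any(bad)) stop("non-standard residue in substitution: ", x[bad][1])
  if (any(wt == mut)) stop("self-substitution not allowed: ", x[wt == mut][1])
  data.frame(wt = wt, mut = mut, stringsAsFactors = FALSE)
}

## ---- trinucleotide channels -------------------------------------------

.comp <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Enumerate trinucleotide mutation channels
#'
#' Channels are written `"A[C>T]G"`: the mutated base with its 5' and 3'
#' neighbours. `"pyrimidine"` gives the 96 strand-collapsed channels
#' (reference base C or T); `"all"` gives the 192 raw channels (all 12 base
#' changes, i.e. both strand representations).
#'
#' @param set `"pyrimidine"` (96 channels) or `"all"` (192).
#' @return Character vector of channel strings in a fixed documented order
#'   (reference base, then alternate, then 5' and 3' context,
#'   all alphabetical).
#' @export
trinuc_channels <- function(set = c("pyrimidine", "all")) {
  set <- match.arg(set)
  refs <- if (set == "pyrimidine") c("C", "T") else BASES
  out <- character(0)
  for (ref in refs)
    for (alt in BASES[BASES != ref])
      for (p5 in BASES)
        for (p3 in BASES)
          out <- c(out, paste0(p5, "[", ref, ">", alt, "]", p3))
  out
}

#' Parse channel strings of the form `"A[C>T]G"`
#' @param x Channel strings.
#' @return data.frame with columns `p5`, `ref`, `alt`, `p3`.
#' @export
parse_channel <- function(x) {
  m <- regmatches(x, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed channel string: ", x[bad][1])
  p <- do.call(rbind, m)
  df <- data.frame(p5 = p[, 2], ref = p[, 3], alt = p[, 4], p3 = p[, 5],
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("channel with ref == alt: ", x[df$ref == df$alt][1])
  df
}

#' Reverse-complement a trinucleotide channel
#'
#' Maps a channel onto its opposite-strand representation; an involution that
#' pairs each purine-reference channel with a pyrimidine-reference one, so the
#' 192 raw channels collapse onto the 96 pyrimidine-centric set.
#'
#' @param ch Channel strings, e.g. `"G[C>T]C"`.
#' @return Reverse-complemented channel strings (`"G[G>A]C"` for the example).
#' @export
revcomp_channel <- function(ch) {
  p <- parse_channel(ch)
  paste0(.comp[p$p3], "[", .comp[p$ref], ">", .comp[p$alt], "]", .comp[p$p5])
}

#' Collapse a raw channel to its pyrimidine-centric representative
#' @param ch Channel strings.
#' @return Channel strings with reference base C or T.
#' @export
collapse_channel <- function(ch) {
  p <- parse_channel(ch)
  pur <- p$ref %in% c("A", "G")
  ch[pur] <- revcomp_channel(ch[pur])
  ch
}

## ---- physicochemical scales -------------------------------------------

#' Physicochemical scale for the 20 standard residues
#'
#' Default hydrophobicity is the Kyte-Doolittle hydropathy index; charge is
#' the net charge at neutral pH (D, E: -1; K, R: +1; all others including H:
#' 0). A custom scale can be supplied as a TSV with columns
#' `residue`, `hydrophobicity`, `charge`.
#'
#' @param path Optional path to a TSV overriding the packaged scale.
#' @return data.frame with rownames = residues and columns `hydrophobicity`,
#'   `charge`; attribute `scale_id` records the scale identity.
#' @export
physchem_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physchem_kyte_doolittle.tsv",
                        package = "aasig")
    id <- "kyte_doolittle_hydropathy/net_charge_pH7"
  } else {
    id <- paste0("user:", basename(path))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "charge")
  if (!all(need %in% names(df)))
    stop("physicochemical scale must have columns: ",
         paste(need, collapse = ", "))
  missing <- setdiff(AA20, df$residue)
  if (length(missing))
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  out <- df[match(sort(AA20), df$residue), c("hydrophobicity", "charge")]
  out[] <- lapply(out, as.numeric)
  rownames(out) <- sort(AA20)
  attr(out, "scale_id") <- id
  out
}
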