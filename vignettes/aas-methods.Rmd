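---
title: "Amino acid substitution signatures: models and methods"
author: "aasig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino acid substitution signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aasig)
```

## The model

Somatic missense mutations in a tumour replace one amino acid by another.
Collapsing a sample's missense burden onto the 150 directed substitutions
`X>Y` that a single nucleotide change can produce (extendable when
multi-nucleotide variants contribute additional pairs) gives each sample a
substitution-fraction vector on a simplex. `aasig` models a cohort of such
vectors as a non-negative mixture of a small number of *amino acid
substitution signatures* (AAS):

$$ V \approx W H, \qquad V \in \mathbb{R}_{\ge 0}^{n \times m},\;
   W \in \mathbb{R}_{\ge 0}^{n \times k},\;
   H \in \mathbb{R}_{\ge 0}^{k \times m}, $$

where rows of `H` are signature profiles (the *coefficients*, association
strengths $a_{i,k}$ of substitution $i$ with signature $k$) and rows of `W`
are per-sample *exposures*. The factorisation minimises the generalised
Kullback–Leibler divergence by multiplicative updates with random uniform
initialisation, the classical variant for mutational-signature work; the
best of `nrun` random restarts is kept. After fitting, each coefficient row
is L1-normalised with the scale pushed into the exposures. Because the
input rows are fractions summing to one, exposures then also sum to
approximately one per sample, which makes the 0.6 dominance threshold
directly interpretable: a sample is *dominated* by a signature whose
exposure exceeds 0.6 (largest value wins when several exceed it) and
*mixed* otherwise.

### Rank selection

The number of signatures is chosen by consensus clustering over the random
restarts. Each run clusters samples by their maximal exposure; the run
connectivity matrices are averaged into a consensus matrix per rank. We
report the cophenetic correlation of average-linkage hierarchical
clustering of `1 − consensus`, the mean silhouette width of the k-cluster
consensus partition, the consensus dispersion, and the residual sum of
squares and explained variance of the best fit. The selected rank maximises
the mean of cophenetic correlation and silhouette width, with ties broken
toward the smaller rank. The criteria are deliberately reproducibility-led:
RSS always improves with rank, so it is reported but never drives the
choice.

Default survey settings are ranks 2–10 with 30 restarts per rank. A desk
machine handles a 600-sample survey in a few minutes; the range is
configurable for larger studies.

### Numerical choices

* Multiplicative updates run to a relative objective change below `tol`
  (default `1e-5`, checked every 10 iterations) or `max_iter = 2000`.
  Entries of `WH` are floored at `1e-16` to keep the KL terms finite.
* Restart seeds are drawn reproducibly from the user seed, so a fit is a
  pure function of `(matrix, rank, nrun, seed)`.
* Signature matching between two fitted models (`robustness_compare`) uses
  exact maximum-weight bipartite assignment on pairwise cosine similarity,
  computed by a bitmask dynamic program (exact up to rank 20).
* Numeric TSV/JSON output is written at 10 significant digits so re-runs
  produce byte-identical files.

## Projecting nucleotide signatures into substitution space

Single-base substitution (SBS) signatures are probability vectors over 96
strand-collapsed trinucleotide channels (or 192 with transcriptional strand
labels). To translate one into amino-acid space, `simulate_missense` draws
missense events over a coding sequence set: every interior coding position
× alternate base is classified once (`site_catalogue`), and each missense
site is weighted by the signature probability of its channel. This is
*opportunity-weighted* sampling — contexts that occur more often in the CDS
receive proportionally more mutations — which we prefer over
channel-then-site sampling because it matches how mutational processes act
on available sequence. Synonymous and nonsense sites carry zero weight
rather than being rejected after sampling; the emitted distribution is the
same and no draws are wasted. For strand-collapsed signatures each
channel's probability is split equally between the two orientations; for
stranded signatures the untranscribed probability applies to coding-strand
pyrimidine sites and the transcribed probability to coding-strand purine
sites. The exact expectation (`expected_spectrum`) is available in closed
form by normalising the site weights, and Monte-Carlo spectra converge to
it at the usual $n^{-1/2}$ rate.

`context_aas_motif` inverts the view: for each of the 192 raw coding-strand
contexts it simulates missense mutations uniformly over that context's
sites, assigns each to a signature with probability proportional to
$a_{i,k}$, and converts the per-context signature fractions to information
content, $IC = \log_2 k - H_{\text{Shannon}}$, with column heights
$IC \times$ fraction — standard information-count-matrix semantics.
Contexts with no eligible site in the CDS are flagged absent rather than
erroring, since small or biased CDS sets legitimately lack contexts.

## HLA class I amino acid specificity

From an allele's immunopeptidome we build per-length positional
residue-frequency models (lengths 8–12; an allele needs 400 peptides
overall and a length subset 100 peptides to be analysed — smaller sets give
unstable frequency estimates). Positions are weighted by information
content, $w_p \propto \log_2 20 - H_p$, normalised within a subset;
low-entropy anchor positions dominate. The allele's specificity for residue
$a$ is $\sum_p w_p f_p(a)$ per subset, averaged across subsets weighted by
subset size. With frequencies and weights each summing to one the profile
is automatically a simplex vector; the package asserts this rather than
renormalising. Two degenerate conventions are fixed deliberately: if every
position is maximally entropic the weights fall back to uniform, and a
single-residue peptidome yields a delta profile on that residue.

No pseudocounts are added by default — the profiles feed ranking
statistics, not log-odds scores — but an additive pseudocount is available
for small peptidomes.

A signature's affinity for an allele aggregates coefficients by *mutated*
residue ($m_k(a) = \sum_{i: \text{mut}(i)=a} a_{i,k}$) and dots that with
the specificity profile; patient-level values average over the up-to-six
allele genotype with homozygous alleles repeated, so each HLA locus keeps
its gene-dosage weight. 9-mers are scored as the mean over positions of
$w_p f_p(\text{residue})$ from the 9-mer subset, and a genotype's score for
a peptide is the maximum over its alleles (the strongest binder presents).

## Detection validation

For sample $s$, $c_{s,k}$ is the cosine similarity between its substitution
fractions and coefficient row $k$; the weighted-sum association strength of
substitution $i$ is $A_{s,i} = \sum_k c_{s,k} a_{i,k}$. Detection of
substitutions in HLA-bound neopeptides is validated by the ROC AUC of $A$
against detected/undetected flags, pooled over samples by default (each of
the alphabet's substitutions contributes one observation per sample;
a flag restricts to substitutions actually mutated in the sample). AUC is
computed as the exact Mann–Whitney rank statistic with midrank ties, not by
trapezoid integration, so small worked examples are exact.

## Physicochemical impact and the division index

Hydrophobicity uses the Kyte–Doolittle hydropathy index and charge the net
charge at neutral pH (D, E: −1; K, R: +1; histidine 0) — the field's
defaults when no scale is named; the scale identity travels in the output
metadata and a 20-row TSV can replace it. Per-substitution deltas are
`prop(mut) − prop(wt)` and per-sample values are fraction-weighted means,
which equal the mean change over the sample's observed mutations.

The CFSE division index of a generation histogram $N_0..N_g$ is
$\sum_i i N_i / 2^i \big/ \sum_i N_i / 2^i$: dividing $N_i$ by $2^i$
recovers founder-cell equivalents, so the index is the mean number of
divisions per founder. Z-transforms within replicate groups use the sample
(n−1) standard deviation. Generations beyond the histogram are treated as
absent; no truncation correction is applied.

## What the synthetic data emulates — and what it does not

The generator suite produces every input the pipeline consumes, each a
deterministic function of its seed:

* **Cohorts** (`simulate_cohort`): per-sample mixing weights from a
  symmetric Dirichlet (concentration 0.3 — sparse mixtures, so most samples
  are dominated by one signature, matching the structure reported for real
  tumour cohorts) over five packaged profiles whose flagship substitutions
  follow the published signature descriptions (C>A-type; C>T-type led by
  P>S/D>N; the arginine signature R>H/C/Q/W; T>C-type; E>K/E>Q). Counts are
  multinomial with either a fixed burden or a log-uniform 10–1000 spread
  mimicking tumour-mutational-burden variation. Pairwise profile cosines
  are below 0.5.
* **SBS signatures**: symmetric-Dirichlet channel vectors with tunable
  sparsity. **CDS**: in-frame records with start/stop and tunable GC.
  **Peptidomes**: uniform residues with planted anchors at given purity.
  **Detection data**: flags drawn from a logistic model
  $\Pr(\text{detected}) = \text{logit}^{-1}(\alpha + \beta A_{s,i})$, with
  $\alpha = -3$, $\beta = 25$ as the "strong association" default —
  coefficient rows are simplex vectors, so $A$ lives on a scale of roughly
  0–0.5 and $\beta = 25$ spans the logistic's dynamic range; $\beta = 0$ is
  the null. **CFSE histograms**: founder clones dividing synchronously with
  per-round probability $p$, capped at `max_gen`.

These generators plant clean, well-separated structure. Real cohorts add
features the generators deliberately omit: correlated signature exposures,
tumour-type composition, sequencing artefacts, MNV-derived substitutions,
peptide-processing biases, and CFSE peak overlap. Tests passing on
synthetic data therefore demonstrate that the algorithms recover known
structure under their stated assumptions — not that the biological
conclusions transfer to any particular real dataset.

## Problem sizes used in the packaged checks

The study-scale synthetic analyses use 600 samples × 200 substitutions per
sample for the rank survey and recovery checks (chosen as a cohort size at
which consensus metrics stabilise while a survey remains a desk-scale
computation), 20 × 1.5 kb CDS records (~30 kb) with $10^5$ simulated
mutations for simulator–expectation agreement, 17-sample detection datasets
echoing the immunopeptidomics validation design, and 400–600-peptide
anchored peptidomes.

## Known limitations

* The factorisation is the classical KL-NMF; Bayesian or refitting-based
  signature attribution against fixed catalogues is out of scope.
* The exposure convention makes multiple >0.6 exposures per sample rare;
  conventions that scale basis columns differently can report them more
  often, so dominance proportions are comparable only within a convention.
* Stranded simulation assumes the CDS is the untranscribed (coding) strand.
* HLA scoring is specificity-based; it is not a binding-affinity predictor
  and ignores proteasomal processing and transport.
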