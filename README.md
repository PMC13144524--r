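# aasig — amino acid substitution signatures from somatic mutation cohorts

Nucleotide-level mutational signatures describe *how* DNA is damaged;
what shapes neoantigens and tumour immunogenicity is *which amino acids*
those mutations swap. `aasig` works at that protein level. It is aimed at
cancer genomics and tumour immunology analysts who have per-sample somatic
missense mutation tables (MAF-style) and want to:

1. **Extract amino acid substitution signatures (AAS).** Each sample is a
   fraction vector over the directed substitutions `X>Y` reachable by a
   single nucleotide change (150 under the standard code; extendable).
   The cohort matrix `V` (samples × substitutions) is factorised as
   `V ≈ W H` by non-negative matrix factorisation minimising the
   generalised Kullback–Leibler divergence, with the number of signatures
   chosen by consensus clustering over random restarts (cophenetic
   correlation + silhouette). Rows of `H` are signature profiles
   (association strengths `a_ik`); rows of `W` are sample exposures, and a
   sample is *dominated* by a signature whose exposure exceeds 0.6,
   otherwise *mixed*.
2. **Bridge to nucleotide signatures.** COSMIC-format SBS signatures
   (96 or 192 trinucleotide channels) are projected into substitution
   space by simulating missense mutations over a coding sequence set, with
   per-site weights given by the signature's channel probabilities; the
   reverse view builds an information-content motif of how each of the 192
   contexts feeds each AAS.
3. **Score HLA class I presentation.** Entropy-weighted positional
   residue frequencies of an allele's immunopeptidome yield a 20-residue
   specificity profile; signature affinity dots it with the signature's
   mutated-residue aggregate, 9-mers are scored per genotype, and
   detection of substitutions in immunopeptidomes is validated with
   `A_si = Σ_k c_sk a_ik` and exact Mann–Whitney ROC/AUC.
4. **Quantify downstream impact.** Hydrophobicity/charge changes per
   substitution and per sample, 2×2 enrichment odds ratios with exact
   p-values, and the CFSE division index
   `DI = Σ i·N_i/2^i / Σ N_i/2^i` with replicate-wise Z-transforms.

A seeded synthetic-data module generates every input the pipeline consumes
(cohorts with planted signatures, sparse SBS signatures, in-frame CDS,
anchored peptidomes, detection datasets, CFSE histograms), so the whole
pipeline is testable without external data.

## Worked example

```r
library(aasig)

# a synthetic cohort from the packaged five-signature ground truth
cfg    <- ground_truth_profiles()
cohort <- simulate_cohort(cfg, n_samples = 150, seed = 42, mutations = 300)

fit <- aas_nmf(cohort, rank = 5, nrun = 5, seed = 42)
fit
#> Amino acid substitution signature model (KL-NMF)
#>   rank:       5
#>   samples:    150
#>   alphabet:   150 substitutions
#>   objective:  30.7325 (best of 5 restarts)

# the fitted profiles recover the planted ones almost perfectly
robustness_compare(fit, cfg$profiles)
#>   signature_a signature_b    cosine
#> 1        AAS1        AAS1 0.9998063
#> 2        AAS2        AAS3 0.9993578
#> 3        AAS3        AAS2 0.9988322
#> 4        AAS4        AAS5 0.9993415
#> 5        AAS5        AAS4 0.9989786

table(classify_dominance(fit, threshold = 0.6)$label)
#>
#>  AAS1  AAS2  AAS3  AAS4  AAS5 mixed
#>    16    18    16    15    18    67
```

The matched cosines say each fitted signature aligns with one planted
profile at ≥ 0.998 (fitted signatures are ordered by total exposure, so
labels permute relative to the planted order); the dominance table shows
the majority of samples dominated by a single signature and the rest
mixed — the structure the Dirichlet(0.3) mixing plants. Column order of
`robustness_compare` follows the first model's signatures.

Rank selection on a study-scale cohort:

```r
cohort <- simulate_cohort(cfg, n_samples = 600, seed = 1, mutations = 200)
survey <- aas_rank_survey(cohort, ranks = 2:10, nrun = 30, seed = 1)
survey$selected_rank
#> [1] 5
```

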