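# phoskin

Kinase-specific phosphorylation-site prediction from protein sequence,
for computational biologists who have a table of experimentally validated
phosphosites (Phospho.ELM-style) and want to score new candidate S/T/Y
sites for the same kinase group — without training a model.

## Method

For a candidate site, `phoskin` extracts two windows around the residue
and scores its similarity to every peptide of a labelled reference set
(known sites = positives; sampled non-annotated S/T/Y = negatives, 10 per
positive):

* **S_BLOSUM62** — the sum of BLOSUM62 substitution scores over the
  7-residue window (center ± 3), terminal gaps padded with `X`;
* **S_profile** — a global affine-gap profile–profile alignment of the
  41-residue windows (gap open 3.0, extension 0.75), where a column pair
  (i, j) scores `½ Σ_k (f_ik S_jk + f_jk S_ik)` over PSI-BLAST
  frequency/log-odds profiles (or deterministic pseudo-profiles when no
  PSSM files are available);
* **S_combined = S_BLOSUM62 × S_profile** when both are positive, else 0.

A noise-reducing classifier then re-ranks the evidence through *indirect*
relationships: the query's top-α hits are linked to their own top-α
neighbours; same-label links count as signal (+), cross-label links as
noise (−), links to positive partners are up-weighted (weight = the
negative:positive ratio, 10 under standard sampling); the query is called
a phosphosite when more than γ of the top-β peptides by indirect score
are positives, with confidence = the positive fraction of the top β. The
parameter rules are α, β, γ = 1/2, 1/3, 1/4 of the positive count.

A leave-one-out / stratified k-fold harness reports accuracy, precision
and recall at all four feature levels, plus ROC curves in
true-matches-vs-false-matches form. A seeded generator
(`simulate_refset()`) plants a position-weight-matrix motif in synthetic
substrate proteins so the whole pipeline is testable offline.

## Worked example

```r
library(phoskin)

ref <- simulate_refset(n_pos = 30, seed = 1)
ref
#> <ref_set> kinase 'SYNTH': 30 positives, 300 negatives (seed 1001)

sim <- similarity_matrix(ref)           # all-pairs similarity, C++ kernel
cv  <- loocv(ref, feature = "combined", sim = sim)
glance(cv)[c("feature", "acc", "precision", "recall")]
#>   feature    acc precision recall
#> 1 combined 0.939         1  0.333
cv_roc(cv)
#> <phos_roc> AUC 0.9948 (30 positives, 300 negatives)
```

LOOCV with the combined score retrieves a third of the planted sites at
perfect precision (accuracy 0.94 against the 0.91 all-negative baseline
of a 10:1 set), and ranks nearly every true site above the background
(AUC 0.99). `ablation(ref, sim = sim)` prints the same table for all
four feature levels; the methods vignette discusses why the indirect
re-ranking, by design faithful to its published decision rule, floods on
this kind of synthetic data while the direct scores do not.

The miniature worked example of the noise reducer is built in:

```r
fx <- figure1_fixture()
sc <- indirect_scores(indirect_matrix(fx$query, fx$sim, fx$params$alpha),
                      fx$labels, fx$params$weight)
sc[["P2"]]
#> [1] 5.7       # 10 * (0.61 + 0.01) - 0.50
classify_peptide(fx$query, fx$sim, fx$params)[c("predicted", "confidence")]
#>   predicted confidence
#> 1      TRUE       0.75
```

A positive reference peptide with two positive partners (combined scores
0.61 and 0.01) and one negative partner (0.50) gets indirect score 5.70;
three of the top-4 peptides by indirect score are positives, so the query
is called a phosphosite with confidence 0.75.

For real data, `read_fasta()` + `read_sites()` + `build_ref_set()`
construct the reference set (optionally with `read_pssm()` profiles), and
`predict_sites()` scans query proteins, calling sites at confidence
≥ 0.5. A command-line driver with `simulate`, `build-ref`, `predict` and
`evaluate` subcommands is installed at
`system.file("scripts", "phoskin.R", package = "phoskin")`.

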