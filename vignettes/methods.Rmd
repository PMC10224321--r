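---
title: "Methods: models, synthetic worlds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic worlds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what is
modelled, which knobs matter, what the synthetic generators do and do
not emulate, and where genuinely open design questions were settled.
It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The evaluation problem

Given an assay-labelled sequence dataset — binders enriched by
magnetic (MACS) and fluorescence (FACS) sorting against a large naive
background, or proteins labelled with melting temperatures (Tm) — the
package evaluates how the choice of *sequence encoding*, *class
rebalancer*, and *ensembling strategy* affects discriminative model
quality, and ranks all alternatives over six confusion-matrix criteria
(F1, FPR, TPR, precision, NPV, FDR) with entropy-weighted TOPSIS,
validated by replicate-seed statistics.

## 2. Preprocessing model and assumptions

* **Frequency thresholds.** Reads appearing fewer than 10 times in MACS
  or 4 in FACS are background; the keep rule is the inclusive
  complement (≥ 10, ≥ 4). The stricter MACS bound reflects that
  magnetic sorting introduces more carry-over noise than FACS.
* **Hamming purge.** Naive-pool records within one substitution of any
  enriched sequence are discarded as likely sequencing errors. The
  purge is one-directional — enriched members are never removed — and
  compares against the *union* of the MACS/FACS survivors (whether the
  original procedure purged per pool is unknowable from the
  description; the union is the conservative superset).
* **Stability classes.** At working pH 7, Tm ≤ 35 °C is low-stability,
  Tm ≥ 60 °C high-stability; the gap in between is excluded from
  classification but kept for regression. `low_max < high_min` is
  enforced.

## 3. Encodings

* **One-hot**: 20·L indicators in fixed alphabetical channel order
  (ACDEFGHIKLMNPQRSTVWY); invertible; requires equal lengths.
* **Physiochemical panel (20 descriptors).** The exact descriptor
  enumeration of descriptor packages varies; this package's documented
  panel is: length, molecular weight, net charge at pH 7
  (Henderson–Hasselbalch, EMBOSS pKa set), charge density, isoelectric
  point (bisection on the charge curve), instability index (Guruprasad
  DIWV), aromaticity, aliphatic index, Boman index (negated mean
  residue interaction potential), hydrophobic ratio, mean Eisenberg
  consensus hydrophobicity, global Eisenberg hydrophobic moment
  (helix periodicity 100°), GRAVY (Kyte–Doolittle), window-7 Eisenberg
  max and min, per-residue Eisenberg SD, window-11 max hydrophobic
  moment, and acidic/basic/polar composition fractions. This is an
  *approximation* of any particular published panel and is flagged as
  such; scale tables are vendored CSVs with citations
  (`inst/extdata/scales/CITATIONS.md`). GRAVY, aromaticity,
  instability and molecular weight are pinned to independently
  computed reference values in the tests; pI uses the EMBOSS pKa set
  and is therefore tested by physical properties (zero charge at pI,
  acid/base ordering) rather than cross-package equality.
* **Embedding adapters.** Real protein language models (UniRep-like,
  ESM-like) are deliberately out of scope — no weights ship with the
  package. They enter through the `embedding_adapter()` contract
  (name, declared dimension, `embed` function). The deterministic
  `mock_adapter()` concatenates per-k blocks (k = 1, 2, 3) of
  hash-seeded random projections of k-mer counts. The k = 1 block is a
  random linear image of residue composition, so compositional signals
  are linearly recoverable — the property of real embeddings the test
  suite depends on. The hash is a 31-based polynomial mod 2³¹−1,
  exact in doubles, hence platform-stable.

## 4. Sampling

Stratified splits draw `round(f·n_c)` test rows per class, preserving
the population prevalence in the test set (equal-class test sets
overstate performance on imbalanced data). Defaults: test fraction 0.2
for classification, 0.3 for regression. Rebalancing always balances to
exactly 1:1 (the balanced-target ratio is not specified anywhere
authoritative; 1:1 is the convention) and is applied to *training rows
only*, after the split, independently within each encoding's feature
space (SMOTE interpolates in feature space) with the seed shared
across encodings for paired comparisons. SMOTE uses k = 5 minority
neighbours (the original convention), clipped to `n_minority − 1`; a
singleton minority class falls back to duplication with a warning.

## 5. Models

* **Classifier**: ridge-penalised logistic regression (glmnet backend,
  `alpha = 0`) at the single fixed penalty `lambda = 1/(n·C)`,
  `C = 1` by default — the regularisation strength and iteration caps
  are not documented for the original analysis, so defaults are
  declared here, not claimed. Standardisation (train statistics only)
  is on for dense encodings and off for one-hot indicator blocks,
  which are already on a common scale.
* **Regressor**: a random forest implemented in-package (no tree
  package exists in the target environment): bagged CART regression
  trees, per-node `mtry = p/3` feature subsampling, variance-reduction
  splits at midpoints of consecutive distinct values, minimum node
  size 10. Hyperparameters (tree count, max depth) are chosen by
  budgeted uniform random search (default 25 trials) scored by MSE on
  an internal 20% validation split — a generic replacement for any
  specific tuning framework, with the same two search dimensions.
  A degenerate split whose floating-point midpoint rounds onto a
  boundary value is converted to a leaf.
* **Replication harness**: for each seed, one stratified split is
  shared by all alternatives (paired design); failures are recorded as
  failed cells and never imputed; at least two seeds are required so
  downstream statistics have dispersion.

## 6. Ensembles

"Combining encodings by adding them together" is implemented as
feature-axis concatenation — the constituent widths (e.g. 20 / 1160 /
1900 / 1280) make elementwise addition undefined, so concatenation is
the only consistent reading, and it is flagged as an interpretation.
Majority voting trains one model per encoding and takes the strict
label majority on the shared test set; exact ties (even voter counts
only) are broken by mean positive-class probability ≥ 0.5 and flagged.
A three-voter panel never ties.

## 7. MCDA

The decision matrix holds per-alternative seed means of the six
criteria in fixed order (F1, FPR, TPR, precision, NPV, FDR) with signs
(+, −, +, +, +, −). Entropy weighting uses the sum-normalisation
`r_ij = x_ij/Σ_i x_ij`, entropies `E_j = −k Σ r ln r` with
`0·ln 0 := 0` and `k = 1/ln n`, and weights `w_j ∝ 1 − E_j`. The
TOPSIS distance stage uses the standard *vector* normalisation
(`v_ij = x_ij/√Σ_i x_ij²`) — the sum-normalisation belongs to the
entropy stage only; external TOPSIS implementations vary here, so the
choice is documented rather than assumed. Closeness is
`C = d⁻/(d⁺+d⁻)`; ties in the ranking break by alternative id.
Subjective weights default to precision = FPR = 0.20 and 0.15
elsewhere — a declared package default expressing "slightly higher
weight on precision and FPR", not a literature constant. Degenerate
matrices (all criteria uniform; all alternatives identical) raise
errors rather than returning arbitrary ranks.

## 8. Statistics

Classical one-way ANOVA (closed-form F), Bonferroni (`p·m` clipped at
1), Tukey HSD (base-R studentised range), and Pillai-trace MANOVA
(chosen over Wilks for robustness; configurable in principle) with a
per-metric Tukey follow-up producing one reject/fail decision per
(group pair, metric). α = 0.05 throughout — the conventional reading
where no level is stated. Because FDR = 1 − precision *exactly*, the
six-criteria within-group covariance is singular by construction; the
orchestration layer runs the joint test on the five independent
criteria and still reports the Tukey follow-up for all six. The test
suite calibrates the ANOVA type-I rate (5% ± 2% over 2000 null
replicates) and MANOVA null coverage (≥ 90% non-rejection over 100
null simulations).

## 9. The synthetic worlds

**Affibody-like library.** 58-residue Z-domain scaffold; 13 classic
helix-1/2 binding-surface positions variable by default (the cap is
17); substitutions uniform over the 20 canonical residues (the true
mutational distribution of any particular library is unknown; uniform
is the default and configurable). The planted fitness signal is
logistic in the mean Eisenberg hydrophobicity over the variable
positions (steepness 6, centred at the prevalence quantile), optionally
plus a pairwise epistatic bonus for consecutive hydrophobic variable
positions; labels are the top `floor(prevalence·n)` sequences by the
latent score plus Gaussian label noise (SD 0.3 logit units).
Prevalence defaults to 7%. Read tables: every positive is planted
above its pool threshold (MACS ≥ 10 or FACS ≥ 4, routed 40/40/20
MACS/FACS/both); background entries are corrupted copies of library
members (1–3 substitutions — a sequencing-error mimic) whose aggregated
counts are capped strictly below threshold so that recovery of the
planted set is exact by construction; ~2% of positives spawn a
naive-only hamming-1 near-miss to exercise the purge. These choices
were fixed once as a plausible desk-scale rendering of a sorted
combinatorial library; they do not emulate PCR bias, read-depth
variation between pools, or sequence-dependent error rates — a green
recovery test therefore establishes the correctness of the filtering
logic, not robustness to real sequencer noise.

**Stability table.** Per-record hydrophobic propensity
θ ~ U(0.2, 0.6); residues drawn from the hydrophobic set with
probability θ; `Tm = −10 + 150·frac_hydrophobic − 0.005·length +
N(0, 5)` °C, spanning roughly 20–80 °C so both stability classes are
populated; pH drawn from {5, 6, 7, 8} (7 always included). The linear
composition model is a deliberate simplification — real Tm depends on
structure and interactions — so regression tests establish the
pipeline's mechanics, not thermodynamic realism.

**Desk-scale problem sizes.** The acceptance run uses 4,000 library
members standing in for the original ~88,700: large enough that the
one-hot encoder (which must learn position-wise residue effects from
the rare positives) becomes competitive, small enough to keep the
whole planted-world criterion under two minutes. At this scale the
descriptor panel is the strongest single encoder — unlike the original
data, where one-hot and learned embeddings led — because the planted
signal *is* a descriptor (mean Eisenberg hydrophobicity) and the
library is 20–80× smaller.

## 10. Interface conventions

Positions (`variable_positions`) are 1-based, following R convention.
All stochastic functions take an explicit `seed` and run under a
saved-and-restored RNG state (Mersenne-Twister / Inversion /
Rejection), so identical seeds give byte-identical outputs across
platforms and user-level RNG state is never disturbed.

## 11. Known limitations

* No real language-model adapters; conclusions about embedding quality
  transfer only through the adapter contract.
* The regressor is a compact random forest, adequate at desk scale but
  not tuned for wide one-hot matrices on large data.
* Undefined metric ratios (e.g. precision with zero predicted
  positives) propagate as `NA` with a flag; a decision matrix
  containing such cells errors rather than guessing.
* A constant truth vector leaves R² undefined; rather than choosing an
  arbitrary value the package warns and returns `R2 = NA` alongside
  the (well-defined) MSE.
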