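# fitrank

Protein fitness prediction over enrichment-derived sequence data:
encodings, resampling, ensembles, and entropy-weighted TOPSIS ranking.

## The problem

Directed-evolution campaigns paired with deep sequencing produce
*assay-labelled* sequence datasets that are severely imbalanced: a few
thousand high-fitness binders hidden in tens of thousands of
non-functional variants (typically ~93% / 7%). Training discriminative
models on such data raises two coupled questions:

1. **How should sequences be represented?** One-hot indicators,
   physiochemical descriptor panels, or fixed-size language-model
   embeddings all encode different aspects of the sequence.
2. **How should the class imbalance be handled?** Undersampling, random
   oversampling, and SMOTE make very different bias/variance trade-offs.

Because the answer depends on several conflicting criteria at once
(F1, FPR, TPR, precision, NPV, FDR), `fitrank` treats the choice of
encoding × sampling × ensembling as a *multi-criteria decision problem*
and ranks the alternatives with TOPSIS, validated by ANOVA / Tukey /
MANOVA statistics over replicate seeds.

## What the package does

* **Synthetic data with known ground truth** — an affibody-style
  58-residue library with ≤17 variable positions, a planted
  hydrophobicity fitness signal, ~7% positive prevalence, and simulated
  naive/MACS/FACS read-count tables with sub-threshold background and
  one-hamming sequencing-error near-misses; plus a melting-temperature
  (Tm) stability table generator with an additive composition + length
  model.
* **Preprocessing** — cleaning (stop codons / invalid residues),
  pool-specific frequency thresholds (keep count ≥ 10 in MACS, ≥ 4 in
  FACS), pool merging, a one-hamming purge of naive near-misses, and
  pH / Tm class construction (low ≤ 35 °C, high ≥ 60 °C at pH 7).
* **Encoders** — one-hot (20·L indicators), a 20-descriptor
  physiochemical panel (H_Eisenberg, Boman index, GRAVY, charge, pI,
  instability, …), and a pluggable embedding-adapter contract with a
  deterministic mock adapter (hash-seeded random projection of k-mer
  counts) standing in for UniRep/ESM-style models.
* **Sampling** — prevalence-preserving stratified splits and the three
  rebalancers, with SMOTE implemented from its defining algorithm:
  synthetic minority rows `x + u·(x_nn − x)`, `u ~ U(0,1)`, `x_nn` one of
  the k nearest minority neighbours.
* **Models** — ridge (L2) logistic regression for classification and a
  random-forest regressor with budgeted random hyperparameter search for
  Tm regression; a multi-seed replication harness with a paired design
  (every alternative sees the same test set per seed).
* **Ensembles** — feature-axis concatenation and majority voting with a
  mean-probability tie-break.
* **Ranking** — the decision matrix of per-alternative seed-mean
  criteria is weighted either objectively, via Shannon entropy,

  ```
  r_ij = x_ij / Σ_i x_ij
  E_j  = −k Σ_i r_ij ln r_ij ,  k = 1/ln(n)
  w_j  = (1 − E_j) / Σ_j (1 − E_j)
  ```

  or subjectively (precision and FPR slightly up-weighted), then ranked
  by TOPSIS closeness `C_i = d⁻_i / (d⁺_i + d⁻_i)` to the ideal /
  anti-ideal alternatives.
* **Statistics** — one-way ANOVA, Bonferroni, Tukey HSD, and
  Pillai-trace MANOVA with a per-metric Tukey follow-up.

## Worked example

```r
library(fitrank)

cfg <- experiment_config(
  task     = "classification",
  affibody = affibody_sim_config(n_unique = 600, prevalence = 0.07, seed = 42),
  encodings = c("onehot", "physchem", "mock"),
  samplers  = c("under", "over", "smote"),
  ensembles = list(alternative(c("onehot", "physchem", "mock"), "smote", "vote")),
  seeds = 1:5)

run_experiment(cfg, "runs/demo")
write_report("runs/demo")
```

The report (abridged, actual output) shows the seed-mean criteria and
both rankings:

```
Per-alternative criteria (mean +/- sd over seeds):
  physchem_smote               F1=0.7028+/-0.0801 FPR=0.0446+/-0.0155 ...
  onehot_smote                 F1=0.3943+/-0.0661 FPR=0.0411+/-0.0257 ...
  onehot+physchem+mock_smote_vote F1=0.7085+/-0.1341 FPR=0.0268+/-0.0167 ...

TOPSIS ranking (entropy weights):
   1. onehot+physchem+mock_smote_vote C = 0.9866
   2. physchem_smote               C = 0.9378
   3. onehot_over                  C = 0.9171
   ...
TOPSIS ranking (subjective weights):
   1. onehot+physchem+mock_smote_vote C = 0.9202
   2. physchem_smote               C = 0.8944
   ...
Tukey decisions: 115 of 270 pairs rejected
```

Reading the numbers: on this synthetic library the majority vote over
the three encodings tops both weighting schemes, SMOTE beats
undersampling within every encoding, and the purely hydrophobicity-based
planted signal makes the physiochemical panel the strongest single
encoder at this (small) data size. The closeness coefficient `C` is 1
for an alternative coinciding with the per-criterion ideal and 0 at the
anti-ideal; the Tukey line counts rejected pairwise null hypotheses over
all (alternative pair, metric) combinations at α = 0.05.

## Command line

```sh
Rscript inst/cli/fitrank.R simulate affibody --out sim_dir --n 1000 --seed 1
Rscript inst/cli/fitrank.R run --task classification --out runs/full
Rscript inst/cli/fitrank.R report --out runs/full
```

## Scope notes

Real UniRep/ESM adapters are out of scope (no model weights ship with
the package); embeddings enter through the `embedding_adapter()`
contract, and the deterministic mock adapter is used throughout the
tests. See `vignettes/methods.Rmd` for the modelling assumptions, the
synthetic-data design, and known limitations.
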