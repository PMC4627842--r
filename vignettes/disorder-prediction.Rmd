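---
title: "Predicting intrinsically disordered residues with idpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intrinsically disordered residues with idpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Intrinsically disordered regions (IDRs) are stretches of a protein chain
that lack a stable three-dimensional structure in isolation.  They are
common — roughly a quarter of residues in curated disorder datasets are
disordered — and functionally important, but they are invisible to
structure-based annotation, so sequence-based prediction is the standard
route.  `idpred` is a per-residue binary classifier: given a chain, it
emits for every residue a disorder probability and a binary order/disorder
call.

Residue labels take three states throughout: `O` (order), `D` (disorder)
and `U` (unknown).  Unknown residues are never used for training or
scoring, but they are kept in place during featurization so that their
neighbours' sliding windows are built from the true chain context.

## The feature encoding

Each residue is described by 56 features, concatenated in a frozen order:

| block | size | content |
|---|---|---|
| AA | 1 | amino-acid identity mapped to 20 evenly spaced values in \[-1, 1\] (alphabetical: A = -1, Y = +1) |
| PP | 7 | physicochemical parameters (steric/graph-shape index, polarizability, volume, hydrophobicity, isoelectric point, helix and sheet propensity), z-standardized over the 20 residues |
| PSSM | 20 | the residue's profile row of PSI-BLAST log-odds, divided by 9 |
| SS | 3 | predicted helix/sheet/coil probabilities |
| ASA | 1 | predicted relative solvent accessibility |
| Φ/Ψ | 2 | predicted backbone torsion-angle fluctuations |
| MG | 1 | monogram conservation value of the residue's type |
| BG | 20 | bigram row of the residue's type |
| T | 1 | graded terminal indicator |

The monogram/bigram block summarizes fold-level conservation.  With the
normalized profile $P \in \mathbb{R}^{L\times 20}$ and $E_{tj} =
\exp(P_{tj})$:

$$mg_j = \frac{1}{e^6}\sum_{t=1}^{L} E_{tj}, \qquad
  bg_{ij} = \frac{1}{e^6}\sum_{t=1}^{L-1} E_{ti}\,E_{(t+1)j}.$$

A residue of type $a$ receives $mg_a$ and the row $bg_{a\cdot}$, so equal
types within one chain share MG/BG features.  On realistic profiles of
typical chain length the pooled raw sums are approximately log-normal with
log-median near 6 — `mgbg_distribution()` reports this diagnostic — which
is why $e^6$ is the normalizer.  Whether the per-residue bigram features
should be the row $bg_{a\cdot}$, the column $bg_{\cdot a}$, or a
pair-with-successor lookup is not determined by the method description we
follow; the row lookup is implemented because it is the simplest
type-indexed choice consistent with the feature count.

The terminal indicator encodes the five residues at each end (N-terminal
$-1.0 \dots -0.2$, C-terminal $+1.0 \dots +0.2$, 0 elsewhere); terminal
residues are disorder-prone, and the graded value tells the classifier how
deep into the chain a position sits.  For chains shorter than ten residues
the two sets can collide; the C-terminal value wins, an arbitrary but
frozen tie-break.

A residue's row in the design matrix is the concatenation of the 56-vectors
of the $W$ residues centred on it ($W$ odd; default 21, giving $21 \times
56 = 1176$ columns).  Windows extending past a chain end are padded with
zero blocks — a neutral choice, since every feature column is subsequently
scaled to $[-1, +1]$ by per-column extrema *fitted on training rows only*
(`fit_scaler()`/`apply_scaler()`; constant columns map to 0, unseen data
may exceed the range and is not clipped).

## The classifier

The classification layer is a soft-margin support vector machine with the
radial basis kernel $k(u, v) = \exp(-\gamma\,\|u - v\|^2)$, fitted through
libsvm (the `e1071` binding).  Disordered residues are the positive class.
Because ordered residues outnumber disordered ones roughly 3:1, disorder
rows are duplicated in the training fold (`oversample` copies in total,
default 2); evaluation rows are never duplicated.

The optimization layer selects $(C, \gamma)$ by grid search over powers of
two — $C \in 2^{\{-5,-3,\dots,15\}}$, $\gamma \in 2^{\{-15,-13,\dots,3\}}$
— scored by stratified 5-fold cross-validated balanced accuracy.  Balanced
accuracy is the criterion because plain accuracy is dominated by the
majority class at this imbalance.  A full grid search on all training rows
is prohibitively slow, so it runs on a seeded uniform 5% subset of the
training rows; ties break toward the smallest $C$, then the smallest
$\gamma$, preferring the smoother model.  The defaults $(C, \gamma) = (2,
2^{-7})$ are the window-21 optimum this search finds.

Disorder probabilities come from a sigmoid (Platt) calibration
$p = 1/(1 + e^{Af + B})$ fitted on decision values $f$ collected by a
seeded internal 5-fold cross-validation over the training set, minimizing
the calibration log-loss with Platt's smoothed targets.  Two numerical
choices matter here:

* the calibration cross-validation runs on a stratified subsample of at
  most `calib_max` rows (default 5000).  The sigmoid has two parameters;
  a few thousand held-out decision values determine it stably, and the cap
  bounds the cost of the five extra kernel fits on large training sets;
* calibration is implemented in R rather than through libsvm's internal
  probability machinery because the latter draws from a C random stream
  that cannot be reseeded from R, which would break the package's
  contract that identical inputs, hyperparameters and seeds give
  byte-identical prediction files.

The binary call is a pure threshold on the probability: $p \ge 0.5$ (or a
user threshold) is disorder, ties going to disorder.

## Evaluation

`binary_metrics()` computes the CASP-style binary suite from a confusion
table with disorder positive: SENS $= TP/N_d$, SPEC $= TN/N_o$, balanced
accuracy ACC $= (SENS + SPEC)/2$, precision PPV, Matthews correlation
coefficient, and the prevalence-weighted score

$$S_w = \frac{w_d\,TP - w_o\,FP + w_o\,TN - w_d\,FN}
             {w_d\,N_d + w_o\,N_o},
  \quad w_d = \frac{N_o}{N_o+N_d},\; w_o = \frac{N_d}{N_o+N_d},$$

which algebraically equals $2\,\mathrm{ACC} - 1$; the test suite asserts
the identity to $10^{-12}$ over random tables.  Metrics with a zero
denominator are reported as `NA`, never silently as 0, so they cannot
corrupt fold averages.

`roc_auc()` computes AUC by the rank (Mann–Whitney) formulation with mean
ranks on ties — the suite checks it against an exhaustive pairwise-ranking
oracle — and a 95% confidence interval by stratified percentile bootstrap
(default 2000 replicas, seeded; positives and negatives resampled
separately).  Content-level error is summarized by `content_mae()`, the
mean absolute difference between actual and predicted per-chain disorder
fractions.

`cross_validate()` supports two fold constructions (`make_folds()`):
*residue-level*, global residue index mod $k$, and *sequence-level*, chain
index mod $k$ with all of a chain's residues travelling together.
Residue-level splitting can in principle leak information between folds
through overlapping windows; the analytic probability of such an overlap,
$(100/9)\,(W-1)/(N^2 \mathcal{L})$ for $N$ chains of expected length
$\mathcal{L}$, is exposed as `overlap_probability()` and is of order
$10^{-6}$ at realistic dataset sizes — documented, not corrected for.
Within each fold the scaler and the oversampling are refitted on the
training portion only.  Both per-fold mean ± SD and pooled-count views are
reported, along with per-fold AUCs and the pooled AUC, since either
convention appears in the assessment literature.

## Post-hoc diagnostics

* `composition_profile()` compares the amino-acid composition of truly
  versus predictedly disordered residues (20-vectors $r_a$, $r_p$), with
  RMSE and Pearson correlation.  The correlation is computed over only 20
  points, so its significance is reported but never asserted in tests.
* `region_stats()` characterizes contiguous same-label regions by mean
  predicted coil probability and the fraction of residues with relative
  accessibility strictly above 0.25, after discarding 5 residues from each
  terminus (terminal residues are surface-biased and conformationally
  atypical).
* `mgbg_distribution()` pools raw monogram/bigram values in log space and
  reports their medians against the expected value 6.

## The synthetic-data generator

`simulate_dataset()` exists so the entire pipeline — file formats,
featurization, training, evaluation, diagnostics — is exercisable with no
external database or upstream predictor.  It emulates, per chain:
alternating ordered/disordered runs with ~24% disorder prevalence and a
70/30 short (≤ 30 residues) / long (31–90) mix of disordered regions;
disordered-segment composition enriched in D, G, S, E, K, P and depleted
in hydrophobics; PSSM log-odds (integers clipped to ±13) whose column
means differ by state — native-residue conservation is weaker, and
disorder-prone columns drift up, inside disordered segments; coil
probability (+0.45), accessibility (+0.35) and torsion fluctuations
elevated in disorder; and a 5% unknown-label rate to exercise the
exclusion logic.  A single `signal` knob in \[0, 1\] scales *every*
state-dependent shift, so `signal = 0` produces two statistically
identical states (a null dataset on which any predictor must score AUC ≈
0.5) and intermediate values give intermediate learnability; the test
suite checks that cross-validated AUC is monotone across signal 0, 0.5, 1.
Default sizes are 50 chains of mean length 400 (SD 100), the typical scale
of curated disorder datasets.

What the generator does **not** emulate: real evolutionary profile
statistics beyond first moments (no phylogenetic correlation, no
position-specific conservation patterns), sequence complexity structure,
or annotation noise between experimental sources.  Passing the synthetic
end-to-end suite therefore demonstrates that the machinery is correct and
that the classifier recovers a signal of the assumed form — it does not
certify accuracy on real proteins, which depends on upstream profile and
secondary-structure predictors outside this package's scope.

## Validation problem sizes

The package's end-to-end validation (in the test suite) simulates 100
chains of mean length 150 at full signal, runs the grid search on a 5%
subset and a 10-fold residue-level cross-validation with a window of 7,
and requires pooled AUC ≥ 0.95 and MCC ≥ 0.8; the matching null run at
signal 0 must land within 0.05 of AUC 0.5.  A window of 7 is used there —
the synthetic disorder signal is strongly local, so the wider default
window adds columns without adding information; real profile data is where
the window sweep up to 21–25 earns its keep.  The null measurement is a
5-fold chain-level rotation pooling out-of-train predictions: within-chain
label runs correlate residues, so a single holdout estimates the null AUC
with too much variance, while pooling over five independently trained
models does not.  Each null fold trains on a capped stratified subsample
(3000 rows), since an RBF fit on inseparable data grows support vectors —
and solver time — roughly linearly in n without changing the conclusion.

## Known limitations

* Upstream inputs (PSSMs from an iterated profile search, predicted
  secondary structure, accessibility and torsion fluctuations) are
  consumed, not produced; prediction quality on real chains is bounded by
  their quality.
* The model archive is R-native serialization with a format-version
  string; it is portable across platforms but not across incompatible
  major R serialization versions.
* The seven physicochemical parameters are one widely used choice among
  several; `assemble_features()` accepts any replacement 20 × 7 table.
* Chains shorter than the trimming margin are skipped by `region_stats()`
  with a warning rather than scored.
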