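---
title: "Two-layer enhancer classification: model, feature selection, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-layer enhancer classification: model, feature selection, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancr)
library(dplyr)
```

## The problem

Enhancers are cis-regulatory DNA elements that increase transcription of
target genes, often from a distance, and they differ in regulatory activity:
chromatin-state segmentations distinguish strong from weak enhancers.
`enhancr` formulates both questions as binary sequence classification over
fixed-length DNA fragments (200 bp by convention, matching nucleosome plus
linker length):

* **Layer I** — is a fragment an enhancer or not?
* **Layer II** — given an enhancer, is it strong or weak?

The two layers are trained as separate models with their own feature subsets
and SVM operating points, because the sequence properties that separate
enhancers from background differ from those that separate strong from weak
enhancers — in particular, overall C-composition discriminates strongly in
layer I but carries almost no layer-II information, which is the empirical
motivation for the cascade design.

## Feature families

All features are frequencies in $[0, 1]$; no rescaling is applied before the
SVM (an optional min–max rescale exists for user data on other scales).

**Bi-profile Bayes (BPB).** Given positive and negative training sequences
of common length $n$, the per-position nucleotide frequencies are estimated
separately in each class. A sequence $s$ is encoded as
$V = (p_1, \dots, p_n, p_{n+1}, \dots, p_{2n})$ where $p_i$ is the frequency
of base $s_i$ at position $i$ among the *positive* training sequences and
$p_{n+i}$ the frequency among the *negative* ones. The frequency is used as
the posterior probability estimate, which is adequate at benchmark sample
sizes; an optional additive smoothing pseudocount `alpha` (default 0, i.e.
raw frequencies) is exposed because very small classes otherwise produce
many exact zeros. At $n = 200$ this family contributes 400 features.

**Nucleotide composition (NC).** The normalised single-base frequencies in
the fixed order (A, T, G, C); 4 features summing to 1.

**Pseudo-nucleotide composition (PseNC).** The frequencies of the 64
overlapping trinucleotides in lexicographic order, counts over the $n - 2$
sliding windows divided by the number of windows, so the vector sums to 1.
The normalising denominator is the overlapping-window count $n-2$: that is
the standard $k$-mer-frequency reading and the one that makes the vector a
probability distribution.

Together the three families give $2n + 4 + 64$ features — 468 at
$n = 200$. (Method descriptions in the literature occasionally quote 472
for this feature set; the per-family definitions above sum to 468, and the
implementation follows the definitions.)

## F-score ranking and the wrapper schedule

For feature $i$ with overall mean $\bar{x}_i$, class means $\bar{x}_i^+$,
$\bar{x}_i^-$ and class sizes $n^+$, $n^-$:

$$
F(i) = \frac{(\bar{x}_i^+ - \bar{x}_i)^2 + (\bar{x}_i^- - \bar{x}_i)^2}
       {\frac{1}{n^+ - 1}\sum_k (x^+_{k,i} - \bar{x}_i^+)^2 +
        \frac{1}{n^- - 1}\sum_k (x^-_{k,i} - \bar{x}_i^-)^2}
$$

A greater F-score means greater between-class separation relative to
within-class scatter. Two degenerate cases are defined explicitly: a feature
constant across all samples (numerator and denominator both zero) scores 0;
a feature constant *within* each class but different *between* classes
(denominator zero, numerator positive) scores `Inf` and ranks first. Equal
scores are broken by original column index, so the ranking is a
deterministic permutation.

`run_full_selection()` executes the published schedule per layer:

1. **BPB coarse scan** over F-score thresholds $w$ (default step
   $\Delta w_1 = 0.001$): keep features with $F \ge w$, evaluate by
   jackknife accuracy, take the best threshold (ties towards the larger
   threshold, i.e. fewer features).
2. **BPB fine scan** over the number of top-ranked dimensions around the
   coarse optimum (default step $\Delta w_2 = 2$, span ±10; ties towards
   fewer dimensions).
3. **NC greedy add-one**: NC candidates in descending F-score order, each
   kept iff accuracy strictly improves (`accept = "gte"` relaxes this to
   ties; up to `nc_k_max = 4` trials).
4. **PseNC coarse scan** (default $\Delta w_3 = 0.01$) and
5. **PseNC fine scan** (default $\Delta w_4 = 2$), each evaluated jointly
   with the already-selected features and accepted only on improvement.

Accuracy is the sole selection criterion; Sn, Sp and MCC are logged in the
trajectory but never drive a decision. Because every combination stage is
accept-on-improvement, the final accuracy is non-decreasing across stages —
a property the test suite asserts. Evaluations are memoised on the feature
subset, so a fine threshold grid costs no more than the number of *distinct*
subsets it induces.

Two caveats are deliberate and worth knowing:

* **Selection uses the same jackknife it reports.** The published protocol
  selects features by jackknife accuracy on the full dataset and reports
  that same accuracy, which is optimistically biased. The package reproduces
  this protocol (it is what the scan trajectories mean), and the evaluator
  is pluggable — `kfold_evaluator()` gives a cheaper inner loop, and an
  outer hold-out around `run_full_selection()` is the statistically sound
  way to estimate generalisation of the *selected* model.
* **Scan bounds are configuration.** Only the informative threshold windows
  are conventionally reported, not the scan bounds; defaults span zero to
  the largest finite F-score.

## The SVM and its parameters

Both layers use a C-SVM with RBF kernel $\exp(-\gamma\|x - x'\|^2)$ (libsvm
via `e1071`). The published operating points are preserved as
`layer_svm_defaults()`: $C = 0.35355 = 2^{-1.5}$ for both layers,
$\gamma = 0.03125 = 2^{-5}$ for layer I and $\gamma = 1.4142 = 2^{0.5}$ for
layer II. `grid_search()` reproduces the conventional selection procedure:
both parameters over the powers-of-two lattice $2^{-8}, 2^{-7.5}, \dots,
2^{8}$, scored by stratified 15-fold cross-validation accuracy, ties towards
smaller $C$ then smaller $\gamma$.

Those numeric operating points were tuned to one specific benchmark. For any
other dataset — including synthetic ones — the appropriate default is
`svm_config(C = 1, gamma = "scale")`, which computes the standard scale
heuristic $\gamma = 1/(d \cdot \widehat{\mathrm{Var}}(X))$ on the training
features at fit time. This matters more than it may look: frequency features
concentrate in a narrow band, so a fixed small $\gamma$ can make the kernel
nearly constant, and a near-constant SVM predicts the training majority
class. Under leave-one-out with balanced classes the training majority is
always the *other* class, so an underfit model scores near 0% rather than
near 50% — a well-known LOOCV artifact, worth recognising before reading
any jackknife number.

## Evaluation

`jackknife()` (leave-one-out) and `kfold()` (stratified) report Sn, Sp, Acc
and MCC recomputed from explicit confusion counts; `MCC` uses the standard
Matthews definition with the value defined as 0 when any denominator factor
vanishes, and Sn/Sp raise an error rather than silently reporting 0 when a
class is absent. With `k` equal to the dataset size, `kfold()` is exactly
the jackknife, prediction by prediction.

Two jackknife modes exist because the BPB encoding is fit on training
labels:

* `paper_literal` — BPB frequencies fit once on the complete dataset. This
  is the convention under which published jackknife figures for this method
  family are computed, and is the mode to use when reproducing them. It
  leaks the held-out sequence's bases into its own features; on small
  datasets the inflation is substantial.
* `leakage_free` (default) — BPB refit in every fold with the held-out
  sequence excluded (NC and PseNC do not depend on labels and are encoded
  once). An instrumentation hook (`fold_hook`) lets tests assert that the
  held-out sequence never enters training.

Positive-class conventions: layer I positive = enhancer, layer II positive =
strong enhancer.

## The synthetic generator

No benchmark data ship with the package; `generate_dataset()` produces
datasets in which every pipeline stage has a controllable, known signal. The
defaults mirror the published benchmark's shape: 742 strong enhancers, 742
weak enhancers, 1484 non-enhancers, 200 bp, i.i.d. uniform A/C/G/T
background. Three signal kinds are planted, all scaled by a global
`effect_size` in $[0,1]$:

* **Positional biases** (BPB-detectable): the default boosts one base by
  0.35 at ten positions in the first half of the fragment for both enhancer
  classes (the layer-I contrast) and, independently, at ten second-half
  positions for strong enhancers only (the layer-II contrast) — mirroring
  the observation that the two layers need different features.
* **Composition shift** (NC-detectable): +0.06 on C in enhancers,
  compensated equally on the other bases, emulating the C-enrichment of
  enhancers relative to non-enhancers.
* **Trinucleotide enrichment** (PseNC-detectable): ATA, TAT and GGC doubled
  in enhancers and CAG, AGG in strong enhancers — drawn from the
  trinucleotides reported informative for both layers. Enrichment is planted
  by overwrite-insertion: a Poisson number of occurrences per sequence,
  calibrated so the expected count matches the multiplier times the
  background expectation. This controls the enrichment in expectation (all
  tests need) with an exactly calibrated null at effect 0, and is simpler
  than resampling windows until a tilt target is met.

At `effect_size = 0` every class is an exchangeable draw from the
background, which makes null calibration analytic: F-score exceedances
against a permuted-label reference sit at the nominal rate, and leave-one-out
accuracy of any adequately specified downstream model sits near 0.5 (the
test band is 0.40–0.60, i.e. roughly ±3 binomial standard deviations at 200
sequences, noting the slight downward LOOCV bias discussed above).
`truth_report()` lists the planted features — including trinucleotides only
indirectly perturbed by a composition shift, flagged `indirect` — so signal
recovery can be scored mechanically.

What the generator does **not** emulate: chromatin-state segmentation,
cell-line heterogeneity, sequence redundancy structure (the real benchmark
was de-duplicated at 0.8 identity), genomic background composition, and
motif grammar beyond single planted trimers. Passing tests on synthetic data
therefore demonstrate the *pipeline's* correctness and calibration, not
field performance on real enhancers.

## Degenerate inputs and numerical policies

* Ambiguity codes (N, IUPAC): rejected by default with the offending record
  and position named; under `ambiguity = "mask"` the position contributes to
  no count — BPB lookups return the uniform 0.25, NC and PseNC denominators
  shrink to the unambiguous bases/windows.
* Soft-masked (lowercase) input is uppercased on read and treated
  identically.
* Labels come from per-class FASTA files or a `path`/`label` manifest,
  never from FASTA header parsing.
* BPB columns with an entirely masked position fall back to the uniform
  distribution; fitted columns otherwise sum to 1 within 1e-12.
* All scans, folds and the generator are deterministic given their seeds;
  libsvm training is deterministic given data order.

## Problem sizes used by the test suite

The bundled tests and the acceptance script run entirely on generated data,
sized so the whole suite completes in a few minutes on one core: encoder and
F-score oracle checks on sequences up to 12 bp and matrices up to 20×10;
null calibration and signal recovery on 100+100 sequences of 60 bp; the full
jackknife-driven selection schedule on 100+100 sequences of 60 bp with scan
steps of 0.02 (the scan machinery is step-agnostic; the published step sizes
remain the defaults); and the cascade on a 400-fragment training set with a
held-out 160-fragment draw. The monotone-accept property, the metric
identities, and the jackknife/n-fold equivalence are size-free and hold at
any scale.

## Limitations

* The wrapper selection inherits the published protocol's optimism when its
  jackknife accuracy is read as a generalisation estimate (see above).
* PseNC is exactly overlapping 3-mer composition; no higher-order $k$-mers,
  gapped pairs, or physicochemical pseudo-compositions.
* The cascade's layer-I decision is the sign of the SVM decision value; no
  probability calibration or rejection band is applied to marginal calls.
* Published accuracy figures for the original benchmark cannot be verified
  without that benchmark's FASTA files; with them, `paper_literal` mode,
  `layer_svm_defaults()`, and per-layer feature counts of 114 and 99
  reproduce the published protocol end to end (see the README's reproduction
  notes).
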