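---
title: "Predicting tailed-phage capsid architecture: models and methods"
author: "capsidarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tailed-phage capsid architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidarch)
```

## The problem

Tailed bacteriophages protect their double-stranded DNA genomes in
icosahedral protein capsids whose surface lattice is indexed by the
triangulation number T. Environmental sequencing recovers phage genes in
vast numbers but says nothing directly about the capsid that carried
them. `capsidarch` bridges that gap: it predicts the capsid architecture
(T-number) of a tailed phage either from its genome length or from the
amino-acid sequence of a single gene, the major capsid protein (MCP).

## Icosahedral lattice mathematics

The classic theory counts quasi-equivalent positions on an icosahedral
surface: two neighbouring pentamers are separated by lattice steps
$(h, k)$, giving

$$T_0(h, k) = h^2 + hk + k^2,$$

and $60\,T_0$ major capsid proteins. Tailed phages realize two lattice
classes. On the *hexagonal* lattice $T = T_0$. On the *trihexagonal*
lattice, $60\,T_0$ minor capsid proteins inserted as trimers add surface
area, so $T = \tfrac{4}{3} T_0$; the factor 4/3 is why fractional
T-numbers (1.33, 5.33, 9.33, 17.33, ...) occur. `enumerate_architectures()`
lists every realizable (T, lattice) pair up to `t_max` (default 60,
which covers T = 52, the largest solved structure, with margin) using a
canonical representative $h \ge k \ge 0$; chirality is not
distinguished because nothing downstream depends on handedness.
T-values are held as exact numbers internally and formatted with two
decimals only for display.

## The allometric genome-to-T (G2T) model

Across tailed phages the genome is packed at near-crystalline, roughly
constant density, and each capsid protein occupies a roughly constant
exterior area. For a quasi-spherical shell of radius $R$ this gives
$T \propto R^2$ (surface) and $G \propto R^3$ (volume), hence
$T \propto G^{2/3}$ (`theoretical_exponent()`). Empirically the model is
the power law

$$\ln T = a \ln (G / G_0) + \ln b, \qquad G_0 = 1\ \text{kbp},$$

fitted by ordinary least squares in natural-log space (`fit_g2t()`). On
the packaged 37-structure high-resolution table the fitted exponent is
$a \approx 0.71$, close to but slightly above 2/3 — consistent with
head-full packaging strategies storing somewhat more DNA than the
genome length. Predictions back-transform directly,
$T = b\,(G/G_0)^a$, with no smearing correction: the model is used as a
point predictor whose error is quantified empirically (below), and a
bias correction would silently change the assignment intervals.

### Functional-form control

`compare_alternative_models()` refits T against G under four alternative
two-parameter families (exponential $b e^{aG}$, quadratic
$c_0 + c_1 G^2$, reciprocal $c_0 + c_1 / G$, logarithmic
$c_0 + c_1 \ln G$) and compares coefficients of determination computed
on the raw T scale for every model, so the comparison is
scale-consistent. The two-parameter quadratic form keeps the comparison
parallel — a three-parameter polynomial would win on flexibility alone,
which is exactly the over-fitting the control is meant to expose. On the
high-resolution table the power law attains the highest T-scale $R^2$.

### Error model

`mre_curve()` estimates the mean relative error (MRE) by repeated
random subsetting: draw $n$ records without replacement, fit, predict T
for the held-out records, accumulate $|T_{pred} - T_{emp}|/T_{emp}$.
The relative error is taken in absolute value; a signed mean would
cancel opposite residuals and understate the error, and only the
absolute reading is consistent with quoting a single percentage error.
The MRE as a function of training size is fitted to

$$\mathrm{MRE}(n) = p\,e^{-qn} + w$$

by robust least squares (`fit_error_decay()`). We use a soft-L1 loss
(quadratic near zero, linear in the tails, scale 1): "robust least
squares" fixes the family, not the loss, and soft-L1 degrades
gracefully to ordinary least squares on clean data, which is what makes
the noiseless-recovery tests exact. Confidence intervals come from a
percentile bootstrap over the $(n, \mathrm{MRE})$ points. On the
packaged table the asymptote is $w \approx 0.09$: the genome length
predicts T with about 91% accuracy and more structures are not expected
to improve it.

### Architecture assignment

`assign_architecture()` converts a continuous prediction into a
discrete call: candidates are every enumerated T-value inside
$T_{pred} \pm T_{pred}\cdot\mathrm{MRE}$; the selected architecture is
the nearest candidate, with ties broken in favour of the hexagonal
lattice and then the smaller $T_0$ (hexagonal capsids are the majority
among solved structures, so it is the more probable call at equal
distance). When the interval contains no valid icosahedral T the capsid
is called `"elongated"` — a categorical fallback, not a prolate lattice
model. `t_to_genome_range()` is the exact inverse map, and the two are
kept mutually consistent by a property test.

## Genome-length density estimation

Isolate genome lengths are strongly multimodal with very different
local scales (a sharp mode near 40 kbp, broad structure above
270 kbp), so a single kernel bandwidth either over-smooths the narrow
modes or invents spurious ones in the tails. `multiregion_density()`
therefore selects a Gaussian-kernel bandwidth separately in each of
four genome-length regions (defaults 17–130, 130–210, 210–270,
270–498 kbp; configurable, since the grouping is a judgement call) by
5-fold cross-validated held-out log-likelihood over 30 log-spaced
candidates in [0.1, 30] kbp. Region densities are weighted by their
sample fraction — combining unweighted densities would give a tiny
region the same mass as the dominant one — summed on a common grid of
2,048 points (finer than the smallest plausible bandwidth) and
renormalized to unit trapezoid mass. `find_density_peaks()` reports
strict local maxima above a topographic prominence of 1% of the maximum
density, suppressing floating-point ripples; peaks are annotated with
their architecture assignment and tallied with
`tally_architectures()`.

## The MCP/T library

`build_library()` labels MCP sequences with T-numbers. Sequences are
selected from annotated genomes by a case-insensitive substring match
of "major capsid" against the CDS `/product` qualifier only (notes and
functions fields are too noisy), filtered by an external
structural-function score at the inclusive threshold 2 (~98%
true-positive confidence), and dereplicated to one representative per
identical sequence. Entries whose phage has a solved structure take the
structure's T-number; all others are labelled through the G2T model,
keeping alternative candidates. HK97-fold validation requires external
structure-modelling services and visual inspection, so entries carry an
externally supplied `hk97_validated` flag (defaulting to true with a
notice) rather than a re-implementation.

## The proximity-matrix (PM) classifier

`predict_nearest()` assigns a query the T label of its most similar
library sequence, subject to a minimum-similarity threshold.
Similarity is blastp-style percent identity: thresholds are expressed
in percent, so percent identity is the only consistent reading.
External blast tabular files are consumed directly
(`load_similarity()`, e-value ≤ 0.001, pairs symmetrized by the
maximum); alternatively `align_similarity()` computes Smith–Waterman
local alignments (BLOSUM62, gap open 11 / extend 1) and screens them
with a Karlin–Altschul e-value at the same 0.001 threshold — without
that screen, three-residue perfect local matches between unrelated
sequences would report 100% identity. Ties at equal similarity break
to the smaller T label, then lexicographic id, making evaluation
order-independent. `evaluate_pm()` reports coverage and accuracy per
threshold over repeated 80/20 splits; accuracy over zero calls is
undefined and reported as `NA`, never 0. The relative T difference in
`t_difference_by_bin()` uses the smaller T as denominator, which lets
the difference range asymmetrically above 100% — the convention under
which the largest observed differences are expressible.

## The random-forest (RF) classifier

`compute_features()` maps a sequence to 22 features: length,
isoelectric point, and the 20 amino-acid frequencies. Frequencies are
taken over canonical residues only (ambiguity codes are excluded from
numerator and denominator — an X carries no compositional
information). The isoelectric point is computed from first principles:
bisection on pH ∈ [0, 14] of the Henderson–Hasselbalch net charge with
a simplified Bjellqvist pKa set shipped as an editable data file
(`load_pka_table()`); the charge is monotone in pH, so bisection to
|charge| < 1e-4 is exact for practical purposes.

Classes are built by `build_class_scheme()`: T-values whose G2T genome
ranges overlap are merged (e.g. 9 with 9.33), all T ≥ 25 form one
jumbo class (large genomes are too sparsely sampled to separate), and
elongated is its own class. The forest (via `ranger`) uses 250 trees,
4 features per split, depth ≤ 20, minimum node size to split 46,
minimum terminal node 1, bootstrap resampling and balanced class
weights — the hyperparameter mapping is documented on
`train_classifier()`. Training and evaluation are single-threaded and
seeded, so every result reproduces bit-for-bit.

A prediction is scored correct when the predicted class's member T
closest to the entry's library T lies within 9% of it — the most
permissive reading of "within the margin of error", measured against
the library T (the predicted class has no unique center); elongated
must match exactly. `accuracy_vs_size()` and `fit_log_accuracy()`
quantify how accuracy grows with the training library under

$$\mathrm{MACC}(n) = g \log_{10} n + h,$$

again by soft-L1 robust least squares with bootstrap intervals, and
invert it ($n(A) = 10^{(A-h)/g}$) to project the library size needed
for a target accuracy. `feature_analysis()` provides permutation and
dropout importances; `clade_feature_profile()` flags features whose
clade mean departs from the library mean by more than one library
standard deviation.

## Synthetic data: what it emulates and what it does not

The generators in this package define the conditions under which the
pipeline is tested without any external download:

* `simulate_g2t_records()` — genome lengths log-uniform on
  [15, 500] kbp (the observed tailed-phage range), T-numbers
  $b G^a e^\varepsilon$ with lognormal noise. Defaults $a = 0.67$,
  $b = 0.5$, $\sigma = 0.1$: the theoretical exponent, a prefactor near
  the empirical fit, and noise of the order of the observed ~9%
  relative error.
* `simulate_genome_mixture()` — Gaussian mixtures for the multimodal
  length distribution.
* `simulate_mcp_classes()` — sequence classes separable by length and
  composition, with genome lengths back-computed from the class T
  through the inverse G2T map (2% lognormal jitter, small enough that
  library building round-trips the labels).

These sequences are i.i.d. draws from per-class residue weights. Real
MCPs are homologous, phylogenetically autocorrelated, and share the
HK97 fold; real class boundaries are far less clean. Passing tests on
synthetic data therefore demonstrate that the machinery is correct —
that separable classes are learned, that label permutation collapses
accuracy to chance, that coverage falls and accuracy rises with the
similarity threshold — not that any particular real-data accuracy is
reproduced. Results that depend on the full curated 635-sequence
library or on gut-metagenome downloads (PM accuracy near 70–75%, RF
accuracy near 74%, the 19-peak length distribution, the 18% elongated
fraction, the per-region bandwidths 1.78/3.33/1.39/20 kbp, and the gut
architecture frequencies) are documented here but are not asserted by
the test suite, which has no access to those data.

## Numerical choices and degenerate inputs

* OLS fits are closed-form and deterministic; resampling functions
  take a mandatory seed.
* The robust fits start from method-of-moments / OLS values, explore
  with Nelder–Mead and polish with BFGS; non-convergence warns with
  diagnostics rather than failing silently.
* KDE held-out log-likelihoods floor the density at the smallest
  positive double to avoid `-Inf` on far-out folds.
* Regions with fewer points than CV folds fall back to the smallest
  candidate bandwidth.
* Splits that miss a class are redrawn (with a message) rather than
  silently scored; a test-set class never seen in training is counted
  incorrect, never fatal.
* Sequences reduce to canonical residues before feature computation;
  a sequence with no canonical residue is an error.

## Problem sizes used by the shipped checks

The packaged test-and-verification workloads use the 37-record table
at 10,000 resampling repetitions for the headline error estimate and
1,000 repetitions per training size for the error-decay curve;
synthetic classifier checks use two classes of 30–60 sequences over
tens of splits. These sizes give Monte-Carlo noise comfortably inside
the asserted tolerances while keeping a full run in well under a
minute on a laptop.

## Known limitations

* "Elongated" is a fallback label; prolate dimensions and packing-
  strategy corrections are out of scope.
* The internal aligner approximates blastp percent identity; for exact
  parity, supply blastp tabular output.
* Fold validation (HK97) is consumed as an external flag, not
  computed.
* The G2T error floor (~9%) propagates into every library label made
  from a genome length; improving it requires features beyond genome
  length, not more structures.
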