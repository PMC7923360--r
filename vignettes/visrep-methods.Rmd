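---
title: "Methods: dataset curation and representational similarity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dataset curation and representational similarity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visrep)
```

`visrep` covers the full computational path from choosing ecologically
relevant image categories to deciding, with calibrated inference, whether
one trained model family matches human visual representations better than
another. This vignette explains the model behind each stage, the parameters
that matter, and the choices we made where the design was genuinely open.

## Lexical category selection

Nouns are scored by the frequency–concreteness index

$$\mathrm{FCI} = \tfrac12 \frac{f}{\max f} + \tfrac12 \frac{c}{\max c},$$

with $f$ a spoken-corpus occurrence count and $c$ the mean concreteness
rating on a 1–5 Likert scale. Frequency proxies how important a concept is
to speakers; concreteness restricts the set to things that can be
photographed. Normalisation is division by the table maximum — not min–max
scaling — so the word attaining both maxima scores exactly 1 and every word
with positive frequency or rating scores in $(0, 1]$. Defaults follow the
curation rule the index was designed for: a concreteness floor of 4.0 and
the 3,500 top-ranked candidates (`select_candidates()`).

Two details are underdetermined by the scoring rule and fixed here as
package policy: FCI ties are broken by higher concreteness and then
alphabetically, making the ranking a deterministic function of the table
contents (and hence invariant to row order); and entries with a missing
concreteness rating are dropped with a warning rather than imputed, since
an unrated word cannot be placed on the scale.

## Near-duplicate image detection

Within one category every image is reduced to a center square (side
`min(width, height)`), resized to 128×128 with bilinear interpolation, and
flattened channel-major. A per-category PCA keeps the smallest number of
components whose cumulative explained variance reaches 90%, and every
unordered pair whose component-score vectors correlate at Pearson
$r > 0.975$ (strict) is flagged. Flagged pairs are chained into clusters by
connected components — if a ≈ b and b ≈ c, all three are one duplicate
group even when a and c fall below threshold — and the largest-resolution
member of each cluster is kept, ties going to the smallest id.

Choices the procedure itself does not pin down: PCA operates on flattened
RGB vectors (a grayscale flag is available); correlation across PCA
components is unweighted; the resampling filter is bilinear. If the PCA
retains a single component, Pearson correlation over a length-1 vector is
undefined; we treat two 1-D scores as duplicates when they agree within
1e-9 and document this as a degenerate dialect. NSFW filtering removes a
record only when its externally supplied score strictly exceeds 0.8
(classifier not included), and category survival requires at least 700
images, inclusive.

## Dataset trimming

To rule out dataset-size confounds when comparing training sets, two
inventories are equated in category count and category-size distribution:
subsample the larger inventory to the common category count (uniformly,
seeded), sort both by category size (descending, ties broken by name),
pair rank-wise, and downsample the larger member of each pair to the
smaller one's count. The sorted size vectors of both outputs then equal the
element-wise minimum of the two sorted inputs — which makes the procedure
idempotent and the total removal count equal to the summed absolute
difference of the sorted vectors, two properties the tests verify on random
inventories. Which images are dropped is a uniform seeded draw
(`subsample_ids()`).

## RDMs and model scoring

A representational dissimilarity matrix (RDM) summarises a system's
response geometry: entry $(i, j)$ is $1 - r_{ij}$, the Pearson correlation
distance between the response patterns to stimuli $i$ and $j$, giving a
symmetric matrix with zero diagonal and entries in $[0, 2]$. Correlation
distance is the single supported metric; zero-variance patterns are
rejected by stimulus name, and non-finite activations are rejected rather
than imputed.

Models are compared to subjects by Spearman rank correlation (average ranks
for ties) of the strictly-upper triangles; per-instance scores are the mean
over subjects. No fitting or reweighting is applied anywhere — a model is
scored on the geometry it actually has. The noise ceiling's lower bound is
the mean, over subjects, of each subject's Spearman agreement with the
arithmetic mean RDM of the remaining subjects; it estimates what a true
model of the group-average representation could reach given inter-subject
variability. Averaging happens in dissimilarity space. One subtlety the
tests document: because of that averaging, the ceiling is invariant under a
common positive *scaling* of all dissimilarities but not under arbitrary
nonlinear monotone maps; the pairwise Spearman comparison itself is fully
rank-invariant.

## Inference over network instances

Training-set effects are tested on per-instance scores with a permutation
test that re-splits the pooled scores of both groups into groups of the
original sizes — under the null the training-set labels are exchangeable.
With $\binom{n_a + n_b}{n_a}$ distinct splits at or below
`exhaustive_limit` (default 10,000) every split is enumerated and the
two-sided p-value is exact: two groups of five give all 252 splits. Larger
designs fall back to Monte-Carlo sampling (default 10,000 draws) with the
add-one correction $(1 + k)/(B + 1)$, so a reported p can never be zero.
Layer-wise families are Bonferroni-corrected with `bonferroni()`. The test
is two-sided by default; instances are treated as unpaired (the re-split
ignores any pairing of initialisation seeds across groups).

Confidence intervals for a group mean use the percentile bootstrap over
instances (1,000 resamples, 95%). A known limitation, stated here because
the acceptance checks measure it: with very few instances (n ≈ 10) the
percentile interval undercovers — its half-width behaves like
$1.96\,s\sqrt{n-1}/n$ rather than the $t$-quantile — so empirical coverage
near 0.90 at nominal 0.95 is expected behaviour of this estimator, not an
implementation artifact.

The stimulus-wise decomposition applies the same Spearman comparison to one
RDM column at a time (diagonal removed), asking which stimuli drive a
model's fit. The animacy interaction test takes per-stimulus benefits
(score difference between two models) and compares animate against
inanimate stimuli; because the scientific hypothesis is directional
(benefits larger for animate stimuli), this test is one-sided, unlike the
layer-wise tests. Its null permutes animacy labels across stimuli.

Robust association between two sets of layer scores uses the
percentage-bend correlation with bend constant 0.2: each margin's most
extreme 20% of observations is bent toward the robust location estimate
before correlating, and the p-value uses the Student-t approximation with
$n - 2$ degrees of freedom. With clean data it tracks Pearson's r; a single
gross outlier cannot dominate it.

## Unit selectivity

A unit is face-selective when its responses to condition-A stimuli exceed
condition B under a one-sided Wilcoxon rank-sum test ("selective" is
directional), with Benjamini–Hochberg FDR applied across all units of the
whole network — not per layer — at $\alpha = 0.05$ on the adjusted values.
Per-layer percentages are compared across training sets by a paired
Wilcoxon signed-rank test over instances (paired by instance index, i.e.
seed order), Bonferroni-corrected over layers. Units constant in both
conditions carry no rank information and are never selective; layers where
all instance pairs tie give p = 1 by convention.

## Receptive-field arithmetic

Effective receptive fields follow the standard recursion: starting from
rf = 1, jump = 1, an operation with kernel $k$ and stride $s$ updates
rf ← rf + (k − 1)·jump, then jump ← jump·s; convolution precedes the
layer's pooling and the layer's RF is read after its last operation. The
kernel solver works front to back: given the kernels already fixed, it
picks the odd kernel minimising the absolute pixel error to that layer's
target (ties to the smaller kernel), where targets in degrees are converted
through px/deg = input\_px / fov\_deg with a 3° default field of view.
Greedy choice is optimal per layer given the prefix, and the achieved error
is bounded by the jump entering the layer (odd-kernel granularity); targets
unreachable even with kernel 1 clamp with a warning. The default pooling
layout disables max pooling in layers 1, 2, 5 and 6 of a 10-layer stack.
Published cortical pRF-size targets (V1 … mFUS at 0.75° eccentricity, plus
two extrapolated anterior stages) are required user input;
`placeholder_rf_targets()` provides a smooth documented stand-in for tests
and examples only, and the 0.75° eccentricity travels as metadata. Training
hyperparameters can be recorded in the exported architecture JSON for
provenance but are never executed.

## What the synthetic generators emulate — and what they do not

Every pipeline input has a seeded generator whose defaults encode the study
conditions the machinery is built for:

- `gen_lexicon()`: Zipf-law frequencies (exponent 1, sampled
  multinomially from a 10⁶-token corpus) with uniform concreteness on
  [1, 5] — the rank-frequency structure of subtitle corpora, without
  semantics (concreteness is independent of frequency here, which real
  norms are not).
- `gen_image_set()`: smooth low-pass noise images (bilinear upsampling of a
  6×6 random grid) at varied resolutions, with planted duplicates disguised
  by rescaling (0.5×/2×) or an aspect change (symmetric crop of the longer
  dimension, capped so the central square survives). Smoothness makes PCA
  similarity structure non-degenerate; these are not natural images, so
  passing tests show the dedup machinery is correct, not that the 0.975
  threshold is optimal for photographs.
- `gen_subject_rdms()`: subject activations = shared latent signal
  (standard normal, 30 features) + white Gaussian noise, RDMs computed from
  activations — so every generated RDM is valid by construction and the
  noise ceiling has a known monotone relationship to `noise_sd`. Real fMRI
  noise is neither white nor homogeneous across subjects.
- `gen_unit_responses()`: 50 stimuli per condition, planted units shifted
  by `effect_size` SDs in condition A, layers assigned round-robin.
- `gen_category_sizes()` / `gen_stimulus_metadata()`: uniform integer
  inventories and exact expansion of printed class compositions (the
  1,200-scene set: 312 animate / 888 inanimate; the 92-object set: 48
  animate / 44 inanimate).

All generators are bit-reproducible under a seed; none emulates natural
image statistics, hemodynamics, or trained feature hierarchies.

## Numerical choices and problem sizes

Monte-Carlo permutation p-values carry the add-one correction; comparisons
against thresholds use a 1e-12 guard so exact ties count as extreme.
Spearman ties take average ranks throughout. RDM symmetry is enforced to
1e-10 and tiny negative distances from rounding at $r \approx 1$ are
clamped to 0. In calibration simulations we use 999 Monte-Carlo
permutations, which makes the add-one p exactly attain the 0.05 grid point.

The validation suite sizes its simulations for a single CPU: type-I-error
and bootstrap-coverage checks use 1,000 replicates (5 + 5 instances
exhaustive, n = 10 bootstrap); noise-ceiling monotonicity uses 5 subjects ×
15 stimuli × 50 seeds per noise level; selectivity recovery uses 2,000
units × 20 seeds; de-duplication uses 200 base images + 20 planted
duplicates across 10 seeds. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bands while keeping the full suite in the
low minutes.

## Known limitations

- Correlation distance is the only RDM metric; no crossvalidated distances,
  no RDM whitening, no upper noise-ceiling bound (the analyses here use
  only the lower bound).
- The permutation test treats instances as unpaired; a paired design would
  need a sign-flip test not implemented here.
- Percentile bootstrap undercoverage at small n, as discussed above.
- The duplicate detector's threshold semantics (strict >, unweighted
  correlation over PCA scores) are faithful to the curation procedure it
  implements, not tuned for other image domains.
- Actual network training, forward passes, and image harvesting are out of
  scope: activations, scores and NSFW probabilities enter as data.
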