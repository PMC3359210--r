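---
title: "Methods: entropy-based segmentation and stain quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based segmentation and stain quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroseg)
```

## Overview

`entroseg` quantifies stain expression in two imaging settings: fluorescent
live-cell fields, where cells carry a blue stain over a gray background, and
IHC tissue images, where nuclei are stained with Haematoxylin and a DAB
chromogen marks antigen. Both pipelines share three stages — stain
unmixing, unsupervised entropy-based segmentation, and a foreground-mean
quantification score — and differ only in the stain matrix and the
segmentation variant.

## Stain model and colour deconvolution

The Lambert–Beer law gives the transmitted intensity of a stained specimen
as $I_1 = I_0 \exp(-\alpha c)$, so the optical density per RGB channel,
$\mathrm{OD} = \ln(I_0 / I_1)$, is linear in the amount of stain. Each
stain is described by a 3-vector of channel ODs, normalized to unit
Euclidean length; with the normalized matrix $A$ (stains in rows) a pixel's
OD row vector $D$ decomposes as $D = C A$, and the per-stain amounts are
$C = D K$, $K = A^{-1}$.

Numerical conventions:

* **Sign.** OD is computed as $\ln(I_0/I_1) \ge 0$ for absorbing pixels —
  the standard optical-density convention, so that OD grows with stain.
* **Clamp.** Intensities are clamped to $\ge 1$ count before the
  logarithm, bounding the OD at $\ln I_0$. This is invisible for ordinary
  8-bit content; it only truncates synthetic mixtures so dense that fewer
  than one count is transmitted.
* **Two-stain completion.** A 2-stain system (the fluorescence blue /
  background pair) cannot be inverted as a 2×3 array; it is completed to
  3×3 with the unit cross product of its rows, the established convention.
  The completion channel absorbs residual colour and is discarded on
  output.
* **Polarity.** Deconvolved amounts are re-expressed on the intensity
  scale, $v = (2^c - 1)\,e^{-C_i}$, so "no stain" is bright and stained
  pixels are dark. This keeps the downstream foreground-is-low mask coding
  consistent. `deconvolve(..., output = "concentration")` returns the raw
  amounts instead.
* **Incident intensity.** $I_0$ defaults to the channel maximum
  ($2^c - 1$); it is configurable because fluorescence backgrounds render
  gray rather than white. The built-in matrices are fixed constants; no
  stain-vector estimation from images is attempted.

## Maximum-entropy thresholding

Segmentation splits the stain-channel histogram
$P = \{p_0, \dots, p_{2^c-1}\}$ at the cutoff $j^\*$ maximizing an entropy
criterion over the two classes $A = \{0..j\}$ and $B$ (its complement).
The default criterion is the classical Kapur maximum-entropy form: the sum
of Shannon entropies of the *normalized* within-class distributions,

$$\psi(j) = \hat H(A) + \hat H(B), \qquad
  \hat H(A) = -\sum_{i \le j} \frac{p_i}{P(A)} \log \frac{p_i}{P(A)}.$$

The criterion algebra was a genuinely open design point: plausible
alternative readings of the class-entropy weighting insert
$-\log P(A) - \log P(B)$ terms or divide the class entropies by the class
masses. We evaluated these variants numerically on bimodal histograms
typical of stained images (a dark foreground mode near 30 and a bright
background mode near 220). Every variant carrying $-\log P(A)$ terms
drives the argmax toward an extreme bin — $-\log P(A)$ grows without bound
as the low class shrinks to a single tail pixel — and fails to separate
the modes, while the classical form cuts in the inter-mode gap. The
classical form is therefore the default (`criterion = "kapur"`); the
literal alternative algebra
$-\log P(A) - \log P(B) - H(A)P(A) - H(B)P(B)$ over raw bin probabilities
remains available as `criterion = "printed"` for comparison. Further
conventions: natural logarithms (the argmax is base-invariant); splits
with an empty class score $-\infty$ and are never selected; exact ties
take the smallest $j$ (determinism); histograms whose mass sits in a
single bin return that bin with a `degenerate` flag rather than erroring,
so batch runs survive blank fields. The binarized mask codes foreground
(stained, $i \le j^\*$) as 0 and background as $2^c - 1$.

## Multistage segmentation for IHC nuclei

Tissue images have at least three intensity populations in the
Haematoxylin channel — nuclei (dark), cytoplasm/stroma (middle),
background (bright) — and a single two-class cut routinely merges
cytoplasm into either side. The multistage variant proceeds:

1. Fixed equal-width quarters of the 8-bit range, boundaries
   $j_1 = 63$, $j_3 = 127$, $j_5 = 191$. We read "four equal
   sub-histograms" as equal-width intervals rather than equal-mass
   quartiles because the boundaries are produced by the division step
   itself, before any entropy computation.
2. A maximum-entropy point inside each quarter ($j_0, j_2, j_4, j_6$) on
   the renormalized sub-histogram. Quarters with no mass, or mass in one
   bin, contribute no boundary (the boundary collapses; with all mass in
   one quarter the procedure provably reduces to the single-stage
   threshold on that quarter, which the tests check).
3. The ordered boundaries quantize the image into up to eight layers.
4. A second maximum-entropy cut on the *layer-label* histogram selects
   the cut layer; layers at or below it (high stain) become nuclei. The
   polarity is a flag (`low_is_foreground`).
5. A majority (mode) filter with radius `r = 3` re-assigns each pixel the
   most frequent value in its $(2r+1)\times(2r+1)$ window, removing
   spurious isolated detections. Windows are clipped at borders (no
   invented padding); exact ties vote foreground, which favours
   recovering weak, low-contrast nuclei pixels. The filter is applied to
   the binary mask, not to the gray channel, keeping thresholding and
   cleanup separable.

**Known limitation — layer granularity.** The second-stage cut can only
fall on a layer boundary. When the middle population is large, its lower
tail below the nearest boundary is absorbed into the foreground: with
populations at means 40/140/240 (sd 8) the nuclei Dice is ≈ 0.95 when
nuclei occupy ≥ two-thirds of the cytoplasm mass but degrades to ≈ 0.93
when cytoplasm dominates 35 % vs 15 %. This is intrinsic to quantizing
before the final cut, and mirrors the moderate recall the approach
achieves on real tissue.

## Quantification score

The cell-replication score is the mean stain measure over foreground,
$s = \sum_{I^\*(m,n)=0} \mu(m,n) / \#\{I^\* = 0\}$. Reading the
normalizer as the *cardinality* of the foreground set is the only
well-defined interpretation (the foreground code itself is 0), and a mean
matches the intended invariance to cell count. Because the deconvolved
channel is intensity-like, the per-pixel measure defaults to the stain
magnitude $2^c - 1 - I_B$ so that more stain means a higher score; a
`polarity = "raw"` flag averages the channel directly. Properties (all
under test): invariance to replicating the foreground pattern at fixed
stain level; a uniform $+\delta$ stain shift moves the score by exactly
$\delta$; the score is bounded by the foreground magnitude range. The
per-cell variant averages per-cell means over 8-connected components,
weighting each cell equally regardless of area; both are provided since
they answer different questions, and they deliberately differ on unequal
cell sizes. Empty-foreground images yield a flagged, score-less record —
a 0 would silently mimic "no stain".

## Group validation statistics

Scores grouped by condition are compared with one-way ANOVA
(`stats::aov` decomposition) and two post hoc procedures sharing the
pooled variance: LSD (unadjusted pairwise $t$ with
$se = \sqrt{ms_w (1/n_i + 1/n_j)}$) and Tukey HSD via the studentized
range distribution (`stats::ptukey`, accurate well past the three
decimals reports print), in the Tukey–Kramer form that remains exact for
balanced designs. Zero within-group variance flags the table degenerate
instead of reporting an unstable F. `anova_from_ss` completes a table
from printed sums of squares, supporting desk verification of published
tables. P-values are kept at full precision; `format_p` mirrors the
conventional 3-decimal display with "< 0.001".

## Synthetic data: what it emulates, what it does not

`make_fluor_field` renders non-overlapping elliptical cells (mild
eccentricity jitter, rejection-sampled placement) over a uniform gray
background — fluorescence backgrounds are transparent and render gray.
Cells absorb multiplicatively along the blue-stain OD vector:
pixel $= g\,e^{-a\,v_{blue}}$ with $a = -\ln(1 - v/255)$ for a per-cell
stain magnitude $v \sim N(\mu_g, 8)$. Composing with the actual stain
vector guarantees the deconvolution stage is exercised, not bypassed, and
makes cells darker than background in the blue channel for any positive
stain. Defaults, chosen once as realistic study conditions: 256×256
fields (a computationally convenient stand-in for full-resolution
captures; all algorithms are resolution-agnostic), 30 cells of radius
6–12 px, background gray 200, additive Gaussian noise σ = 3 clipped to
range, group means 30/60/90 for low/mid/high stain conditions. The
returned `true_score` is computed by running the scorer on the noiseless
channel with the ground-truth mask, so fixture and scorer are
self-consistent by construction.

`make_ihc_composite` builds two-stain tiles with the Lambert–Beer forward
model and the Haematoxylin/DAB vectors: nuclei (ellipses, radius 5–10 px)
draw Haematoxylin 0.5–0.9 and DAB 0–0.3 concentration units; a diffuse
counterstain of 0.05 covers the background; noise σ = 2. Deconvolving a
noiseless composite recovers the concentration maps within quantization
error (≤ 0.02 OD, under test).

Neither generator simulates uneven illumination, chromatic aberration,
overlapping or touching cells, texture within cells, or out-of-focus
light. Passing tests on this material therefore demonstrates correctness
of the algorithms under their stated model — separable stains, distinct
intensity populations, spatially compact cells — not performance on real
tissue, where staining heterogeneity and nuclear overlap dominate the
error budget.

## Problem sizes and reproducibility

All generation is bit-reproducible from (spec, seed). The test suite and
the acceptance script use 256×256 images — nine IHC composites for the
precision/recall evaluation (mirroring a nine-core evaluation design) and
three groups of five fluorescence fields with per-image cell counts
varied over 10–30 for the end-to-end ordering check; these sizes were
chosen as the smallest at which the intensity populations are
well-resolved statistically. The pipeline itself is deterministic:
identical inputs and configuration give identical masks and scores, and
every run can persist its resolved configuration as JSON for provenance.
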