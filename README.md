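# entroseg

Automated quantification of stain expression in fluorescent live-cell and
immunohistochemistry (IHC) microscopy images.

## The problem

In live-cell fluorescence imaging of cultured cells, the stain level of a
field of view carries biological signal (for example, blue-stain intensity
is negatively correlated with cell replication activity), but simple
measures — total stain intensity, count of positive pixels — depend on how
many cells the camera happens to capture at a given sampling location.
Robust quantification therefore needs three steps: isolate the stain of
interest from the raw RGB capture, segment the cells without supervision,
and average the stain only over cell regions. `entroseg` implements that
workflow, plus a multistage extension for nuclear segmentation in IHC
tissue images and the group-comparison statistics used to validate the
scores.

## The method

**Colour deconvolution.** Under the Lambert–Beer law the optical density
per channel, `OD = ln(I0 / I1)`, is linear in the amount of stain. Each
stain is a unit 3-vector of per-channel ODs; stacking them gives a
normalized matrix `A`, and per-pixel stain amounts are recovered as
`C = D K` with `K = A⁻¹` and `D` the pixel's OD row vector. Two systems
are built in: `fluor-blue` (blue stain vs background colour, completed to
a 3×3 basis with the unit cross product) and `ihc-hed`
(Haematoxylin / Eosin / DAB).

**Maximum-entropy segmentation.** The deconvolved stain channel is
thresholded at the cutoff `j*` that maximizes the Kapur criterion — the
sum of Shannon entropies of the two normalized class distributions of the
histogram split at `j`. Foreground (stained, dark) pixels are coded 0.
For IHC nuclei a multistage variant first splits the intensity range into
four equal quarters, finds a maximum-entropy point inside each, uses the
seven ordered boundaries to quantize the image into eight layers, and
applies a second maximum-entropy cut to the layer histogram; a
radius-3 majority (mode) filter then removes spurious isolated
detections.

**Quantification score.** The cell-replication score is the mean stain
magnitude over segmented foreground pixels,
`s = Σ (2^c − 1 − I_B) / #foreground` — a mean, hence invariant to the
number of cells in the field. A per-cell variant (`cell_mean_score`)
averages per-cell means over 8-connected components.

**Validation statistics.** Per-image scores grouped by condition are
compared with one-way ANOVA and Tukey HSD / LSD post hoc tests
(`one_way_anova`, `tukey_comparisons`, `lsd_comparisons`,
`compare_groups`).

## Worked example

```r
library(entroseg)

# synthetic fluorescence field with known ground truth
f   <- make_fluor_field(fluor_field_spec(stain_mean = 60, n_cells = 20, seed = 42))
seg <- segment_image(f$image, pipeline_config("live-cell"))
quant_score(seg$channel, seg$mask)
#> Quantification score (pixel-mean): 130.3291 over 5947 foreground pixels
```

The score 130.33 is the mean blue-stain magnitude over the 5947 pixels
segmented as cells (entropy cutoff `j* = 150`); the generator's own
ground-truth score for this field is 132.59, and the segmentation reaches
pixel precision 0.912 / recall 1.0 against the known mask
(`evaluate_mask(seg$mask, f$mask)`).

Completing a published-style ANOVA table from its sums of squares:

```r
anova_from_ss(1429.6, 2, 98.022, 6)
#> One-way ANOVA
#>                  Sum Sq df Mean Sq       F     p
#> Between groups 1429.600  2 714.800 43.7534 3e-04
#> Within groups    98.022  6  16.337
#> Total          1527.622  8
```

A command-line front end wrapping the same functions is installed at
`exec/entroseg` (subcommands `segment`, `quantify`, `evaluate`,
`compare-groups`, `synth`, `pipeline`).

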