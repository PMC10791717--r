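---
title: "Automated PWAT scoring: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PWAT scoring: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwatr)
```

## The problem

The Photographic Wound Assessment Tool (PWAT) grades chronic wounds from
photographs on an 8-item scale totalling 0-32. Trained clinicians score
items such as necrotic tissue type and amount, granulation tissue, edges
and peri-ulcer skin viability; the total is a workhorse outcome measure in
wound care, but it is manual and carries inter-rater subjectivity. `pwatr`
implements a fully automated scoring pipeline: given a wound photograph and
a binary wound-bed segmentation mask (produced upstream, e.g. by a neural
segmentation model — segmentation itself is out of scope here), it derives
the peri-wound region, extracts 54 interpretable colour and texture
features, and maps them to a continuous PWAT estimate with a penalized
linear model. Because every feature is a named, human-readable quantity,
the fitted coefficients can be ranked and read clinically, unlike
end-to-end deep-learning predictors.

## Peri-wound derivation

Several PWAT items concern the skin around the wound, which the wound-bed
mask excludes. The peri-wound mask is the morphological gradient of the
wound mask $M$:

$$M_{\text{peri}} = (M \oplus k) \setminus (M \ominus k),$$

with $k$ a 3×3 elliptical structuring element. On a discrete 3×3 grid the
inscribed ellipse is exactly the 5-pixel plus
$\{(0,0), (\pm 1,0), (0,\pm 1)\}$, which is what `struct_element(3)`
constructs; fixing this makes results bit-reproducible. Border handling is
the usual set-convention: erosion treats out-of-grid neighbours as
background (so foreground touching the image edge erodes away), and
dilation is clipped to the grid. With the default element the ring is about
two pixels wide, straddling the wound boundary. The element size is
exposed (`--kernel-size`) so the sensitivity of the ring width can be
explored, but 3 is the default everywhere. The ring is taken as-is: no
attempt is made to exclude non-skin background that may fall inside it.

## Colour and redness features

For each region (wound bed, peri-wound ring) the package computes the mean
and standard deviation of the R, G, B channels and, after a hexcone
RGB→HSV conversion, of the H, S, V channels — 12 statistics per region.
All statistics are plain averages over the masked pixels with population
(divisor $n$) standard deviations. Hue is measured in degrees $[0, 360)$
with achromatic pixels assigned hue 0; saturation and value are fractions.

Two erythema indices complete the colour block:

$$\mathrm{Redness}_{RGB} = \frac{1}{n}\sum_i
  \frac{2R_i - G_i - B_i}{2\,(R_i + G_i + B_i)}, \qquad
  \mathrm{Redness}_{HSV} = \frac{1}{n}\sum_i H_i S_i.$$

The RGB index is a per-pixel chromatic ratio, bounded in $[-0.5, 1]$ and
invariant to uniform channel rescaling; black pixels ($R+G+B=0$)
contribute 0 — a black pixel is not red, and the convention avoids a
division by zero. The HSV index uses hue in degrees; the scale is a pure
constant factor that the downstream robust scaler absorbs. Note the
built-in discontinuity of the HSV index: red sits at the hue origin, so
pure red scores 0 while reds just below 360° score maximally. The index is
implemented exactly as defined; the discontinuity is a property of the
definition, not a bug to repair.

## Texture features

Texture is summarized by Haralick statistics of the grey-level
co-occurrence matrix (GLCM). The image is converted to 8-bit grey with
BT.601 luma ($0.299R + 0.587G + 0.114B$), quantized into $L$ equal-width
bins, and, for each of the four standard unit displacements (0°, 45°, 90°,
135°), a symmetric GLCM is accumulated **only over pixel pairs that both
lie inside the region mask**. The 13 canonical features
(f1-f13: energy, contrast, correlation, variance, inverse difference
moment, sum average/variance/entropy, entropy, difference
variance/entropy, and the two information measures of correlation) are
computed per direction and averaged, the common radiomics convention;
averaging makes the result invariant to the ordering of the direction
list. Logs are base 2 with $0\log 0 = 0$; grey levels enter moment sums by
their quantized value $0..L-1$. Degenerate marginals (a constant region)
make the information measures undefined; they are reported as 0 with a
warning, and a region with no co-occurring in-mask pair at all raises a
degenerate-texture error so the pipeline can skip the sample with a logged
reason.

Two naming notes. Cluster shade and cluster prominence are often mentioned
alongside Haralick features but are *not* part of the canonical 13; they
are available via `extras = TRUE` and excluded from the default 54-feature
vector, whose arithmetic (12 colour + 2 redness + 13 texture per region ×
2 regions = 54) only works with the canonical set. The quantization depth
is not a standardized constant; the default is $L = 64$, a robust choice
for wound-sized regions where a 256-level GLCM is too sparse, and it is
recorded in the trained-model metadata so training and prediction always
agree.

## Regression pipeline

The 54 features are robust-scaled: $x \mapsto (x - \mathrm{med})/(q_3 -
q_1)$ with linear-interpolation quartiles, estimated on training data only
and then applied to test data. A constant feature is centred with divisor
1 rather than raising an error. The model is a Lasso,

$$\min_{\beta_0, \beta}\; \frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2
 + \alpha \lVert \beta \rVert_1,$$

with unpenalized intercept and $\alpha = 10^{-2}$ by default. The
objective convention matters — the same nominal penalty means different
things under different scalings of the residual term — so it is pinned to
the form above (glmnet's convention) and stored in the model metadata.
Predictions are continuous and deliberately **not** clamped to the 0-32
scale by default (a clamp flag exists): the floating-point score is finer
grained than the integer scale it estimates.

Evaluation uses shuffled stratified 10-fold cross-validation. A continuous
score has no classes, so stratification bins the observed scores into 5
quantile bins (bins smaller than the fold count are merged) and deals each
bin's shuffled samples round-robin over the folds. Scaler and model are
refit inside each training fold; out-of-fold predictions are pooled and
summarized by one Spearman rank correlation (average-rank ties) — the
pooled statistic, not a mean of per-fold correlations, is the headline
number of one cross-validation. The repeated protocol re-runs the whole
procedure (default 100 times) with repeat seeds derived deterministically
from a master seed, yielding a distribution of correlations and one
coefficient vector per repeat (the mean over that repeat's ten hold-out
fits). Feature ranking averages coefficients across repeats and orders by
absolute value — signed means are also reported, since the sign carries
the clinical direction; exact zeros are flagged uninformative.

## The synthetic study

No clinical wound dataset ships with the package, so a generator renders
elliptical wounds on skin-toned backgrounds with the statistical structure
the pipeline assumes. Severity $t = (\mathrm{PWAT}-2)/22$ drives five
appearance channels, each receiving independent Gaussian jitter
(sd 0.15, clamped to $[0,1]$):

1. **erythema** — wound chroma: green/blue fractions of the wound colour
   fall with severity;
2. **necrosis** — wound brightness: a global darkening plus an exactly
   controlled fraction of dark necrotic blobs (multiplicative, so chroma
   ratios are untouched);
3. **roughness** — wound texture: a fixed-variance oscillatory pattern
   whose spatial frequency grows with severity, raising neighbour contrast
   while leaving the marginal pixel variance flat;
4. **ring chroma** — the peri-wound ring reddens;
5. **ring darkening** — the ring darkens.

Scores are drawn from a truncated normal (mean 15, sd 3, bounds [2, 24]),
the distribution observed in clinical chronic-wound populations. Three
renderer details exist purely to keep the channels identifiable rather
than photorealistic: the wound base intensity is luma-compensated so that
chroma changes leave grey-level (texture) features untouched; the wound
margin blends towards the ring tone so the two-pixel morphological ring
reads the ring channels on both of its bands rather than being half wound
colour; and wound/ring hues sit near 15-20°, away from the hue wrap point,
so chroma readouts stay mutually collinear instead of fragmenting into
noise-driven hue-dispersion features. With these defaults the recoverable
ceiling of the pipeline is a pooled Spearman of roughly 0.87-0.89 at
$n = 300$ — comfortably above the 0.8 the test suite demands, with the
jitter sd chosen by a simple signal-to-noise computation: five independent
reads of $t$ (sd across samples ≈ 0.136) at jitter 0.15 leave
$R^2 \approx 0.8$ recoverable.

Because each channel is expressed through a *group* of definitionally
coupled features (a brightness change moves every RGB mean together; a
chroma change moves hue, saturation and both redness indices together), a
sparse model selects a data-dependent representative per group — it cannot
be forced to elect one pre-specified feature out of a collinear set. The
generator therefore documents its channel→feature-group map
(`channel_feature_groups()`), and the recovery test asserts the structural
property that holds: every top-5 ranked feature is a readout of a planted
channel, and all five channels are represented in the top 10.

What the generator does *not* emulate: uncontrolled illumination,
camera optics, anatomical context, wound shapes beyond ellipses, or the
per-sub-item structure of the PWAT. Passing tests show the pipeline's
machinery recovers planted, approximately linear signal; they say nothing
about performance on real photographs.

## Numerical choices and degenerate inputs

* Quartiles: linear interpolation (`stats::quantile` type 7), pinned for
  bit-reproducibility.
* Lasso solver: coordinate descent at convergence threshold $10^{-14}$, so
  the unpenalized limit agrees with ordinary least squares to $10^{-8}$.
* Binarization of mask rasters: strict threshold at grey level 127 of the
  first channel; loading a saved mask is the identity.
* Empty wound or ring, and texture-degenerate regions, raise typed errors;
  batch extraction logs and skips such samples instead of aborting.
* Spearman correlation of a constant vector is undefined and raises an
  error rather than returning `NA`.
* All stochastic operations take explicit seeds; datasets, samples and
  cross-validation runs are pure functions of their seed arguments.

## Problem sizes

The bundled tests exercise the full pipeline at $n = 300$ images of
256×256 pixels (the generator default, chosen so a complete study —
rendering, extraction of all 54 features, and repeated cross-validation —
runs in about two minutes on one core), with 20-repeat cross-validation
for the ranking distribution and a 100-repeat protocol on a tabular
study of $n = 100$.

## Known limitations

* The HSV redness index inherits the hue-origin discontinuity discussed
  above; on real images with deep reds it is noisier than the RGB index.
* The peri-wound ring is taken from mask morphology alone; if the dilated
  ring leaves the skin (bandages, background), those pixels contaminate
  the ring features.
* Stratification of a continuous score by quantile bins is one of several
  defensible conventions; with very small samples the bin merging can
  reduce to unstratified shuffling.
* Wound area is deliberately not a feature: absolute area is not
  recoverable from unstandardized photographs without a reference object.
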