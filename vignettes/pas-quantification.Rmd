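---
title: "Measuring per-cell glycogen from PAS-stained smears: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring per-cell glycogen from PAS-stained smears: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasquant)
```

## The measurement problem

Periodic acid–Schiff (PAS) staining turns glycogen and other polysaccharides
magenta, and a hematoxylin counterstain colours the rest of the cell blue.
On a bright-field image of a stained smear, the fraction of a cell's stained
area that is PAS-positive is a per-cell proxy for glycogen content. Two
things make naive colour thresholding unreliable: illumination is
inhomogeneous across the field (and differs between colour channels, so the
cast varies with position), and the exact stain tones drift from slide to
slide, which defeats colour deconvolution with fixed stain vectors. The
approach implemented here sidesteps both: correct the illumination with
calibration frames, move to hue–saturation–brightness (HSB) space where tone
drift appears only as a small shift of peak *positions*, and measure the
stain mixture by deconvolving the *hue histogram* into two peaks whose
locations are free parameters.

The per-cell pipeline, orchestrated by `quantify_image_set()`:

1. `correct_background()` — flat-field correction,
2. `rgb_to_hsb()` — hexcone colour conversion,
3. `segment_cells()` — saturation/brightness gating plus 8-connected
   components (skipped when a label mask is supplied),
4. `extract_hue_histogram()` — per-cell binned hue counts,
5. `fit_emg_mixture()` — two-component peak deconvolution,
6. `pas_index()` — the PAS peak's share of the fitted area.

## Flat-field correction

With a specimen frame $I_s$, an open-light-path frame $I_b$ and a
blocked-light-path frame $I_d$ (all 8-bit, same optics), the corrected image
is, per pixel and channel,

$$I_c = 255\,\frac{I_s - I_d}{I_b - I_d},$$

computed in floating point and clipped to $[0, 255]$. Pixels where
$I_b - I_d \le \varepsilon$ carry no illumination information; they are set
to 0 and counted, and a warning is raised when more than 1 % of pixels are
degenerate.

Because the three frames are stored with 8-bit quantization, per-pixel
recovery of the underlying scene is limited to roughly
$(0.5 + 0.5)/g_{\min}$ intensity units, where $g_{\min}$ is the smallest
gain in the field — about 1.7 units at the default minimum gain of 0.6. In
practice quantization errors rarely align: on rendered test scenes the mean
absolute deviation from the ideal scene is a few hundredths of a unit and
99 % of pixels land within one unit. The tests assert exactly this (mean and
99th percentile, plus the hard quantization bound) rather than a per-pixel
guarantee the bit depth cannot support.

## Hue histograms and the pixel filters

Hue is an angle in $[0°, 360°)$; hematoxylin sits near 250° ("blue") and
PAS near 270° ("purple"), far from the 0°/360° seam, so circular statistics
are unnecessary. Per cell, pixels pass into the histogram when their
saturation is at least `s_min = 0.08` (drops near-white background bleed,
including achromatic pixels whose hue is undefined) and their brightness
lies in `[0.05, 0.98]` (drops near-black debris and sensor-saturated
pixels). Both filters are configurable; excluded pixels are counted so that
`sum(counts) + n_excluded` always equals the cell's pixel count. The bin
width of 1° (360 bins) resolves the 20°-separated peaks with ample samples:
a typical cell at 100× covers on the order of $10^4$ pixels.

## The two-component EMG deconvolution

Each stain population is modelled as an exponentially modified Gaussian
(EMG): a Gaussian of location $\mu$ and width $\sigma$ convolved with a
one-sided exponential of scale $\tau$ pointing toward larger hue,

$$f(x;\mu,\sigma,\tau) = \frac{1}{2\tau}
  \exp\!\Big(\frac{\mu-x}{\tau} + \frac{\sigma^2}{2\tau^2}\Big)\,
  \mathrm{erfc}\!\Big(\frac{\mu-x}{\sqrt2\,\sigma} +
  \frac{\sigma}{\sqrt2\,\tau}\Big),$$

a standard skewed peak shape in chromatography-style histogram fitting. The
right-hand tail captures the high-hue shoulder that the purple PAS signal
rides on. Numerically the density is evaluated through the scaled
complementary error function (via `pnorm(·, log.p = TRUE)`), switching to
the direct exponential form where the argument is negative; both branches
are finite over the whole real line, which the tests check out to the far
tails.

`fit_emg_mixture()` minimizes the squared deviation between observed bin
counts and the model (bin-width × density at bin centres, times a free area
per component) over the 8 parameters
$(A_1, A_2, \mu_1, \mu_2, \sigma_1, \sigma_2, \tau_1, \tau_2)$, using
box-constrained Levenberg–Marquardt (`minpack.lm::nls.lm`). The boxes
$\mu_1 \in [230, 262]$, $\mu_2 \in [262, 300]$ keep the components
identified (hematoxylin below the 262° midpoint, PAS above) while leaving
room for slide-to-slide tone drift; $\sigma, \tau \in [0.5, 30]$ excludes
degenerate spikes and absurdly wide peaks. Overlapping-peak least squares
has local minima, so the fit starts from four deterministic configurations
(the nominal 250°/270° setup with an 80/20 area split, a data-driven start
that splits the observed mass at 262°, and narrow/wide shape variants) plus
seeded jittered restarts, keeping the best residual sum of squares. On
histograms sampled from the model itself the recovered optimum must fit at
least as well as the generating parameters; the suite asserts this with a
$10^{-3}$ relative slack.

If no start converges, the result is flagged and `pas_index()` falls back
to the model-free fraction of counts at hue ≥ 262°, with `fallback_used`
set — a coarser but fail-safe estimate.

The **PAS index** of a converged fit is $A_{\mathrm{PAS}} / (A_{\mathrm{PAS}}
+ A_{\mathrm{hem}})$, in $[0, 1]$ by construction. Fitting is per cell by
default, since cohort comparisons operate on individual cells; a pooled
per-image mode (`per_cell = FALSE`) exists for quick whole-slide summaries.

## The synthetic-scene generator

`render_scene()` produces the full acquisition: an ideal scene (near-white
background, elliptical cells), per-channel polynomial illumination gain in
$[0.6, 1]$, a dark offset, additive Gaussian sensor noise (SD 2 by
default), and 8-bit quantization (round half away from zero, clip), plus
the matching open- and blocked-path calibration frames, a label mask and
the per-cell ground truth. Exposure is modelled so the open-path frame
peaks exactly at 255 without clipping, as one would set a real camera.

Design choices that matter:

* **Dye hue model.** Each cell pixel is assigned to the PAS dye with
  probability equal to the cell's true fraction `p_pas` (implemented as a
  seeded permutation of exactly `round(p_pas · n)` pixels, so the realized
  fraction equals the target and end-to-end accuracy can be assessed per
  cell), and its hue is drawn from an EMG with mean at the nominal dye hue
  (250° or 270°), $\sigma = 3°$, $\tau = 2.5°$. Using the same peak family
  the fitting stage assumes is deliberate: with a mismatched generator
  shape (e.g. symmetric truncated Gaussians of spread 6°), the
  better-fitting skewed component systematically absorbs mass from its
  neighbour and biases the recovered area split by several hundredths —
  an artefact of the synthetic shape choice, not a property of the
  estimator being validated. The generator therefore tests sampling,
  optics, quantization and deconvolution, *not* robustness to arbitrary
  peak shapes (see Limitations).
* **Within-cell stain variation.** Saturation and brightness vary per pixel
  (uniform on [0.45, 0.65] and [0.5, 0.7]). Besides being what stained
  cells look like, this prevents every pixel of a cell from mapping onto
  one coarse quantized hue grid after the 8-bit RGB round trip, which
  would otherwise produce comb-shaped histograms and inflate the error of
  small-area components.
* **Cell size.** Default ellipse semi-axes around 60 × 52 px (≈ 10⁴ pixels
  per cell), plausible for cells imaged with a 100× oil objective. The
  statistical error of the fitted area split scales as $n^{-1/2}$; at this
  size the end-to-end index error stays within ±0.02 noise-free and ±0.05
  at default noise across true fractions from 0.05 to 0.9.
* **Per-channel vignette.** The default illumination coefficients differ
  between channels, so an uncorrected image has a position-dependent colour
  cast; skipping the correction measurably degrades the index, which the
  suite uses as a regression guard.

`simulate_cohort_images()` layers a donor design on top: per-cell true
fractions are Beta-distributed with a donor-level random effect (SD 0.005)
around group means of 0.10 (young) and 0.35 (old, i.e. 3.5-fold), with
cell-level SD 0.03 in young and 0.10 in old donors — the old group is
deliberately far more heterogeneous, the hallmark of aged samples. With the
default design (3 + 3 donors, 15 cells each) simple error propagation puts
the SD of the pipeline's estimated fold change near 0.2, so the design
separates the groups decisively while leaving realistic donor-to-donor
scatter.

What the generator does **not** emulate: chromatin texture and organelle
structure, focus gradients and chromatic aberration, stain batch effects or
fading, touching or overlapping cells (overlap is an error unless
explicitly allowed), and debris. Passing the synthetic suite therefore
demonstrates the correctness of the measurement chain under the stated
optical model, not segmentation robustness on difficult real smears — on
real data a curated label mask remains the safer path, and
`quantify_image_set()` accepts one.

## Cohort statistics

The statistics layer mirrors how such imaging and enzymology cohorts are
analysed:

* `normalize_by_reference()` divides each donor's enzyme activities by the
  same donor's reference activity (pyruvate kinase "high affinity" in the
  bundled table), cancelling donor-level multiplicative variation in
  overall glycolytic state. The suite verifies exact invariance to such
  factors.
* `z_standardize()` is provided because published analyses of this kind
  standardize before testing; the t statistic and trend $r^2$ are invariant
  to it (and to any affine map), which the suite checks to $10^{-10}$ —
  standardization changes presentation, not inference.
* `age_trend_r2()` is ordinary least squares of activity on age. Exclusions
  (e.g. a median-valued donor) are an explicit id list per analysis, never
  automatic.
* `one_sided_t_test()` (raw data, via `stats::t.test`) and
  `t_test_from_summary()` (hand-computed from means/SDs/sizes, for
  published summary tables) both offer the pooled and Welch variants; the
  two functions agree to $10^{-10}$ on data reconstructed from matching
  summaries. Pooled-vs-Welch is a per-call choice: with 4-vs-4 donor
  groups the pooled form is conventional, while unbalanced summary
  comparisons (7 vs 3 donors with unequal SDs) call for Welch.
* `summarize_groups()` uses age cutoffs (young < 40, old > 50 by default)
  so middle-aged donors fall in neither group; overall means/SDs use all
  donors. Positional column addressing is supported throughout because
  header labels in transcribed tables are easy to shift by one; positions
  are unambiguous.
* `compare_pas_indices()` reports the old/young fold change of mean
  per-cell indices, a one-sided test, and the outlier fraction (old cells
  above the young maximum) as a heterogeneity readout.

## Lineage priming and proliferation enrichment

For gene-by-cell count matrices, `classify_lineage()` scores each cell by
its mean log1p expression over myeloid and over lymphoid marker genes after
scaling every cell to a common total count (making calls invariant to
sequencing depth, which the suite checks). A cell is primed toward the
lineage whose score exceeds the other by more than `margin = 0.25` on the
log scale, otherwise unprimed. The margin is a declared default: at the
simulated depth it recovers > 95 % of strongly planted primed cells while
leaving genuinely unbiased cells mostly uncalled; it is not derived from
any biological threshold and should be tuned per dataset.

`proliferation_counts()` calls a gene "detected" in a group when at least
25 % of the group's cells show at least 1 count — robust to dropout, but
note that with deeply expressed genes the rule saturates (everything
detected everywhere); raising `detection_threshold` above the background
mean restores discrimination, and the enrichment tests do exactly that.
`proliferation_enrichment()` tests myeloid-vs-lymphoid detection of
proliferation genes with the one-sided Fisher exact test
(`stats::fisher.test`; the suite verifies exact agreement with brute-force
hypergeometric enumeration for all margins up to 12).
`compare_age_by_lineage()` tests old-vs-young per-cell gene-set scores per
lineage with the one-sided t-test; on generator defaults the effect appears
in myeloid-primed and not lymphoid-primed cells in ≈ 98 % of seeded
replicates. The choice of a t-test on per-cell set scores (rather than a
count-model contrast) is a declared simplification appropriate for set-level
screening, not per-gene differential expression.

## Numerical conventions

* Corrected intensities are floating point internally; images are written
  to disk with round-half-away-from-zero quantization.
* Matrices follow R's 1-based, column-major conventions; masks are integer
  matrices with 0 background, and connectivity is 8-way.
* All generators take integer seeds and restore the caller's RNG state;
  identical seeds give bit-identical outputs.
* Hue circularity is ignored (both peaks are ≥ 70° from the seam);
  achromatic pixels get hue 0 and are removed by the saturation filter.

## Problem sizes

The test-suite and acceptance computations use: single scenes of four
~10⁴-pixel cells for recovery checks; an EMG recovery histogram of 10⁵
samples; the full default cohort (6 donors × 15 cells, 24 rendered image
sets) for the fold-change check; all 2×2 tables with margins ≤ 12
(5 550 tables) for the Fisher oracle; and 100 seeded expression replicates
(200 genes × 360 cells each) for the enrichment power check. The whole
suite runs in about a minute on one core.

## Known limitations

* The EMG shape and the generator's dye model are matched by design;
  validation against histograms whose peaks are *not* EMG-shaped is limited
  to the fallback index path.
* Two stains only; a third dye population would require widening the model.
* Segmentation is intensity gating plus connected components — adequate for
  well-spread smears, not for clumped preparations.
* The enzyme and glucose-uptake analyses operate on small donor cohorts;
  the one-sided tests inherit the usual small-sample caveats and no
  multiple-testing correction is applied.
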