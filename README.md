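# pasquant

Semi-quantitative measurement of per-cell glycogen content from
bright-field images of periodic acid–Schiff (PAS) stained cell smears, with
the cohort statistics and single-cell lineage-priming analyses that go with
it.

PAS turns glycogen magenta on top of a blue hematoxylin counterstain.
Because stain tones drift from slide to slide, fixed-vector colour
deconvolution is unreliable; `pasquant` instead works in
hue–saturation–brightness space, where the two stains appear as a
hematoxylin hue peak near 250° and a PAS "purple" subpeak near 270°. Per
cell, the hue histogram is deconvolved into two exponentially modified
Gaussian (EMG) peaks with free locations,

    f(x; mu, sigma, tau) = 1/(2 tau) * exp((mu - x)/tau + sigma^2/(2 tau^2))
                           * erfc((mu - x)/(sqrt(2) sigma) + sigma/(sqrt(2) tau)),

by bounded nonlinear least squares, and the **PAS index**

    A_pas / (A_pas + A_hematoxylin)

— the PAS peak's share of the total fitted area — is the per-cell glycogen
measure. Upstream, images are flat-field corrected with open/blocked
light-path calibration frames, `I_c = 255 (I_s - I_d) / (I_b - I_d)`.

The package is aimed at quantitative microscopy of stained smears
(hematopoietic stem and progenitor cells in the bundled examples), and at
reanalysis of the accompanying cohort-level measurements: donor
enzyme-activity tables, glucose-uptake fraction summaries, and
marker-based lineage priming of single-cell count matrices. Synthetic-data
generators render full image sets (specimen, calibration frames, label
mask) with known ground truth so every stage is testable end to end.

## Worked example

Render a synthetic smear (four cells with known PAS fractions, vignetted
illumination, sensor noise) and quantify it:

```r
library(pasquant)

cells <- data.frame(x = c(140, 372, 140, 372), y = c(140, 140, 372, 372),
                    a = 60, b = 52, angle = c(0, 45, 90, 135),
                    p_pas = c(0.08, 0.25, 0.45, 0.70))
r <- render_scene(image_scene(cells, seed = 7))
m <- quantify_image_set(r$specimen, r$bright, r$dark, mask = r$mask)
cbind(m[, c("cell_id", "n_pixels", "pas_index")], truth = r$truth$p_pas)
#>   cell_id n_pixels pas_index truth
#> 1       1     9789    0.0814  0.08
#> 2       2     9805    0.2502  0.25
#> 3       3     9789    0.4563  0.45
#> 4       4     9805    0.7019  0.70
```

The estimated index tracks the true dye fraction to within a few
thousandths despite the vignette and the noise. The fit behind one cell:

```r
hsb <- rgb_to_hsb(correct_background(r$specimen, r$bright, r$dark))
fit <- fit_emg_mixture(extract_hue_histogram(hsb, r$mask, 4))
fit
#> Two-component EMG hue-histogram fit
#>   status: converged, residual SS 1.215e+04, 7 starts
#>   hematoxylin  area    2927.5  mu 248.94  sigma  4.51  tau  0.91
#>   pas          area    6894.4  mu 267.21  sigma  3.78  tau  2.68
#>   PAS index: 0.7019
```

`fit` is an ordinary model object with `summary()`, `coef()`, `predict()`,
`plot()`, `residuals()` and `simulate()` methods.

Cohort statistics on the bundled nine-donor enzyme-activity table
(activities normalized within donor to pyruvate kinase "high affinity"):

```r
tab <- enzyme_activities()
summarize_groups(tab)
#> Group summary (young: age < 40, n = 4; old: age > 50, n = 4)
#>            column  mean   sd mean_young mean_old
#>            pk_ref  0.57 0.32       0.40     0.76
#>          aldolase  0.77 0.48       0.41     1.13
#>  adenylate_kinase 10.63 7.53       5.36    16.64
#>               tpi  0.17 0.09       0.12     0.23
#>        hexokinase 13.68 7.03      13.77    12.38

age_trend_r2(tab, "adenylate_kinase")
#> Age trend of adenylate_kinase: slope 0.2263, r = 0.648, r^2 = 0.420 (n = 9)

one_sided_t_test(tab$adenylate_kinase[tab$age > 50],
                 tab$adenylate_kinase[tab$age < 40], "pooled")
#> One-sided pooled t-test (greater): t = 2.8343, df = 6.000, p = 0.01489
```

Adenylate-kinase activity rises with age (r² = 0.42) and is significantly
higher in the old donor group. For single-cell count matrices,
`classify_lineage()`, `proliferation_enrichment()` and
`compare_age_by_lineage()` implement the marker-based priming calls and the
Fisher-exact / one-sided-t enrichment tests; see the vignette in
`vignettes/pas-quantification.Rmd` for the full methods account.

A thin command-line wrapper ships in `inst/cli/pasquant`
(`pasquant simulate|quantify|stats|lineage ...`).

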