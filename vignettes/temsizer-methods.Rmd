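---
title: "Measuring particulate nanomaterials from TEM micrographs: models, parameters and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring particulate nanomaterials from TEM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temsizer)
```

## The measurement problem

Regulatory definitions of a *nanomaterial* hinge on the minimal external
dimension of the **constituent particles** — the primary particles that
may be bound inside aggregates or agglomerates. Transmission electron
microscopy is one of the few techniques that yields a *number-based* size
distribution of constituent particles across the whole 1–1000 nm range,
provided the micrographs can be segmented into individual particles and
each particle's minimal external dimension measured. `temsizer`
implements that measurement chain and, around it, the full validation
calculus used to qualify such a method: working-range rules, a top-down
measurement-uncertainty budget, trueness against certified reference
values, ruggedness against the number of measured particles, and ISO
5725-2 interlaboratory precision with outlier screening.

The operational size measurand is the **minimal Feret diameter**: the
smallest caliper width of the particle's 2-D projection over all
directions. The secondary measurand is the **equivalent circular
diameter** (ECD), the diameter of the circle with the particle's
projected area; modal ECD values are what silica reference materials are
certified for, so trueness is assessed on ECD.

## Geometry: exact measurands on pixel masks

A segmented particle is a set of pixels. Its outline is taken as the
boundary of the union of pixel squares (the *pixel-corner convention*):
a particle that is exactly `k` pixels across has a minimal Feret
diameter of exactly `k` pixel widths, which makes the 10-pixel lower
quantification limit exact and sub-pixel questions unambiguous. Feret
diameters are computed on the convex hull of the pixel corners by
rotating calipers: the minimal width is attained flush against a hull
edge, so the minimum over hull edges of the maximal vertex–edge distance
is exact for polygons. The maximal Feret diameter is the largest
pairwise hull-vertex distance.

Convexity is the ratio of the pixel area to the hull area. Ellipse axes
come from the second-order central moments of the pixel set (with the
1/12-px² per-pixel square correction); the axes are those of the
uniform-density ellipse with the same moments, so for a truly
ellipsoidal particle they equal the true axes.

Two systematic effects of the pixel representation matter in practice:

* **Rasterization floor.** The minimum-over-directions of a binary mask
  is biased low by roughly half a pixel, because the caliper picks the
  direction where the discretization happens to be tightest. At the
  10-pixel LLOQ this is ~5 %; at 25–40 pixels per particle it falls
  below 1–2 %. This is the quantitative reason behind the working-range
  rule: sizes should be measured well above the LLOQ.
* **Capsule–ellipse mismatch.** The moment-fitted short axis of a
  capsule-shaped (stadium) rod exceeds the true width by up to ~15 %
  (a rectangle's cross-sectional variance is w²/12 against the
  ellipse's w²/16). This is a property of moment ellipse fitting, not of
  the implementation; for rod-like materials the caliper width (kept in
  `feret_caliper_nm`) is the accurate column, and the ellipse-fitting
  mode is intended for ellipsoidal constituent particles.

## Working range

For a camera of `n` pixels imaging a field of view `F` (nm):
LOD = one pixel = `F/n`; LLOQ = 10 pixels (below which rasterized size
measurements carry large systematic deviations); ULOQ = `F/10` (a
particle should not dominate the field of view). The usable range
ULOQ/LLOQ = `n/100` is a property of the camera alone — a factor of
about 40 for a 4k × 4k CCD:

```{r}
quantification_limits(2450, 4096)
working_range_factor(4096)
```

Only particles with minimal Feret diameter inside `[LLOQ, ULOQ]`
(boundary inclusive at the LLOQ) enter the distributions; particles cut
by the image border are excluded by default because truncated outlines
bias the minimal Feret diameter low.

## Detection and the four segmentation modes

Preprocessing applies an edge-preserving median filter whose radius is
the single `smoothing_factor` (0 = identity), then flattens the
large-scale background. The background estimator tiles the image into
blocks (default 64 px, larger than any quantifiable particle), takes an
upper quantile per block (dark particles occupy the lower tail of a
bright-field histogram), and interpolates bilinearly — with linear
extrapolation at the edges so a linear illumination gradient is removed
exactly. A morphological closing with a structuring element several
times the particle size would achieve the same on these backgrounds at
much higher cost; the block-quantile envelope is the package's
rolling-ball-style equivalent.

Thresholding is global and automatic (inter-class-variance criterion on
the corrected histogram). The `min_otb` parameter — minimum
object-to-background intensity difference — then vetoes candidate
objects whose median contrast against the background is below it, or
below three times the image noise floor; a blank image therefore yields
an empty mask, and raising `min_otb` can only ever reduce the particle
count.

The mode dispatch mirrors how different material classes must be
treated:

| mode | intended class | mechanism |
|---|---|---|
| `default` | non-aggregated / slightly overlapping round particles | distance-transform watershed |
| `irregular_watershed` | irregular touching particles (e.g. nanorods) | watershed + convexity-driven merge so elongated particles are not over-split |
| `ellipse_fitting` | touching ellipsoidal particles | watershed split, per-particle moment ellipse; the short axis is the reported minimal Feret |
| `single_particle` | highly overlapping aggregates | no splitting; only blobs with convexity ≥ `convexity_threshold` are kept as proxies for the constituent particles |

The merge criterion of `irregular_watershed` fuses two touching
fragments when their union reaches convexity `merge_convexity`
(default 0.92): two halves of one rod form a convex union and are
re-joined; two distinct rods meeting at an angle do not. The
`single_particle` convexity cut defaults to 0.95; both thresholds are
configuration, logged with every run, since the corresponding values of
the original interactive tool are not published.

## Size statistics

Specimen distributions pool all images of one specimen (typically 10).
The specimen statistic is the sample median of the minimal Feret
diameters (even samples: mean of the two central order statistics). The
modal ECD is the location parameter of a normal distribution fitted to
the raw per-particle ECD values by maximum likelihood — i.e. the sample
mean — so that histogram binning (Freedman–Diaconis, reporting only)
cannot influence the mode. For skewed distributions the fitted-normal
mode and the histogram peak differ; both are reported.

## The top-down uncertainty budget

The validation design is `n_days` days × `n_r` replicate specimens per
day (5 × 3 in the standard campaign), one median per specimen. One-way
ANOVA with day as the factor gives `MS_within` and `MS_between`, and the
relative components (all in % of the grand mean `C_m`):

* repeatability `u_r = 100·√MS_within / C_m`;
* day effect `u_day = 100·√((MS_between − MS_within)/n_r) / C_m` when
  `MS_between > MS_within`; otherwise the day effect is unresolvable and
  the degenerate branch
  `u_day = 100·√(MS_within/n_r)·(2/ν)^{1/4} / C_m` (ν = within-days
  degrees of freedom) bounds it by the uncertainty of the within-day
  estimate itself, keeping `u_day` real and non-negative in all cases;
* intermediate precision `u_IP = √(u_r² + u_day²)`;
* trueness `u_t = √(u_t,CRM² + u_IP²)`, where `u_t,CRM` is the relative
  standard uncertainty of the reference value (for materials without a
  reference, the mean of the two silica CRM components is used);
* combined `u_c = √(u_IP² + u_t² + u_cal²)`, with `u_cal` a supplied
  per-magnification calibration constant (defaults 1.0 % at 18,500×,
  0.8 % at 9,300×, 0.2 % at 68,000×, 0.1 % at 30,000×);
* expanded `Ucx = 2·u_c` (coverage factor 2, ≈95 %).

Trueness is then judged in absolute nm: the bias `Δm = |C_m − C_CRM|`
is compared with `U_Δ = 2·√(u_c² + u_CRM²)`; `Δm ≤ U_Δ` means no
significant bias.

```{r}
combine_budget(u_r = 1.5, u_day = 1.0, u_cal = 1.0, u_t_crm = 3.6)
trueness(19.2, 0.9, crm_reference(19.4, 0.7))
```

**Closure of published tables.** The package ships the published
budget, trueness, working-range and interlaboratory tables and
recomputes every derivable cell. Because the published inputs are
themselves rounded to one decimal, the recomputed chain can differ from
a printed value by slightly more than half a unit (up to ~0.11 was
observed); closure is therefore asserted as *interval compatibility*:
the printed output must be reachable from the rounding intervals of the
printed inputs. Under that reading every budget column, trueness row and
precision cell closes (`budget_closure()`, `trueness_closure()`,
`interlab_closure()`, `working_range_closure()`).

## Ruggedness versus particle count

`ruggedness_curve()` subsamples each specimen pool to `N` particles
(without replacement, averaged over resamples), recomputes the medians
and the `u_IP` chain, and fits both an overall and a piecewise
log10–log10 regression (single breakpoint chosen by least total
residual, since no breakpoint rule is prescribed). On i.i.d. pools the
median's standard error scales as `N^{-1/2}`, so the log-log slope is
−0.5; with a real day effect the curve plateaus at the day-variance
floor, which is exactly why "measure more particles" stops helping at
some point. The smallest `N` with mean `u_IP` below 5 % is reported;
depending on the material this is of the order of 50–500 particles per
specimen.

## Interlaboratory statistics

The interlaboratory table holds per-laboratory replicate medians.
Outlier screening runs, in order: Cochran (largest within-lab variance
against the sum of variances), Grubbs-internal (extreme replicate within
a lab), Grubbs on laboratory means, and double Grubbs (two extreme means
on the same side), each classified against 5 % (straggler) and 1 %
(outlier) critical values. Critical values are computed, not tabulated:
Cochran from the F-quantile relation
`C = 1/(1 + (L−1)/F_{1−α/L}(ν, (L−1)ν))`, Grubbs from the t-quantile
closed form. The double-Grubbs statistic has no closed-form critical
value; it is estimated once per `(n, α)` by Monte Carlo under the normal
null with a fixed internal seed (memoized), which reproduces the
published tables to Monte Carlo accuracy. 1 %-level outliers are
excluded (the whole laboratory, or the single replicate for
Grubbs-internal), the tests re-run on the cleaned table, and — following
common interlaboratory practice — no more than 2/9 of the laboratories
are ever excluded. The iteration order and every decision are logged
because the screening order is convention, not mathematics.

Precision on the retained data is one-way ANOVA with laboratory as the
factor: `S_r² = MS_within`; the between-laboratory component uses the
effective replicate count `n̄ = (N − Σn_i²/N)/(p−1)` for unbalanced
tables; `S_R² = S_r² + S_L²` is floored at `S_r²`. The repeatability and
reproducibility limits are `r = 2.8·S_r` and `R = 2.8·S_R`
(2.8 ≈ 1.96·√2: the 95 % bound on the difference of two results).

## The synthetic-scene generator

Every stage above is testable because the generator produces calibrated
micrographs with exact ground truth for the four material classes:
non-aggregated spheres; touching/slightly overlapping ellipsoids;
touching/slightly overlapping rods (stadium outlines); and highly
overlapping aggregates of irregular, star-convex particles. Sizes are
drawn from a configurable law (constant, lognormal median/GSD, normal);
clusters are built by attaching particles to random anchors at contact
distance, with pairwise overlap capped at a configurable fraction of the
smaller particle (verified by exact polygon clipping); rendering is
bright-field (dark particles on a brighter background) with a low-order
illumination gradient, Poisson shot noise and Gaussian read noise on
top of a binary rasterization (a pixel belongs to a particle when its
center lies inside the outline). Everything is deterministic in the
scene seed.

Default study conditions used across the tests: 20 nm median particles
(lognormal GSD 1.15–1.2 for polydisperse scenes), background 1000
counts with a 10 % gradient, contrast 0.7, read noise 8 counts — noise
and background are free knobs of the simulator, chosen once as a
realistic CCD regime, since no instrument characterization is in scope.
Recovery scenes use 500 particles at ~40 px per particle (2048² image);
the validation-pipeline tests use reduced designs (3 days × 2
replicates, ~40 particles per image at 512²) so the whole suite stays
fast; statistical recovery checks use 10⁴ Monte Carlo draws.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: partial-pixel (graded) particle edges,
defocus and astigmatism, diffraction contrast, specimen drift, carbon
support texture, and operator-dependent optimization of settings.
Binary rasterization in particular makes edge pixels crisper than real
bright-field contrast, which is why the recovery tolerances (2 % on
disk medians, 5 % on ellipsoid short axes) should be read as
segmentation-chain correctness, not as instrument-level uncertainty.

## Numerical choices and degenerate inputs

* Collinear outlines get Feret width 0 and a degeneracy flag rather
  than an error; empty masks and blank images yield empty particle sets.
* The even-length median rule (mean of central order statistics) is
  fixed and documented; it matters at small per-specimen counts.
* Rounding for reports: two decimals below ~2 nm, one decimal above,
  matching how such limits are conventionally published.
* The ANOVA is computed from direct sums of squares (the budget needs
  the mean squares themselves); `stats::aov` serves as the independent
  cross-check in the tests.
* Watershed over-splitting is controlled by `watershed_tolerance`
  (depth in distance-map units, default 1 px); under-splitting of
  heavily fused aggregates is expected and is precisely the case the
  `single_particle` mode exists for.

## Known limitations

* Not bit-compatible with the original interactive plugin; modes are
  re-implemented at contract level.
* Moment-ellipse short axes overestimate capsule-shaped rod widths by
  up to ~15 % (see above); use the caliper column for rods.
* The placement sampler is rejection-based: extremely dense scenes
  (fill fractions well above ~30 %) can fail with a placement error
  rather than degrade gracefully.
* Double-Grubbs critical values are Monte Carlo estimates (±~0.001 at
  the shipped simulation size); all other critical values are exact.
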