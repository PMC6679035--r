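# temsizer

Number-based size measurement of particulate (nano)materials from
calibrated transmission electron micrographs, together with the complete
intra- and inter-laboratory validation calculus that qualifies such a
method for regulatory use.

Whether a material counts as a *nanomaterial* under the EC
Recommendation depends on the minimal external dimension of its
constituent particles — the primary particles, possibly fused inside
aggregates. `temsizer` is for microscopists and metrologists who need
to (a) segment TEM micrographs of four morphology classes into
constituent particles, (b) measure each particle's **minimal Feret
diameter** d_min (the smallest caliper width over all directions,
computed exactly by rotating calipers on the convex hull of the pixel
corners) and **equivalent circular diameter** ECD = √(4A/π), and then
(c) run the validation statistics on the resulting per-specimen medians:

* **working range**: LOD = 1 px, LLOQ = 10 px, ULOQ = FOV/10, a usable
  range factor of n_pixels/100 (≈40 for a 4k camera);
* **uncertainty budget** (components in % of the grand mean C_m):
  u_r = 100·√MS_within/C_m, u_day from the between/within mean-square
  contrast, u_IP = √(u_r²+u_day²), u_t = √(u_t,CRM²+u_IP²),
  u_c = √(u_IP²+u_t²+u_cal²), Ucx = 2·u_c;
* **trueness**: Δm = |C_m − C_CRM| against U_Δ = 2·√(u_c²+u_CRM²);
* **ruggedness**: u_IP as a function of the number of measured
  particles (log–log slope −1/2 on i.i.d. pools, plateau at the
  day-effect floor);
* **interlaboratory precision** (ISO 5725-2): Cochran and
  Grubbs/double-Grubbs outlier screening with computed critical values,
  then S_r, S_R, r = 2.8·S_r, R = 2.8·S_R, RSD_r, RSD_R.

A synthetic micrograph generator with exact polygonal ground truth
(spheres, ellipsoids, rods, irregular aggregates; configurable size
laws, clustering, overlap, noise and illumination gradient) makes every
stage verifiable without instrument data.

## Worked example

```r
library(temsizer)

# working range of a 4k CCD at 18,500x (2450 nm field of view)
quantification_limits(2450, 4096)
#> LOD 0.60 nm, LLOQ 6.0 nm, ULOQ 245.0 nm (fov 2450 nm, 4096 px, range factor 41)

# simulate a colloidal-silica-like scene: 30 disjoint 20 nm spheres
sc <- simulate_scene(scene_spec("sphere", list(family = "constant", value = 20),
                                particle_count = 30, fov_nm = 500,
                                n_pixels = 512, seed = 3))
a <- analyze_micrograph(sc$micrograph, detection_params(min_otb = 200))
nrow(a$retained)                        # 30  (all particles recovered)
median(a$retained$min_feret_nm)         # 19.53 nm (truth: 20 nm; ~0.5 px
                                        # rasterization floor at 1 nm/px)

# uncertainty budget from precision components (all in %)
combine_budget(u_r = 1.5, u_day = 1.0, u_cal = 1.0, u_t_crm = 3.6)
#> u_r = 1.5%, u_day = 1.0%, u_IP = 1.8%, u_cal = 1.0%, u_t = 4.0%, u_c = 4.5%, Ucx = 9.0%

# trueness of a measured 19.2 +/- 0.9 nm against a 19.4 +/- 0.7 nm CRM
trueness(19.2, 0.9, crm_reference(19.4, 0.7))
#> Δm = 0.2 nm, U_Δ = 2.28 nm -> no significant bias
```

The numbers mean: all 30 particles were detected and none rejected by
the working-range filters; the detected median sits half a pixel below
truth (the documented binary-rasterization floor — sample finer than
~25 px/particle for percent-level accuracy); a method with 1.8 %
intermediate precision and the given calibration/trueness components
carries an expanded uncertainty of 9 %; and a 0.2 nm bias is well
inside the 2.3 nm expanded comparison uncertainty.

End-to-end: `simulate_validation_dataset()` builds a day × replicate ×
image campaign, `run_pipeline()` takes it to the full budget, and
`interlab_evaluation()` screens and summarizes a multi-laboratory
table. A thin CLI over the same functions is in `inst/cli/temsizer.R`
(subcommands `simulate`, `limits`, `analyze`, `summarize`,
`validate-intra`, `validate-inter`).

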