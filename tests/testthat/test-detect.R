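flat_scene <- function(gradient = 0, noise = TRUE, n_particles = 6, seed = 21) {
  simulate_scene(scene_spec(
    "sphere", list(family = "constant", value = 30), particle_count = n_particles,
    fov_nm = 300, n_pixels = 256,
    noise = if (noise) list(poisson = TRUE, read_sd = 8) else list(poisson = FALSE, read_sd = 0),
    background = list(level = 1000, gradient = gradient), seed = seed))
}

test_that("preprocessing flattens a pure illumination gradient to the noise floor", {
  sp <- scene_spec("sphere", list(family = "constant", value = 20),
                   particle_count = 1, fov_nm = 300, n_pixels = 256,
                   noise = list(poisson = FALSE, read_sd = 0),
                   background = list(level = 1000, gradient = 0.2), seed = 5)
  out <- render_scene(list(), sp)   # no particles, pure gradient
  rng0 <- diff(range(out$micrograph$intensity))
  corr <- preprocess(out$micrograph, smoothing_factor = 0)
  expect_gt(rng0, 100)              # the gradient is substantial before
  expect_lt(diff(range(corr)), 0.02 * 1000)
})

test_that("background residual is small relative to particle contrast on clean scenes", {
  sc <- flat_scene(gradient = 0.15, noise = FALSE, n_particles = 1, seed = 31)
  corr <- preprocess(sc$micrograph, smoothing_factor = 0)
  bgres <- diff(range(corr[!sc$mask]))
  contrast <- stats::median(corr[!sc$mask]) - stats::median(corr[sc$mask])
  expect_lt(bgres, 0.05 * contrast)
})

test_that("zero smoothing leaves the denoising step as the identity", {
  sc <- flat_scene(noise = FALSE, seed = 22)
  m <- sc$micrograph
  c0 <- preprocess(m, smoothing_factor = 0)
  # with a flat background the correction is a constant shift only
  shift <- c0 - m$intensity
  expect_lt(diff(range(shift)), 1e-6 + 0.02 * 1000)
  expect_equal(stats::cor(as.vector(c0), as.vector(m$intensity)), 1,
               tolerance = 1e-9)
})

test_that("thresholding recovers particles and suppresses low-contrast objects", {
  sc <- flat_scene(seed = 23)
  corr <- preprocess(sc$micrograph, 1)
  mask <- threshold_particles(corr, min_otb = 100)
  truth <- sc$mask
  jacc <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jacc, 0.9)
  # min_otb above the particle contrast empties the mask
  mask2 <- threshold_particles(corr, min_otb = 2000)
  expect_equal(sum(mask2), 0)
})

test_that("a blank (noise-only) image produces an empty mask", {
  set.seed(9)
  img <- matrix(1000 + stats::rnorm(256 * 256, 0, 10), 256, 256)
  m <- micrograph(img, 1)
  mask <- threshold_particles(preprocess(m, 0), min_otb = 50)
  expect_equal(sum(mask), 0)
  # fully constant image
  mask2 <- threshold_particles(matrix(5, 64, 64), min_otb = 10)
  expect_equal(sum(mask2), 0)
})

test_that("increasing min_otb never increases the detected particle count", {
  sc <- flat_scene(seed = 24)
  corr <- preprocess(sc$micrograph, 1)
  counts <- vapply(c(0, 50, 100, 300, 500, 800, 2000), function(otb) {
    mask <- threshold_particles(corr, otb)
    max(EBImage::bwlabel(mask))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("default mode separates disjoint and slightly overlapping disks", {
  sc <- scene_disks_small()
  labels <- detect_particles(sc$micrograph, baseline_params())
  expect_equal(max(labels), 30)

  # two equal disks overlapping ~5 % of their area
  spec2 <- scene_spec("sphere", list(family = "constant", value = 40),
                      particle_count = 2, cluster_mean = 2,
                      overlap_fraction = 0.05, fov_nm = 200, n_pixels = 256,
                      seed = 13)
  sc2 <- simulate_scene(spec2)
  labels2 <- detect_particles(sc2$micrograph, baseline_params())
  expect_equal(max(labels2), 2)
})

test_that("single-particle mode retains isolated disks and discards the aggregate", {
  spec <- scene_spec("sphere", list(family = "constant", value = 30),
                     particle_count = 15, cluster_mean = 10,
                     overlap_fraction = 0.25, fov_nm = 700, n_pixels = 512,
                     seed = 37)
  # one 10-particle aggregate placed by the cluster machinery, plus 5
  # singleton disks pinned far away from it
  shapes <- sample_population(spec)
  agg <- place_particles(shapes[1:10], cluster_mean = 10,
                         overlap_fraction = 0.25, fov_nm = 600, seed = 4)
  spots <- list(c(80, 80), c(620, 80), c(80, 620), c(620, 620), c(620, 350))
  singles <- lapply(1:5, function(i) {
    s <- shapes[[10 + i]]
    s$outline <- sweep(s$outline, 2, spots[[i]], "+")
    s$center <- spots[[i]]
    s$cluster_id <- 1L + i
    s
  })
  lay <- c(agg, singles)
  out <- render_scene(lay, spec)
  labels <- detect_particles(out$micrograph,
                             baseline_params(mode = "single_particle"))
  recs <- measure_particles(labels, out$micrograph$pixel_size_nm)
  expect_equal(nrow(recs), 5)
  expect_true(all(recs$convexity >= 0.95))
})

test_that("irregular-watershed merging does not over-split elongated rods", {
  sc <- scene_rods()
  labels <- detect_particles(sc$micrograph,
                             baseline_params(mode = "irregular_watershed"))
  n_true <- nrow(sc$truth)
  expect_gte(max(labels), n_true - 3)
  expect_lte(max(labels), n_true + 3)
})

test_that("segmentation is deterministic and rejects unknown modes", {
  sc <- scene_disks_small()
  l1 <- detect_particles(sc$micrograph, baseline_params())
  l2 <- detect_particles(sc$micrograph, baseline_params())
  expect_identical(as.vector(l1), as.vector(l2))
  expect_error(detection_params(mode = "fancy"))
})

test_that("small perturbations of the tuned settings barely move the median", {
  sc <- scene_disks_small()
  base <- analyze_micrograph(sc$micrograph,
                             baseline_params(smoothing_factor = 1, min_otb = 200))
  med0 <- stats::median(base$retained$min_feret_nm)
  for (fac in c(0.9, 1.1)) {
    a <- analyze_micrograph(sc$micrograph,
                            baseline_params(smoothing_factor = 1 * fac,
                                            min_otb = 200 * fac))
    med <- stats::median(a$retained$min_feret_nm)
    expect_lt(abs(med - med0) / med0, 0.02)
  }
})
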