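#' Specification of a synthetic micrograph scene
#'
#' Defines one simulated TEM field of view: the particle morphology class,
#' the number-based size law of the constituent particles, the clustering
#' (aggregation) law, the camera geometry and the noise model. The four
#' supported classes emulate the material types the sizing approach is
#' designed for: non-aggregated spheres (stable colloids), touching or
#' slightly overlapping ellipsoids, touching or slightly overlapping
#' irregular rods, and highly overlapping aggregates.
#'
#' Coordinates are in nm with the origin at the top-left pixel corner,
#' x to the right and y downwards; pixel centers sit at half-integer
#' multiples of the pixel size. Rendering follows the bright-field
#' convention (dark particles on a brighter background).
#'
#' @param shape_class one of `"sphere"`, `"ellipsoid"`, `"rod"`,
#'   `"irregular"`.
#' @param size_law list describing the distribution of the particle width
#'   (the minimal external dimension): `list(family = "constant", value =)`,
#'   `list(family = "lognormal", median =, gsd =)` or
#'   `list(family = "normal", mean =, sd =)`, all in nm.
#' @param particle_count number of constituent particles (>= 1).
#' @param cluster_mean mean number of particles per cluster (1 = no
#'   clustering).
#' @param overlap_fraction maximal allowed pairwise overlap area between
#'   clustered neighbours, as a fraction of the smaller particle, in
#'   `[0, 1)`.
#' @param fov_nm field-of-view edge length in nm.
#' @param n_pixels image edge length in pixels (>= 64).
#' @param aspect length-to-width ratio for `ellipsoid` and `rod` shapes.
#' @param contrast relative intensity deficit of particles against the
#'   local background, in (0, 1].
#' @param noise list with `poisson` (logical; apply shot noise to the
#'   photon-count image) and `read_sd` (Gaussian read noise, counts).
#' @param background list with `level` (mean background, counts) and
#'   `gradient` (relative amplitude of a low-order illumination gradient).
#' @param seed integer seed making the whole scene reproducible.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(shape_class = c("sphere", "ellipsoid", "rod", "irregular"),
                       size_law = list(family = "lognormal", median = 20, gsd = 1.2),
                       particle_count = 100,
                       cluster_mean = 1,
                       overlap_fraction = 0,
                       fov_nm = 1000,
                       n_pixels = 512,
                       aspect = 1,
                       contrast = 0.7,
                       noise = list(poisson = TRUE, read_sd = 8),
                       background = list(level = 1000, gradient = 0.1),
                       seed = 1L) {
  shape_class <- match.arg(shape_class)
  stopifnot(particle_count >= 1, fov_nm > 0, n_pixels >= 64,
            overlap_fraction >= 0, overlap_fraction < 1,
            cluster_mean >= 1, contrast > 0, contrast <= 1, aspect >= 1)
  if (is.null(size_law$family)) stop("size_law must name a distribution family")
  structure(list(shape_class = shape_class, size_law = size_law,
                 particle_count = as.integer(particle_count),
                 cluster_mean = cluster_mean,
                 overlap_fraction = overlap_fraction,
                 fov_nm = fov_nm, n_pixels = as.integer(n_pixels),
                 aspect = aspect, contrast = contrast,
                 noise = noise, background = background,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

draw_sizes <- function(law, n) {
  switch(law$family,
         constant = rep(law$value, n),
         lognormal = {
           if (is.null(law$median) || is.null(law$gsd) || law$median <= 0 || law$gsd < 1)
             stop("lognormal size law needs median > 0 and gsd >= 1")
           stats::rlnorm(n, meanlog = log(law$median), sdlog = log(law$gsd))
         },
         normal = {
           if (is.null(law$mean) || is.null(law$sd) || law$mean <= 0 || law$sd < 0)
             stop("normal size law needs mean > 0 and sd >= 0")
           pmax(stats::rnorm(n, law$mean, law$sd), law$mean / 20)
         },
         stop("unknown size-law family: ", law$family))
}

# shape constructors: outlines centered on the centroid, width = minimal
# external dimension = w
circle_outline <- function(w, n_vert = 256) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  cbind(w / 2 * cos(th), w / 2 * sin(th))
}

ellipse_outline <- function(w, aspect, n_vert = 256) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  cbind(aspect * w / 2 * cos(th), w / 2 * sin(th))
}

# stadium: rectangle of length L - w plus semicircular caps of radius w/2;
# total length L = aspect * w, width w
stadium_outline <- function(w, aspect, n_cap = 64) {
  r <- w / 2
  half <- (aspect * w - w) / 2  # half-length of the straight section
  th1 <- seq(-pi / 2, pi / 2, length.out = n_cap)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = n_cap)
  rbind(cbind(half + r * cos(th1), r * sin(th1)),
        cbind(-half + r * cos(th2), r * sin(th2)))
}

# randomly perturbed star-convex polygon with mean radius chosen so the
# caliper width comes out near w
irregular_outline <- function(w, n_vert = 96) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  k <- 2:5
  amp <- stats::runif(length(k), 0, 0.12) / k
  ph <- stats::runif(length(k), 0, 2 * pi)
  r <- rep(1, n_vert)
  for (i in seq_along(k)) r <- r + amp[i] * cos(k[i] * th + ph[i])
  r <- pmax(r, 0.3)
  cbind(w / 2 * r * cos(th), w / 2 * r * sin(th))
}

#' Draw a population of particle shapes from a scene specification
#'
#' Samples `particle_count` outlines from the size law. Outlines are
#' centred at the origin and unrotated; true measurands (minimal and
#' maximal Feret diameter, ECD) are computed exactly from each outline.
#'
#' @param spec a [scene_spec()].
#' @param seed seed (defaults to `spec$seed`).
#' @return List of ground-truth particles, each a list with `outline`
#'   (nm), `true_min_feret_nm`, `true_max_feret_nm`, `true_ecd_nm`.
#' @export
sample_population <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  w <- draw_sizes(spec$size_law, spec$particle_count)
  lapply(w, function(wi) {
    outline <- switch(spec$shape_class,
                      sphere = circle_outline(wi),
                      ellipsoid = ellipse_outline(wi, spec$aspect),
                      rod = stadium_outline(wi, spec$aspect),
                      irregular = irregular_outline(wi))
    f <- feret_diameters(outline)
    list(outline = outline,
         true_min_feret_nm = f$min,
         true_max_feret_nm = f$max,
         true_ecd_nm = ecd(polygon_area(outline)))
  })
}

rotate_poly <- function(p, ang) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  p %*% t(R)
}

circumradius <- function(p) sqrt(max(p[, 1]^2 + p[, 2]^2))

# radius of a star-convex outline (centred at origin) in direction phi
radius_at <- function(p, phi) {
  ang <- atan2(p[, 2], p[, 1])
  d <- sqrt(p[, 1]^2 + p[, 2]^2)
  i <- which.min(pmin(abs(ang - phi), 2 * pi - abs(ang - phi)))
  d[i]
}

#' Place particle shapes in the field of view
#'
#' Realizes the cluster law: particles are partitioned into clusters whose
#' sizes are drawn around `cluster_mean`; members of a cluster touch or
#' overlap by at most `overlap_fraction` (area of the smaller particle),
#' different clusters are disjoint, and every particle lies fully inside
#' the field of view. Placement uses bounded rejection sampling and fails
#' with an informative error when the field of view is too crowded.
#'
#' @param shapes list from [sample_population()].
#' @param cluster_mean,overlap_fraction,fov_nm as in [scene_spec()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per cluster.
#' @return List of placed particles; each element gains `center` (nm),
#'   `cluster_id` and a placed (rotated + translated) `outline`.
#' @export
place_particles <- function(shapes, cluster_mean = 1, overlap_fraction = 0,
                            fov_nm, seed = 1L, max_tries = 400L) {
  set.seed(seed)
  n <- length(shapes)
  # partition into clusters
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- if (cluster_mean <= 1) 1L else 1L + stats::rpois(1, cluster_mean - 1)
    sizes <- c(sizes, min(s, n - sum(sizes)))
  }
  idx <- sample.int(n)
  clusters <- split(idx, rep(seq_along(sizes), sizes))

  # build each cluster in local coordinates
  built <- lapply(seq_along(clusters), function(ci) {
    mem <- clusters[[ci]]
    outl <- vector("list", length(mem))
    cent <- matrix(0, length(mem), 2)
    outl[[1]] <- rotate_poly(shapes[[mem[1]]]$outline, stats::runif(1, 0, 2 * pi))
    for (j in seq_along(mem)[-1]) {
      pj <- rotate_poly(shapes[[mem[j]]]$outline, stats::runif(1, 0, 2 * pi))
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        anchor <- sample.int(j - 1, 1)
        phi <- stats::runif(1, 0, 2 * pi)
        ra <- radius_at(outl[[anchor]], phi)
        rb <- radius_at(pj, phi + pi)
        shrink <- if (overlap_fraction > 0) 1 - 0.3 * overlap_fraction else 1.001
        d <- (ra + rb) * shrink
        cand <- cent[anchor, ] + d * c(cos(phi), sin(phi))
        cand_poly <- sweep(pj, 2, cand, "+")
        ok <- TRUE
        for (k in seq_len(j - 1)) {
          other <- sweep(outl[[k]], 2, cent[k, ], "+")
          # quick accept when far apart
          if (sqrt(sum((cand - cent[k, ])^2)) >
              circumradius(pj) + circumradius(outl[[k]]) + 1e-9) next
          ov <- polygon_overlap_fraction(cand_poly, other)
          lim <- if (k == anchor) overlap_fraction else overlap_fraction / 2
          if (ov > lim + 1e-12) { ok <- FALSE; break }
        }
        if (ok) {
          cent[j, ] <- cand
          outl[[j]] <- pj
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("placement failed: cluster too crowded for requested overlap")
    }
    list(members = mem, centers = cent, outlines = outl)
  })

  # place clusters disjointly in the fov
  placed <- vector("list", n)
  occ_c <- matrix(numeric(0), 0, 2)
  occ_r <- numeric(0)
  for (ci in seq_along(built)) {
    b <- built[[ci]]
    abs_out <- lapply(seq_along(b$members), function(j)
      sweep(b$outlines[[j]], 2, b$centers[j, ], "+"))
    rc <- max(vapply(abs_out, circumradius, 0))
    ctr <- colMeans(b$centers)
    rc <- max(vapply(seq_along(abs_out), function(j)
      circumradius(sweep(abs_out[[j]], 2, ctr, "-")), 0))
    if (2 * rc >= fov_nm) stop("placement failed: cluster larger than field of view")
    done <- FALSE
    for (try in seq_len(max_tries)) {
      pos <- stats::runif(2, rc * 1.02, fov_nm - rc * 1.02)
      if (nrow(occ_c) > 0) {
        dd <- sqrt((occ_c[, 1] - pos[1])^2 + (occ_c[, 2] - pos[2])^2)
        if (any(dd <= occ_r + rc + fov_nm * 1e-4)) next
      }
      for (j in seq_along(b$members)) {
        id <- b$members[j]
        sh <- shapes[[id]]
        sh$outline <- sweep(abs_out[[j]], 2, ctr - pos, "-")
        sh$center <- polygon_centroid(sh$outline)
        sh$cluster_id <- ci
        placed[[id]] <- sh
      }
      occ_c <- rbind(occ_c, pos)
      occ_r <- c(occ_r, rc)
      done <- TRUE
      break
    }
    if (!done) stop("placement failed: field of view too small for requested scene")
  }
  placed
}

#' Render a placed scene into a calibrated micrograph
#'
#' Rasterizes the particle outlines onto the pixel grid (a pixel belongs to
#' a particle when its center lies inside the outline), applies the
#' bright-field intensity model with an optional low-order illumination
#' gradient, then shot (Poisson) and Gaussian read noise. Returns the
#' micrograph together with the ground-truth table.
#'
#' @param layout list from [place_particles()].
#' @param spec the [scene_spec()] (geometry, contrast, noise, seed).
#' @param seed seed for the noise draws (defaults to `spec$seed + 1`).
#' @return List with `micrograph` (a [micrograph()] object) and `truth`
#'   (data frame: particle_id, cluster_id, center_x_nm, center_y_nm,
#'   min_feret_nm, max_feret_nm, ecd_nm).
#' @export
render_scene <- function(layout, spec, seed = spec$seed + 1L) {
  np <- spec$n_pixels
  psz <- spec$fov_nm / np
  mask <- matrix(FALSE, np, np)   # [x, y]
  for (p in layout) {
    if (is.null(p$center)) stop("layout particles must be placed first")
    bb <- apply(p$outline, 2, range)
    ix <- max(1L, floor(bb[1, 1] / psz)):min(np, ceiling(bb[2, 1] / psz))
    iy <- max(1L, floor(bb[1, 2] / psz)):min(np, ceiling(bb[2, 2] / psz))
    if (length(ix) == 0 || length(iy) == 0) next
    cx <- (ix - 0.5) * psz
    cy <- (iy - 0.5) * psz
    g <- expand.grid(x = cx, y = cy)
    inside <- pracma::inpolygon(g$x, g$y, p$outline[, 1], p$outline[, 2])
    if (any(inside)) {
      sub <- mask[ix, iy, drop = FALSE]
      sub[matrix(inside, length(ix), length(iy))] <- TRUE
      mask[ix, iy] <- sub
    }
  }
  set.seed(seed)
  bg <- spec$background$level
  grad <- spec$background$gradient
  u <- ((seq_len(np) - 0.5) / np) - 0.5
  gdir <- stats::runif(1, 0, 2 * pi)
  field <- bg * (1 + grad * (outer(u * cos(gdir), u * sin(gdir), "+") * 2))
  img <- field * (1 - spec$contrast * mask)
  if (isTRUE(spec$noise$poisson))
    img[] <- stats::rpois(length(img), lambda = pmax(img, 0))
  if (!is.null(spec$noise$read_sd) && spec$noise$read_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise$read_sd)
  img <- pmax(img, 0)

  truth <- data.frame(
    particle_id = seq_along(layout),
    cluster_id = vapply(layout, function(p) as.integer(p$cluster_id), 1L),
    center_x_nm = vapply(layout, function(p) p$center[1], 1.0),
    center_y_nm = vapply(layout, function(p) p$center[2], 1.0),
    min_feret_nm = vapply(layout, function(p) p$true_min_feret_nm, 1.0),
    max_feret_nm = vapply(layout, function(p) p$true_max_feret_nm, 1.0),
    ecd_nm = vapply(layout, function(p) p$true_ecd_nm, 1.0)
  )
  list(micrograph = micrograph(img, pixel_size_nm = psz,
                               meta = list(simulated = TRUE, seed = spec$seed,
                                           shape_class = spec$shape_class)),
       truth = truth, mask = mask)
}

#' Simulate one complete synthetic micrograph
#'
#' Convenience wrapper: [sample_population()], [place_particles()] and
#' [render_scene()] in sequence, fully determined by the spec (including
#' its seed).
#'
#' @param spec a [scene_spec()].
#' @return As [render_scene()], plus `layout` and `spec`.
#' @export
simulate_scene <- function(spec) {
  shapes <- sample_population(spec)
  layout <- place_particles(shapes, spec$cluster_mean, spec$overlap_fraction,
                            spec$fov_nm, seed = spec$seed + 1000L)
  out <- render_scene(layout, spec)
  out$layout <- layout
  out$spec <- spec
  out
}

poly_to_wkt <- function(p) {
  ring <- rbind(p, p[1, , drop = FALSE])
  sprintf("POLYGON((%s))",
          paste(sprintf("%.6g %.6g", ring[, 1], ring[, 2]), collapse = ", "))
}

#' Write a simulated scene to disk
#'
#' Writes the micrograph as 16-bit grayscale TIFF, the ground truth as CSV
#' (with outlines as WKT polygons) and the scene specification as YAML.
#'
#' @param scene result of [simulate_scene()].
#' @param dir output directory (created if absent).
#' @param stem file name stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tif"))
  write_micrograph(scene$micrograph, tif)
  truth <- scene$truth
  truth$outline_wkt <- vapply(scene$layout, function(p) poly_to_wkt(p$outline), "")
  csv <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(truth, csv, row.names = FALSE)
  yml <- file.path(dir, paste0(stem, "_spec.yaml"))
  sp <- scene$spec
  yaml::write_yaml(sp[setdiff(names(sp), character(0))], yml)
  invisible(c(tif, csv, yml))
}
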