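#' Measure per-particle size and shape descriptors
#'
#' Computes the particle records for every label of a segmented
#' micrograph. The particle outline is taken as the boundary of the union
#' of its pixel squares (pixel-corner convention), which makes the
#' 10-pixel lower quantification limit exact; Feret diameters are measured
#' on the convex hull of those corners by rotating calipers. Ellipse axes
#' come from the second-order moments of the pixel set (with the 1/12
#' per-pixel variance correction). In `ellipse_fitting` mode the reported
#' `min_feret_nm` is the fitted short axis; the hull caliper width is
#' always kept in `feret_caliper_nm` for provenance.
#'
#' @param labels integer label matrix from [segment()] or
#'   [detect_particles()].
#' @param pixel_size_nm pixel calibration in nm.
#' @param mode analysis mode the labels were produced with; defaults to
#'   the `mode` attribute of `labels`.
#' @param image_id identifier copied into every record.
#' @return Data frame with one row per particle: `image_id`, `particle_id`,
#'   `mode`, `area_nm2`, `min_feret_nm`, `feret_caliper_nm`,
#'   `max_feret_nm`, `ecd_nm`, `convexity`, `short_axis_nm`,
#'   `long_axis_nm`, `center_x_nm`, `center_y_nm`, `border` (logical).
#' @export
measure_particles <- function(labels, pixel_size_nm, mode = NULL,
                              image_id = "img") {
  if (is.null(mode)) mode <- attr(labels, "mode") %||% "default"
  pix <- label_pixels(labels)
  nx <- nrow(labels); ny <- ncol(labels)
  rows <- lapply(names(pix), function(id) {
    xy <- as.matrix(pix[[id]])
    npx <- nrow(xy)
    area <- npx * pixel_size_nm^2
    corners <- unique(rbind(cbind(xy[, 1] - 1, xy[, 2] - 1),
                            cbind(xy[, 1], xy[, 2] - 1),
                            cbind(xy[, 1] - 1, xy[, 2]),
                            cbind(xy[, 1], xy[, 2]))) * pixel_size_nm
    hull <- convex_hull(corners)
    f <- feret_diameters(hull)
    hull_area <- if (nrow(hull) >= 3) polygon_area(hull) else area
    conv <- min(area / hull_area, 1)
    ctr <- (colMeans(xy) - 0.5) * pixel_size_nm
    # moment ellipse: pixel-center covariance + 1/12 px^2 square term
    if (npx > 1) {
      cv <- stats::cov(xy) * (npx - 1) / npx + diag(2) / 12
    } else {
      cv <- diag(2) / 12
    }
    lam <- pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
    long_axis <- 4 * sqrt(lam[1]) * pixel_size_nm
    short_axis <- 4 * sqrt(lam[2]) * pixel_size_nm
    border <- any(xy[, 1] == 1L | xy[, 1] == nx | xy[, 2] == 1L | xy[, 2] == ny)
    data.frame(image_id = image_id, particle_id = as.integer(id), mode = mode,
               area_nm2 = area,
               min_feret_nm = if (mode == "ellipse_fitting") short_axis else f$min,
               feret_caliper_nm = f$min,
               max_feret_nm = f$max, ecd_nm = ecd(area), convexity = conv,
               short_axis_nm = short_axis, long_axis_nm = long_axis,
               center_x_nm = ctr[1], center_y_nm = ctr[2], border = border)
  })
  if (!length(rows)) {
    return(data.frame(image_id = character(), particle_id = integer(),
                      mode = character(), area_nm2 = numeric(),
                      min_feret_nm = numeric(), feret_caliper_nm = numeric(),
                      max_feret_nm = numeric(), ecd_nm = numeric(),
                      convexity = numeric(), short_axis_nm = numeric(),
                      long_axis_nm = numeric(), center_x_nm = numeric(),
                      center_y_nm = numeric(), border = logical()))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply working-range and border filters to particle records
#'
#' Retains particles whose minimal Feret diameter lies inside the
#' quantification limits (`min_feret_nm >= lloq_nm`, boundary inclusive,
#' and `min_feret_nm <= uloq_nm`) and applies the border policy. A
#' rejection log counts particles removed per reason.
#'
#' @param particles data frame from [measure_particles()].
#' @param limits a [quantification_limits()].
#' @param border_policy `"exclude_touching"` or `"include"`.
#' @return List with `retained` (filtered data frame, flag columns
#'   `below_lloq`, `above_uloq`, `border` retained) and `log` (named
#'   counts: `input`, `below_lloq`, `above_uloq`, `border`, `retained`).
#' @export
apply_quantification_filters <- function(particles, limits,
                                         border_policy = c("exclude_touching",
                                                           "include")) {
  border_policy <- match.arg(border_policy)
  stopifnot(inherits(limits, "quantification_limits"))
  p <- particles
  p$below_lloq <- p$min_feret_nm < limits$lloq_nm
  p$above_uloq <- p$min_feret_nm > limits$uloq_nm
  drop_border <- border_policy == "exclude_touching" & p$border
  keep <- !p$below_lloq & !p$above_uloq & !drop_border
  list(retained = p[keep, , drop = FALSE],
       log = c(input = nrow(p),
               below_lloq = sum(p$below_lloq),
               above_uloq = sum(p$above_uloq),
               border = sum(drop_border),
               retained = sum(keep)))
}

#' Analyze one micrograph end to end
#'
#' Detection, measurement and working-range filtering for a single image.
#'
#' @param m a [micrograph()].
#' @param params a [detection_params()].
#' @param limits a [quantification_limits()]; defaults to the limits of
#'   the micrograph's own geometry.
#' @param image_id identifier for the records.
#' @return As [apply_quantification_filters()], plus `all_particles`
#'   (unfiltered records).
#' @export
analyze_micrograph <- function(m, params = detection_params(),
                               limits = NULL, image_id = "img") {
  stopifnot(inherits(m, "micrograph"))
  if (is.null(limits))
    limits <- quantification_limits(nrow(m$intensity) * m$pixel_size_nm,
                                    nrow(m$intensity))
  labels <- detect_particles(m, params)
  recs <- measure_particles(labels, m$pixel_size_nm, image_id = image_id)
  out <- apply_quantification_filters(recs, limits, params$border_policy)
  out$all_particles <- recs
  out$labels <- labels
  out
}
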