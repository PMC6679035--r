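#' Detection parameters for micrograph segmentation
#'
#' Bundles the image-analysis settings of a run. `smoothing_factor` is the
#' radius (in pixels) of the edge-preserving median denoiser; 0 disables
#' denoising. `min_otb` is the minimum object-to-background intensity
#' difference: candidate objects whose contrast against the local
#' background falls below it are suppressed. `mode` selects how touching
#' particles are separated:
#'
#' * `default`: distance-transform watershed splitting of touching,
#'   near-convex blobs (non-aggregated or slightly overlapping round
#'   particles);
#' * `irregular_watershed`: watershed followed by a convexity-driven merge
#'   step so elongated irregular particles are not over-split;
#' * `ellipse_fitting`: watershed splitting, with each particle reported
#'   through its moment-fitted ellipse (the short axis is the reported
#'   minimal Feret diameter);
#' * `single_particle`: no splitting; only blobs with convexity at or
#'   above `convexity_threshold` are retained, so that isolated particles
#'   stand in for the constituent particles of dense aggregates.
#'
#' @param smoothing_factor median-filter radius in pixels (>= 0).
#' @param min_otb minimum object-to-background intensity difference, in
#'   the intensity units of the image (>= 0).
#' @param mode one of `"default"`, `"irregular_watershed"`,
#'   `"ellipse_fitting"`, `"single_particle"`.
#' @param convexity_threshold convexity cut in (0, 1] used by
#'   `single_particle` mode (default 0.95).
#' @param merge_convexity convexity a merged pair must reach for
#'   `irregular_watershed` to fuse two fragments (default 0.92).
#' @param border_policy `"exclude_touching"` (default) drops particles
#'   touching the image border; `"include"` keeps them (flagged).
#' @param bg_block_px block size of the background-flattening estimator,
#'   in pixels; should exceed the largest expected particle.
#' @param watershed_tolerance minimum depth (in distance-map units,
#'   pixels) separating two catchment basins before they are split.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(smoothing_factor = 1,
                             min_otb = 50,
                             mode = c("default", "irregular_watershed",
                                      "ellipse_fitting", "single_particle"),
                             convexity_threshold = 0.95,
                             merge_convexity = 0.92,
                             border_policy = c("exclude_touching", "include"),
                             bg_block_px = 64,
                             watershed_tolerance = 1) {
  mode <- match.arg(mode)
  border_policy <- match.arg(border_policy)
  stopifnot(smoothing_factor >= 0, min_otb >= 0,
            convexity_threshold > 0, convexity_threshold <= 1,
            merge_convexity > 0, merge_convexity <= 1,
            bg_block_px >= 8, watershed_tolerance > 0)
  structure(list(smoothing_factor = smoothing_factor, min_otb = min_otb,
                 mode = mode, convexity_threshold = convexity_threshold,
                 merge_convexity = merge_convexity,
                 border_policy = border_policy, bg_block_px = bg_block_px,
                 watershed_tolerance = watershed_tolerance),
            class = "detection_params")
}

bilinear_upsample <- function(B, nx, ny, xc, yc) {
  # B[i, j] = coarse value at (xc[i], yc[j]); evaluate at pixel centers
  px <- seq_len(nx) - 0.5
  py <- seq_len(ny) - 0.5
  ix <- findInterval(px, xc, all.inside = TRUE)
  iy <- findInterval(py, yc, all.inside = TRUE)
  # t is allowed outside [0, 1]: linear extrapolation beyond the outermost
  # block centers keeps a linear field exactly linear at the image edges
  tx <- (px - xc[ix]) / (xc[ix + 1] - xc[ix])
  ty <- (py - yc[iy]) / (yc[iy + 1] - yc[iy])
  b00 <- B[cbind(rep(ix, length(iy)), rep(iy, each = length(ix)))]
  b10 <- B[cbind(rep(ix + 1, length(iy)), rep(iy, each = length(ix)))]
  b01 <- B[cbind(rep(ix, length(iy)), rep(iy + 1, each = length(ix)))]
  b11 <- B[cbind(rep(ix + 1, length(iy)), rep(iy + 1, each = length(ix)))]
  tX <- rep(tx, length(iy)); tY <- rep(ty, each = length(ix))
  v <- (1 - tX) * (1 - tY) * b00 + tX * (1 - tY) * b10 +
    (1 - tX) * tY * b01 + tX * tY * b11
  matrix(v, nx, ny)
}

#' Estimate the large-scale background of a bright-field micrograph
#'
#' Rolling-ball-style upper envelope: the image is tiled into blocks of
#' `block_px` pixels, an upper quantile of each block is taken as the
#' local background (dark particles occupy the lower tail), and the coarse
#' grid is interpolated bilinearly back to full resolution.
#'
#' @param img intensity matrix.
#' @param block_px block edge length in pixels.
#' @param q quantile regarded as background within a block.
#' @return Background matrix of the same size.
#' @keywords internal
estimate_background <- function(img, block_px = 64, q = 0.8) {
  nx <- nrow(img); ny <- ncol(img)
  bx <- max(2L, ceiling(nx / block_px))
  by <- max(2L, ceiling(ny / block_px))
  xb <- floor(seq(0, nx, length.out = bx + 1))
  yb <- floor(seq(0, ny, length.out = by + 1))
  B <- matrix(0, bx, by)
  for (i in seq_len(bx)) for (j in seq_len(by)) {
    B[i, j] <- stats::quantile(img[(xb[i] + 1):xb[i + 1], (yb[j] + 1):yb[j + 1]],
                               q, names = FALSE)
  }
  # light median smoothing of the coarse grid against block outliers
  if (bx >= 3 && by >= 3) {
    Bs <- B
    for (i in 2:(bx - 1)) for (j in 2:(by - 1))
      Bs[i, j] <- stats::median(B[(i - 1):(i + 1), (j - 1):(j + 1)])
    B <- Bs
  }
  xc <- (xb[-1] + xb[-(bx + 1)]) / 2
  yc <- (yb[-1] + yb[-(by + 1)]) / 2
  bilinear_upsample(B, nx, ny, xc, yc)
}

#' Preprocess a micrograph: denoise and flatten the background
#'
#' Edge-preserving median denoising (radius = `smoothing_factor`; identity
#' at 0) followed by subtraction of the large-scale background estimate.
#' The mean background level is added back, so flat regions keep their
#' intensity ordering and absolute scale.
#'
#' @param m a [micrograph()].
#' @param smoothing_factor median filter radius in pixels.
#' @param bg_block_px background estimator block size (pixels).
#' @return Corrected intensity matrix (same dimensions as the input).
#' @export
preprocess <- function(m, smoothing_factor = 1, bg_block_px = 64) {
  stopifnot(inherits(m, "micrograph"))
  img <- m$intensity
  r <- round(smoothing_factor)
  if (r > 0) {
    lo <- min(img); hi <- max(img)
    span <- if (hi > lo) hi - lo else 1
    norm <- (img - lo) / span
    norm <- EBImage::medianFilter(norm, size = as.integer(r))
    img <- norm * span + lo
  }
  bg <- estimate_background(img, block_px = bg_block_px)
  img - bg + mean(bg)
}

#' Threshold particles in a corrected micrograph
#'
#' Global automatic threshold by the inter-class variance (Otsu) criterion
#' on the corrected intensity histogram; dark pixels (bright-field
#' particles) below the threshold form the candidate mask. Candidate
#' objects whose median contrast against the background falls below
#' `min_otb` -- or below the image noise floor -- are suppressed, so a
#' blank image yields an empty mask.
#'
#' @param corrected matrix from [preprocess()].
#' @param min_otb minimum object-to-background intensity difference.
#' @return Logical mask matrix.
#' @export
threshold_particles <- function(corrected, min_otb = 50) {
  lo <- min(corrected); hi <- max(corrected)
  if (hi <= lo) return(matrix(FALSE, nrow(corrected), ncol(corrected)))
  norm <- (corrected - lo) / (hi - lo)
  thr <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
  mask <- norm < thr
  if (!any(mask) || all(mask)) return(mask & FALSE)
  bg_level <- stats::median(corrected[!mask])
  noise_sd <- stats::mad(corrected[!mask])
  labs <- EBImage::bwlabel(mask)
  nlab <- max(labs)
  if (nlab == 0) return(mask)
  med <- tapply(corrected[labs > 0], labs[labs > 0], stats::median)
  contrast <- bg_level - med
  floor_otb <- max(min_otb, 3 * noise_sd)
  bad <- as.integer(names(contrast))[contrast < floor_otb]
  if (length(bad)) mask[labs %in% bad] <- FALSE
  mask
}

label_pixels <- function(labels) {
  pos <- which(labels > 0)
  if (!length(pos)) return(list())
  ij <- arrayInd(pos, dim(labels))
  split.data.frame(ij, labels[pos])
}

mask_convexity <- function(xy) {
  corners <- rbind(cbind(xy[, 1] - 1, xy[, 2] - 1), cbind(xy[, 1], xy[, 2] - 1),
                   cbind(xy[, 1] - 1, xy[, 2]), cbind(xy[, 1], xy[, 2]))
  h <- convex_hull(unique(corners))
  ha <- if (nrow(h) >= 3) polygon_area(h) else nrow(xy)
  min(nrow(xy) / ha, 1)
}

touching_pairs <- function(labels) {
  p <- matrix(integer(0), 0, 2)
  nx <- nrow(labels); ny <- ncol(labels)
  a <- labels[-nx, ]; b <- labels[-1, ]
  s <- a > 0 & b > 0 & a != b
  if (any(s)) p <- rbind(p, cbind(a[s], b[s]))
  a <- labels[, -ny]; b <- labels[, -1]
  s <- a > 0 & b > 0 & a != b
  if (any(s)) p <- rbind(p, cbind(a[s], b[s]))
  # diagonal contacts
  a <- labels[-nx, -ny]; b <- labels[-1, -1]
  s <- a > 0 & b > 0 & a != b
  if (any(s)) p <- rbind(p, cbind(a[s], b[s]))
  a <- labels[-nx, -1]; b <- labels[-1, -ny]
  s <- a > 0 & b > 0 & a != b
  if (any(s)) p <- rbind(p, cbind(a[s], b[s]))
  if (!nrow(p)) return(p)
  unique(t(apply(p, 1, sort)))
}

#' Segment a particle mask into labelled constituent particles
#'
#' Dispatches on the analysis mode of `params`; see [detection_params()]
#' for the mode semantics. Labels are re-numbered consecutively from 1.
#'
#' @param mask logical mask from [threshold_particles()].
#' @param corrected corrected intensity matrix (reserved for
#'   intensity-guided refinements; the geometric modes ignore it).
#' @param params a [detection_params()].
#' @return Integer label matrix with attributes `mode` and `params`.
#' @export
segment <- function(mask, corrected = NULL, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  storage.mode(mask) <- "logical"
  labels <- switch(params$mode,
    default = ,
    ellipse_fitting = split_watershed(mask, params$watershed_tolerance),
    irregular_watershed = merge_by_convexity(
      split_watershed(mask, params$watershed_tolerance),
      params$merge_convexity),
    single_particle = keep_convex_blobs(mask, params$convexity_threshold),
    stop("unknown mode: ", params$mode))
  labels <- relabel(labels)
  attr(labels, "mode") <- params$mode
  attr(labels, "params") <- params
  labels
}

split_watershed <- function(mask, tolerance = 1) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask)
  w <- EBImage::watershed(d, tolerance = tolerance, ext = 1)
  matrix(as.integer(w), nrow(mask), ncol(mask))
}

keep_convex_blobs <- function(mask, convexity_threshold) {
  labels <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  pix <- label_pixels(labels)
  if (!length(pix)) return(labels)
  conv <- vapply(pix, function(ij) mask_convexity(as.matrix(ij)), 0)
  drop <- as.integer(names(conv))[conv < convexity_threshold]
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

merge_by_convexity <- function(labels, merge_convexity) {
  repeat {
    pairs <- touching_pairs(labels)
    if (!nrow(pairs)) break
    pix <- label_pixels(labels)
    conv <- vapply(pix, function(ij) mask_convexity(as.matrix(ij)), 0)
    merged <- FALSE
    # evaluate candidate merges, best (most convex union) first
    gain <- apply(pairs, 1, function(pr) {
      u <- rbind(as.matrix(pix[[as.character(pr[1])]]),
                 as.matrix(pix[[as.character(pr[2])]]))
      mask_convexity(u)
    })
    ord <- order(gain, decreasing = TRUE)
    for (i in ord) {
      if (gain[i] < merge_convexity) break
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (!any(labels == a) || !any(labels == b)) next
      labels[labels == b] <- a
      merged <- TRUE
      break  # recompute adjacency after each merge
    }
    if (!merged) break
  }
  labels
}

relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (!length(u)) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  labels[labels > 0] <- map[labels[labels > 0]]
  labels
}

#' Detect and segment particles in a micrograph
#'
#' Full detection chain: [preprocess()], [threshold_particles()],
#' [segment()]. Deterministic for identical inputs and parameters.
#'
#' @param m a [micrograph()].
#' @param params a [detection_params()].
#' @return Label matrix as returned by [segment()].
#' @export
detect_particles <- function(m, params = detection_params()) {
  corrected <- preprocess(m, params$smoothing_factor, params$bg_block_px)
  mask <- threshold_particles(corrected, params$min_otb)
  segment(mask, corrected, params)
}
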