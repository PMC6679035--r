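#' Polygon geometry for particle measurands
#'
#' Low-level, exact polygon primitives used throughout the package: signed
#' area, centroid, convex hull, caliper (Feret) diameters and second-order
#' moments. All functions take an `n x 2` numeric matrix of vertex
#' coordinates (closed implicitly; the last vertex must not repeat the
#' first). Units are whatever the caller supplies (nm everywhere in this
#' package).
#'
#' @name polygon-geometry
#' @keywords internal
NULL

as_poly_matrix <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 1L || !is.numeric(p))
    stop("polygon must be an n x 2 numeric matrix")
  storage.mode(p) <- "double"
  unname(p)
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param p n x 2 vertex matrix.
#' @param signed return the signed area (positive for counter-clockwise
#'   vertex order)? Default `FALSE`.
#' @return Numeric scalar area.
#' @export
polygon_area <- function(p, signed = FALSE) {
  p <- as_poly_matrix(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

#' Polygon centroid
#' @inheritParams polygon_area
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(p) {
  p <- as_poly_matrix(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(p))))
    return(colMeans(p))  # degenerate: fall back to vertex mean
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Convex hull of a point set as an ordered polygon
#'
#' Thin wrapper around [grDevices::chull()] returning the hull vertices in
#' counter-clockwise order.
#'
#' @param p n x 2 coordinate matrix.
#' @return Hull vertex matrix (counter-clockwise).
#' @export
convex_hull <- function(p) {
  p <- as_poly_matrix(p)
  h <- grDevices::chull(p[, 1], p[, 2])
  hp <- p[h, , drop = FALSE]
  if (nrow(hp) >= 3L && polygon_area(hp, signed = TRUE) < 0)
    hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  hp
}

#' Minimal Feret (caliper) diameter of a polygon
#'
#' The minimal Feret diameter is the smallest width of the particle outline
#' over all caliper directions. For a polygon this minimum is attained with
#' one caliper jaw flush against a convex-hull edge, so the exact value is
#' the minimum over hull edges of the maximal vertex distance to the edge
#' line (rotating-calipers construction).
#'
#' @param p n x 2 vertex matrix (any simple polygon; the convex hull is
#'   taken internally).
#' @return List with `width` (the minimal Feret diameter), `angle_deg`
#'   (direction of the caliper axis, i.e. of the width measurement, in
#'   degrees in `[0, 180)`), and `degenerate` (`TRUE` when all vertices are
#'   collinear, in which case `width` is 0).
#' @seealso [max_feret()], [feret_diameters()]
#' @export
min_feret <- function(p) {
  h <- convex_hull(p)
  n <- nrow(h)
  if (n < 3L) {
    return(list(width = 0, angle_deg = NA_real_, degenerate = TRUE))
  }
  best <- Inf; best_ang <- NA_real_
  nxt <- c(seq_len(n)[-1], 1L)
  ex <- h[nxt, 1] - h[, 1]
  ey <- h[nxt, 2] - h[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  if (!any(keep)) return(list(width = 0, angle_deg = NA_real_, degenerate = TRUE))
  for (i in which(keep)) {
    # unit normal of edge i
    nx <- -ey[i] / len[i]; ny <- ex[i] / len[i]
    d <- (h[, 1] - h[i, 1]) * nx + (h[, 2] - h[i, 2]) * ny
    w <- max(abs(d))
    if (w < best) {
      best <- w
      best_ang <- atan2(ny, nx) * 180 / pi
    }
  }
  if (best == 0)
    return(list(width = 0, angle_deg = NA_real_, degenerate = TRUE))
  list(width = best, angle_deg = best_ang %% 180, degenerate = FALSE)
}

#' Maximal Feret diameter of a polygon
#'
#' Largest distance between any two outline points; for a polygon this is
#' the maximal pairwise distance between convex-hull vertices.
#'
#' @inheritParams min_feret
#' @return Numeric scalar.
#' @export
max_feret <- function(p) {
  h <- convex_hull(p)
  n <- nrow(h)
  if (n == 1L) return(0)
  d <- stats::dist(h)
  max(d)
}

#' Minimal and maximal Feret diameters in one call
#' @inheritParams min_feret
#' @return List `min`, `max`, `angle_min_deg`, `degenerate`.
#' @export
feret_diameters <- function(p) {
  mn <- min_feret(p)
  list(min = mn$width, max = max_feret(p),
       angle_min_deg = mn$angle_deg, degenerate = mn$degenerate)
}

#' Equivalent circular diameter from projected area
#'
#' Diameter of the circle with the same projected area as the particle.
#'
#' @param area_nm2 projected area (nm^2); must be positive.
#' @return ECD in nm.
#' @export
ecd <- function(area_nm2) {
  if (any(!is.finite(area_nm2)) || any(area_nm2 <= 0))
    stop("area must be positive")
  sqrt(4 * area_nm2 / pi)
}

#' Second-order moments and fitted-ellipse axes of a polygon
#'
#' Exact area, centroid and central second moments by Green's theorem,
#' plus the axes of the uniform-density ellipse with the same moments.
#' For an exact ellipse outline the fitted axes equal the true axes.
#'
#' @inheritParams min_feret
#' @return List: `area`, `centroid`, `cov` (2 x 2 covariance of the uniform
#'   density over the polygon), `major_axis`, `minor_axis` (full lengths),
#'   `orientation_deg` (major-axis direction in `[0, 180)`).
#' @export
polygon_moments <- function(p) {
  p <- as_poly_matrix(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a == 0) stop("degenerate polygon (zero area)")
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw second moments about the origin
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12        # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12        # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  vxx <- iyy / a - cx^2
  vyy <- ixx / a - cy^2
  vxy <- ixy / a - cx * cy
  cov <- matrix(c(vxx, vxy, vxy, vyy), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  list(area = abs(a), centroid = c(cx, cy), cov = cov,
       major_axis = 4 * sqrt(lam[1]), minor_axis = 4 * sqrt(lam[2]),
       orientation_deg = ang %% 180)
}

#' Convexity (solidity) of a polygon
#'
#' Ratio of the polygon area to its convex-hull area; 1 for convex shapes.
#'
#' @inheritParams min_feret
#' @return Numeric in (0, 1].
#' @export
polygon_convexity <- function(p) {
  a <- polygon_area(p)
  h <- polygon_area(convex_hull(p))
  if (h == 0) return(NA_real_)
  min(a / h, 1)
}

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' @param subject n x 2 subject polygon (any simple polygon).
#' @param clip m x 2 convex clip polygon.
#' @return Vertex matrix of the intersection (possibly 0 rows).
#' @keywords internal
clip_polygon <- function(subject, clip) {
  clip <- as_poly_matrix(clip)
  if (polygon_area(clip, signed = TRUE) < 0)
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- as_poly_matrix(subject)
  m <- nrow(clip)
  for (i in seq_len(m)) {
    n <- nrow(out)
    if (n == 0L) break
    a <- clip[i, ]; b <- clip[if (i == m) 1L else i + 1L, ]
    # inside = left of directed edge a->b (clip is CCW)
    inside <- (b[1] - a[1]) * (out[, 2] - a[2]) -
      (b[2] - a[2]) * (out[, 1] - a[1]) >= 0
    nxt <- c(seq_len(n)[-1], 1L)
    crossing <- inside != inside[nxt]
    # vectorized segment/line intersections for all crossing edges
    d1x <- out[nxt, 1] - out[, 1]; d1y <- out[nxt, 2] - out[, 2]
    d2x <- b[1] - a[1]; d2y <- b[2] - a[2]
    den <- d1x * d2y - d1y * d2x
    t <- ((a[1] - out[, 1]) * d2y - (a[2] - out[, 2]) * d2x) /
      ifelse(den == 0, 1, den)
    ix <- out[, 1] + t * d1x
    iy <- out[, 2] + t * d1y
    # emit kept vertices (key 2j) then intersection points (key 2j + 1)
    keys <- c(2 * which(inside), 2 * which(crossing) + 1)
    pts <- rbind(out[inside, , drop = FALSE],
                 cbind(ix[crossing], iy[crossing]))
    out <- pts[order(keys), , drop = FALSE]
  }
  out
}

#' Pairwise overlap fraction of two polygons
#'
#' Intersection area divided by the area of the smaller polygon. At least
#' one of the two polygons must be convex (its hull is used as the clip
#' region; for star-convex irregular outlines this slightly overestimates
#' the overlap, which is conservative for placement checks).
#'
#' @param p1,p2 vertex matrices.
#' @return Overlap fraction in `[0, 1]`.
#' @export
polygon_overlap_fraction <- function(p1, p2) {
  p1 <- as_poly_matrix(p1); p2 <- as_poly_matrix(p2)
  if (max(p1[, 1]) <= min(p2[, 1]) || max(p2[, 1]) <= min(p1[, 1]) ||
      max(p1[, 2]) <= min(p2[, 2]) || max(p2[, 2]) <= min(p1[, 2]))
    return(0)
  a1 <- polygon_area(p1); a2 <- polygon_area(p2)
  inter <- clip_polygon(p1, convex_hull(p2))
  ai <- if (nrow(inter) >= 3) polygon_area(inter) else 0
  ai / min(a1, a2)
}
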