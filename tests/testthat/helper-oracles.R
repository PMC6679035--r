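# Independent geometric oracles, deliberately naive: a dense directional
# sweep with local refinement, no use of the rotating-calipers code path.

brute_min_feret <- function(p, step_deg = 0.01) {
  p <- as.matrix(p)
  width_at <- function(theta) {
    u <- c(cos(theta), sin(theta))
    pr <- p %*% u
    max(pr) - min(pr)
  }
  th <- seq(0, pi, by = step_deg * pi / 180)
  M <- cbind(cos(th), sin(th)) %*% t(p)
  w <- apply(M, 1, max) - apply(M, 1, min)
  n <- length(w)
  # refine every local minimum basin of the sweep (minima can be nearly tied)
  locmin <- which(w <= c(w[-1], Inf) & w <= c(Inf, w[-n]))
  best <- min(w)
  for (i in locmin) {
    lo <- th[max(i - 1, 1)]; hi <- th[min(i + 1, n)]
    best <- min(best, stats::optimize(width_at, c(lo, hi), tol = 1e-12)$objective)
  }
  best
}

brute_max_feret <- function(p) {
  p <- as.matrix(p)
  max(stats::dist(p))
}

random_convex_polygon <- function(n_pts = 12, scale = 10) {
  pts <- matrix(stats::rnorm(2 * n_pts), ncol = 2) * scale
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

rotate_pts <- function(p, ang) {
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  as.matrix(p) %*% t(R)
}
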