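#' Median of a minimal Feret diameter distribution
#'
#' Sample median of the retained per-particle values of one specimen
#' (pooled over its images). For an even number of particles the median is
#' the mean of the two central order statistics.
#'
#' @param values numeric vector of minimal Feret diameters (nm).
#' @return Median in nm.
#' @export
median_min_feret <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no particles survive filters: empty distribution")
  stats::median(values)
}

#' Modal equivalent circular diameter via a normal fit
#'
#' Fits a normal distribution to the raw per-particle ECD values by
#' maximum likelihood and reports its location parameter as the mode.
#' A Freedman-Diaconis histogram is returned alongside for reporting; the
#' binning has no influence on the fitted mode. For strongly skewed
#' samples the fitted-normal mode can differ from the histogram peak; both
#' are reported.
#'
#' @param values numeric vector of ECD values (nm); at least 10 required
#'   for a stable fit.
#' @return List with `mode_nm` (fitted normal location), `sd_nm`,
#'   `histogram` (a [graphics::hist()] object, not plotted) and
#'   `hist_peak_nm` (midpoint of the fullest bin).
#' @export
modal_ecd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 10) stop("at least 10 particles needed for the modal fit")
  # normal MLE: location = sample mean, scale = population sd
  mode_nm <- mean(values)
  sd_nm <- sqrt(mean((values - mode_nm)^2))
  h <- graphics::hist(values, breaks = "FD", plot = FALSE)
  peak <- h$mids[which.max(h$counts)]
  list(mode_nm = mode_nm, sd_nm = sd_nm, histogram = h, hist_peak_nm = peak)
}

#' Summarize particle records per specimen
#'
#' Pools the retained particle records of one specimen (typically the 10
#' images of one grid) and computes the number-based summary used by the
#' validation statistics.
#'
#' @param particles retained particle data frame (see
#'   [apply_quantification_filters()]).
#' @param material,day,replicate identifiers copied into the summary.
#' @return One-row data frame: `material`, `day`, `replicate`, `n`,
#'   `median_min_feret_nm`, and (when `n >= 10`) `modal_ecd_nm`.
#' @export
summarize_specimen <- function(particles, material = NA, day = NA,
                               replicate = NA) {
  n <- nrow(particles)
  med <- median_min_feret(particles$min_feret_nm)
  mode_nm <- if (n >= 10) modal_ecd(particles$ecd_nm)$mode_nm else NA_real_
  data.frame(material = material, day = day, replicate = replicate, n = n,
             median_min_feret_nm = med, modal_ecd_nm = mode_nm)
}
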