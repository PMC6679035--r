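#' Calibrated micrograph container
#'
#' A micrograph is a square (or rectangular) grayscale intensity grid with
#' a pixel calibration in nm and free-form identifying metadata (material,
#' day, replicate, image index). The intensity matrix is indexed
#' `[x, y]` with x to the right and y downwards; pixel `(i, j)` covers the
#' square `[(i-1), i] x [(j-1), j]` in pixel units, so its center is at
#' `(i - 0.5, j - 0.5) * pixel_size_nm`.
#'
#' @param intensity numeric matrix of intensities (arbitrary units).
#' @param pixel_size_nm edge length of one pixel in nm (> 0).
#' @param meta named list of identifiers.
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(intensity, pixel_size_nm, meta = list()) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity) || length(intensity) == 0)
    stop("intensity must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a single positive number")
  structure(list(intensity = intensity, pixel_size_nm = pixel_size_nm,
                 meta = meta), class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph %d x %d px, pixel size %.4g nm (fov %.4g nm)\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_nm,
              nrow(x$intensity) * x$pixel_size_nm))
  if (length(x$meta)) utils::str(x$meta, give.attr = FALSE)
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$intensity)

#' Pixel size from field of view and camera size
#'
#' @param fov_nm field-of-view edge length in nm.
#' @param n_pixels number of pixels along the same edge.
#' @return Pixel size in nm.
#' @export
pixel_size <- function(fov_nm, n_pixels) {
  if (any(fov_nm <= 0) || any(n_pixels <= 0))
    stop("fov_nm and n_pixels must be positive")
  fov_nm / n_pixels
}

#' Working-range quantification limits for a magnification
#'
#' The detection floor (LOD) is one pixel. Reliable quantification of the
#' minimal Feret diameter requires at least 10 pixels (avoiding the large
#' systematic deviations seen for smaller rasterized particles), giving
#' the lower limit of quantification LLOQ = 10 x pixel size. The upper
#' limit of quantification is one tenth of the image (field-of-view) size.
#'
#' @inheritParams pixel_size
#' @return Object of class `quantification_limits`: list with `lod_nm`,
#'   `lloq_nm`, `uloq_nm`, `fov_nm`, `n_pixels`.
#' @export
quantification_limits <- function(fov_nm, n_pixels) {
  lod <- pixel_size(fov_nm, n_pixels)
  structure(list(lod_nm = lod, lloq_nm = 10 * lod, uloq_nm = fov_nm / 10,
                 fov_nm = fov_nm, n_pixels = n_pixels),
            class = "quantification_limits")
}

#' @export
print.quantification_limits <- function(x, ...) {
  cat(sprintf("LOD %s nm, LLOQ %s nm, ULOQ %s nm (fov %g nm, %d px, range factor %.3g)\n",
              format_size_nm(x$lod_nm), format_size_nm(x$lloq_nm),
              format_size_nm(x$uloq_nm), x$fov_nm, as.integer(x$n_pixels),
              working_range_factor(x$n_pixels)))
  invisible(x)
}

#' Working-range factor of a camera
#'
#' Ratio of the upper to the lower quantification limit. It depends only
#' on the camera pixel count: ULOQ / LLOQ = n_pixels / 100 (a factor of
#' about 40 for a 4k camera), independent of magnification.
#'
#' @param n_pixels camera edge length in pixels (>= 100).
#' @return Dimensionless ratio.
#' @export
working_range_factor <- function(n_pixels) {
  stopifnot(n_pixels >= 100)
  n_pixels / 100
}

#' Report-precision rounding for sizes in nm
#'
#' House style for reported limits and sizes: two decimals below ~1 nm
#' pixel-scale values (LOD), one decimal otherwise.
#'
#' @param x sizes in nm.
#' @param decimals override the number of decimals.
#' @return Character vector.
#' @export
format_size_nm <- function(x, decimals = NULL) {
  if (is.null(decimals)) decimals <- ifelse(x < 2, 2L, 1L)
  sprintf(paste0("%.", decimals, "f"), round(x, decimals))
}

#' Read a micrograph from a TIFF or PNG file
#'
#' Exactly one of `pixel_size_nm` and `fov_nm` must be given. Multi-channel
#' images are converted to grayscale by averaging channels.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_nm pixel calibration in nm.
#' @param fov_nm alternatively, the field-of-view edge length in nm.
#' @param meta metadata list attached to the result.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_nm = NULL, fov_nm = NULL,
                            meta = list()) {
  if (is.null(pixel_size_nm) == is.null(fov_nm))
    stop("give exactly one of pixel_size_nm or fov_nm")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png_read(path),
                stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  # image files are stored row-major (y, x); transpose to [x, y]
  img <- t(arr)
  if (is.null(pixel_size_nm)) pixel_size_nm <- fov_nm / nrow(img)
  meta$source <- path
  micrograph(img, pixel_size_nm, meta)
}

png_read <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG files")
  png::readPNG(path)
}

#' Write a micrograph as 16-bit grayscale TIFF
#'
#' Intensities are rescaled linearly to `[0, 1]` over their observed range
#' (or a caller-supplied range) before writing.
#'
#' @param m a [micrograph()].
#' @param path output path.
#' @param range intensity range mapped to black..white; default observed.
#' @return Invisibly, `path`.
#' @export
write_micrograph <- function(m, path, range = NULL) {
  stopifnot(inherits(m, "micrograph"))
  img <- m$intensity
  if (is.null(range)) range <- range(img)
  span <- diff(range)
  if (span <= 0) span <- 1
  norm <- pmin(pmax((img - range[1]) / span, 0), 1)
  tiff::writeTIFF(t(norm), path, bits.per.sample = 16)
  invisible(path)
}
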