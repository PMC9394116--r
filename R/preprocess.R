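# Image-to-curve preprocessing chain: black/white reflectance calibration,
# ROI-mean curve extraction (with optional per-pixel wavelet denoising),
# band-window truncation and maximum normalization.

#' Black/white reflectance calibration
#'
#' Converts raw digital numbers to relative reflectance against a dark-current
#' and a white-reference image: `(raw - black) / (white - black)`, elementwise.
#' References may be full arrays of the same shape as `raw` or per-band
#' vectors recycled across pixels (for a pixels-by-bands matrix, a vector of
#' length `ncol(raw)`).
#'
#' @param raw Nonnegative numeric vector, matrix (pixels x bands) or array.
#' @param white,black Reference measurements, same shape as `raw` or
#'   per-band vectors.
#' @return Calibrated reflectance, same shape as `raw`.
#' @examples
#' calibrate(matrix(50, 2, 3), white = rep(100, 3), black = rep(0, 3))
#' @export
calibrate <- function(raw, white, black) {
  expand <- function(ref) {
    if (length(ref) == length(raw)) return(array(ref, dim = dim(raw) %||% length(raw)))
    if (is.matrix(raw) && length(ref) == ncol(raw)) {
      return(matrix(ref, nrow(raw), ncol(raw), byrow = TRUE))
    }
    if (length(ref) == 1) return(array(ref, dim = dim(raw) %||% length(raw)))
    stop("reference shape is not broadcast-compatible with `raw`", call. = FALSE)
  }
  w <- expand(white)
  b <- expand(black)
  denom <- w - b
  if (any(denom <= 0)) {
    stop("degenerate reference: `white - black` must be strictly positive",
         call. = FALSE)
  }
  (raw - b) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean curve over a region of interest
#'
#' Extracts the per-pixel curves of a hyperspectral or fluorescence image cube
#' inside a mask and averages them channelwise. When a [wavelet_spec()] is
#' supplied, each pixel curve is denoised before averaging (the thresholding
#' is nonlinear, so pixel-wise denoising and averaging do not commute);
#' `per_pixel = FALSE` switches to the faster average-then-denoise path.
#'
#' @param cube Numeric array, rows x cols x channels.
#' @param mask Logical matrix, rows x cols, with at least one `TRUE` pixel.
#' @param spec Optional [wavelet_spec()]; `NULL` skips denoising.
#' @param per_pixel Denoise each pixel curve before averaging (default) or
#'   denoise the averaged curve once.
#' @return Numeric vector of length `dim(cube)[3]`.
#' @export
roi_mean_curve <- function(cube, mask, spec = NULL, per_pixel = TRUE) {
  stopifnot(length(dim(cube)) == 3, is.logical(mask))
  if (!all(dim(mask) == dim(cube)[1:2])) {
    stop("`mask` shape must equal the cube's spatial shape", call. = FALSE)
  }
  sel <- which(mask)
  if (length(sel) == 0) stop("empty ROI mask", call. = FALSE)
  px <- matrix(cube, prod(dim(cube)[1:2]), dim(cube)[3])[sel, , drop = FALSE]
  if (!is.null(spec) && per_pixel) {
    px <- t(apply(px, 1, denoise_curve, spec = spec))
  }
  curve <- colMeans(px)
  if (!is.null(spec) && !per_pixel) curve <- denoise_curve(curve, spec)
  curve
}

#' Truncate a curve to a wavelength window
#'
#' Keeps the entries whose wavelengths fall inside the closed interval
#' `[low, high]`, preserving order. The defaults retain the 454--957 nm
#' visible/near-infrared window used for modelling (396 bands for a
#' 380--1030 nm instrument at its native sampling).
#'
#' @param curve Numeric vector.
#' @param wavelengths Strictly increasing numeric vector, same length as
#'   `curve` (nm).
#' @param low,high Window bounds in nm (inclusive).
#' @return The retained entries of `curve`, with the retained wavelengths in
#'   attribute `"wavelengths"`.
#' @examples
#' truncate_bands(seq_len(651), wavelengths = 380:1030)
#' @export
truncate_bands <- function(curve, wavelengths, low = 454, high = 957) {
  if (length(curve) != length(wavelengths)) {
    stop("`curve` and `wavelengths` lengths differ", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("`wavelengths` must be strictly increasing", call. = FALSE)
  }
  if (low > high) stop("`low` must be <= `high`", call. = FALSE)
  keep <- wavelengths >= low & wavelengths <= high
  if (!any(keep)) stop("no wavelength falls inside the window", call. = FALSE)
  structure(curve[keep], wavelengths = wavelengths[keep])
}

#' Maximum normalization
#'
#' Scales a curve by its maximum so the normalized maximum is exactly 1.
#' Scale-invariant (`max_normalize(k * x) == max_normalize(x)` for `k > 0`)
#' and idempotent.
#'
#' @param curve Numeric vector with a strictly positive maximum.
#' @return `curve / max(curve)`.
#' @examples
#' max_normalize(c(2, 4, 8))
#' @export
max_normalize <- function(curve) {
  m <- max(curve)
  if (!is.finite(m) || m <= 0) {
    stop("degenerate curve: maximum must be strictly positive", call. = FALSE)
  }
  curve / m
}

#' Full curve-extraction chain for one sample
#'
#' Convenience wrapper running the whole preprocessing pipeline on one image:
#' black/white calibration per pixel, per-pixel wavelet denoising, ROI
#' averaging, band truncation and maximum normalization. For fluorescence
#' cubes pass `spec = NULL` and `wavelengths = NULL` (kinetic curves are only
#' averaged and normalized).
#'
#' @param cube Raw image cube, rows x cols x channels.
#' @param mask Logical ROI mask, rows x cols.
#' @param white,black Per-channel reference vectors (length channels) or
#'   arrays shaped like `cube`; `NULL` skips calibration.
#' @param wavelengths Per-channel wavelengths (nm) for band truncation;
#'   `NULL` keeps all channels.
#' @param spec Optional [wavelet_spec()] for per-pixel denoising.
#' @param low,high Band window (nm), used when `wavelengths` is given.
#' @return Normalized curve (numeric vector).
#' @export
extract_sample_curve <- function(cube, mask, white = NULL, black = NULL,
                                 wavelengths = NULL, spec = wavelet_spec(),
                                 low = 454, high = 957) {
  if (!is.null(white)) {
    nch <- dim(cube)[3]
    px <- matrix(cube, ncol = nch)
    px <- calibrate(px, white, black %||% 0)
    cube <- array(px, dim = dim(cube))
  }
  curve <- roi_mean_curve(cube, mask, spec = spec)
  if (!is.null(wavelengths)) {
    curve <- truncate_bands(curve, wavelengths, low, high)
  }
  max_normalize(curve)
}
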