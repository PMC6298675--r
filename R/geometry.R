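# Parallel-beam projection geometry.
#
# Discrete conventions used throughout the package:
#   * the image is a square N x N matrix; the first index is the x axis,
#     the second the y axis; the isocenter (rotation center) sits at the
#     pixel with 0-based index floor(N/2) on both axes;
#   * a view angle theta is measured counterclockwise from the +x axis and
#     lives in [0, pi);
#   * the detector coordinate r is the signed distance to the isocenter in
#     pixel units; bins are unit-spaced and centered at r = 0.

#' Construct a CT image
#'
#' A `ct_image` is a square numeric matrix of attenuation values with a
#' pixel size attribute (relative units, default 1).  The first matrix
#' index is the x axis, the second the y axis.
#'
#' @param pixels square numeric matrix, all values finite, at least 2 x 2.
#' @param pixel_size positive pixel edge length in relative units.
#' @return a `ct_image` object.
#' @examples
#' img <- ct_image(matrix(0, 8, 8))
#' @export
ct_image <- function(pixels, pixel_size = 1) {
  .assert_finite_matrix(pixels, "image")
  if (nrow(pixels) != ncol(pixels)) {
    .stop_typed("tomowiener_geometry_error", "image must be square")
  }
  if (nrow(pixels) < 2) {
    .stop_typed("tomowiener_geometry_error", "image must be at least 2 x 2")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    .stop_typed("tomowiener_value_error", "pixel_size must be a positive scalar")
  }
  structure(pixels, pixel_size = pixel_size, class = c("ct_image", "matrix", "array"))
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d, pixel size %g, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

.as_image_matrix <- function(image) {
  m <- unclass(image)
  attr(m, "pixel_size") <- NULL
  m
}

#' Uniform view angles over the half circle
#'
#' @param n_views number of projection angles.
#' @return numeric vector of angles in radians, uniformly spaced over
#'   `[0, pi)` starting at 0.
#' @examples
#' uniform_angles(4)
#' @export
uniform_angles <- function(n_views) {
  if (n_views < 1) .stop_typed("tomowiener_value_error", "n_views must be >= 1")
  seq(0, pi, length.out = n_views + 1)[seq_len(n_views)]
}

.validate_angles <- function(angles) {
  if (length(angles) < 1 || !is.numeric(angles) || !all(is.finite(angles))) {
    .stop_typed("tomowiener_value_error", "angles must be a non-empty finite numeric vector")
  }
  if (any(angles < 0 | angles >= pi)) {
    .stop_typed("tomowiener_value_error", "angles must lie in [0, pi)")
  }
  if (length(angles) > 1 && any(diff(angles) <= 0)) {
    .stop_typed("tomowiener_value_error", "angles must be strictly increasing")
  }
  as.numeric(angles)
}

#' Number of detector bins covering an N x N image
#'
#' The detector must span the image corner to corner
#' (`ceiling(N * sqrt(2))`), rounded up to the next odd integer so that a
#' center bin exists exactly at r = 0.
#'
#' @param n image side length in pixels.
#' @return odd integer bin count.
#' @export
n_detector_bins <- function(n) {
  nb <- ceiling(n * sqrt(2))
  if (nb %% 2 == 0) nb <- nb + 1
  as.integer(nb)
}

#' Construct a sinogram
#'
#' A `ct_sinogram` holds projection data with one row per view angle and one
#' column per detector bin.  Bin centers are unit-spaced signed distances to
#' the isocenter, centered at zero.
#'
#' @param values numeric matrix, `n_views` x `n_bins`.
#' @param angles view angles in radians, strictly increasing, in `[0, pi)`;
#'   row `i` of `values` corresponds to `angles[i]`.
#' @param bin_spacing detector bin width (equals the image pixel size).
#' @param image_size side length of the image the sinogram was computed from
#'   (used as the default reconstruction size); may be `NULL`.
#' @return a `ct_sinogram` object.
#' @export
ct_sinogram <- function(values, angles, bin_spacing = 1, image_size = NULL) {
  .assert_finite_matrix(values, "sinogram")
  angles <- .validate_angles(angles)
  if (nrow(values) != length(angles)) {
    .stop_typed("tomowiener_geometry_error",
                "sinogram must have one row per angle")
  }
  structure(values,
            angles = angles,
            bin_spacing = bin_spacing,
            image_size = if (is.null(image_size)) NULL else as.integer(image_size),
            class = c("ct_sinogram", "matrix", "array"))
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf("<ct_sinogram> %d views x %d bins, angles [%.3f, %.3f] rad\n",
              nrow(x), ncol(x), min(attr(x, "angles")), max(attr(x, "angles"))))
  invisible(x)
}

#' Detector bin centers of a sinogram
#'
#' @param sino a `ct_sinogram` (or any matrix whose columns are bins).
#' @return signed bin-center distances from the isocenter, in pixel units.
#' @export
bin_centers <- function(sino) {
  nb <- ncol(sino)
  (seq_len(nb) - 1) - (nb - 1) / 2
}

#' Discrete Radon transform (forward projection)
#'
#' Pixel-driven projector: each pixel (optionally subdivided into
#' `supersample^2` subpixels) contributes its value to detector bins at its
#' projected signed distance `x cos(theta) + y sin(theta)`.  With
#' `interp = "nearest"` the whole (sub)pixel value lands in the nearest bin;
#' with `interp = "linear"` it is split linearly between the two adjacent
#' bins.  Both variants conserve the per-view mass exactly (projected mass
#' falling beyond the detector edge is clamped to the edge bin; with the
#' corner-to-corner detector of [n_detector_bins()] this affects at most a
#' sub-pixel fringe).
#'
#' The default, `interp = "nearest"` with `supersample = 1`, is the crudest
#' and fastest projector.  `interp = "linear"` with `supersample = 4` is the
#' accurate variant used when per-bin fidelity to the underlying line
#' integrals matters; see [line_integral_oracle()] for the reference it is
#' checked against.
#'
#' @param image square `ct_image` or plain numeric matrix.
#' @param angles view angles (radians, in `[0, pi)`, strictly increasing).
#' @param interp bin-assignment rule, `"nearest"` or `"linear"`.
#' @param supersample integer >= 1; each pixel is subdivided into
#'   `supersample^2` subpixels before binning.
#' @return a `ct_sinogram` with `length(angles)` rows and
#'   `n_detector_bins(nrow(image))` columns.
#' @examples
#' img <- ellipse_phantom(32, data.frame(x = 0, y = 0, a = 0.5, b = 0.5,
#'                                       phi = 0, value = 1))
#' sino <- radon(img, uniform_angles(16))
#' @export
radon <- function(image, angles, interp = c("nearest", "linear"), supersample = 1L) {
  interp <- match.arg(interp)
  if (!inherits(image, "ct_image")) image <- ct_image(as.matrix(image))
  angles <- .validate_angles(angles)
  supersample <- as.integer(supersample)
  if (supersample < 1) .stop_typed("tomowiener_value_error", "supersample must be >= 1")
  n <- nrow(image)
  nb <- n_detector_bins(n)
  values <- radon_cpp(.as_image_matrix(image), angles, nb, supersample,
                      interp == "nearest")
  ct_sinogram(values, angles, bin_spacing = attr(image, "pixel_size"),
              image_size = n)
}

#' Backprojection
#'
#' Smears each projection row back across the image along its acquisition
#' lines and sums over views, approximating the angular integral with
#' `delta_theta = pi / n_views` (so filtered backprojection needs no extra
#' global scale).  The detector lookup at the signed distance
#' `x cos(theta) + y sin(theta)`
#' uses nearest-neighbor interpolation by default; linear interpolation is
#' available for comparison.
#'
#' @param sino a `ct_sinogram` (or matrix with one row per angle, in which
#'   case `angles` must be supplied via [ct_sinogram()] first).
#' @param out_size side length of the output image; defaults to the
#'   sinogram's `image_size` attribute, or `floor(n_bins / sqrt(2))` when
#'   absent.  Pixels whose projection falls off the detector receive no
#'   contribution from that view.
#' @param interp detector interpolation, `"nearest"` (default) or `"linear"`.
#' @return a `ct_image` of side `out_size`.
#' @export
backproject <- function(sino, out_size = NULL, interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  if (!inherits(sino, "ct_sinogram")) {
    .stop_typed("tomowiener_type_error", "sino must be a ct_sinogram (see ct_sinogram())")
  }
  if (nrow(sino) < 1 || ncol(sino) < 1) {
    .stop_typed("tomowiener_value_error", "empty sinogram")
  }
  if (is.null(out_size)) {
    out_size <- attr(sino, "image_size")
    if (is.null(out_size)) out_size <- floor(ncol(sino) / sqrt(2))
  }
  out_size <- as.integer(out_size)
  if (out_size < 2) .stop_typed("tomowiener_value_error", "out_size must be >= 2")
  b <- backproject_cpp(unclass(sino), attr(sino, "angles"), out_size,
                       interp == "nearest")
  ct_image(b, pixel_size = attr(sino, "bin_spacing"))
}

#' Supersampled line-integral oracle
#'
#' Numerically integrates image values along the line
#' `x cos(theta) + y sin(theta) = r` by dense equidistant sampling with
#' nearest-pixel lookup.  Used in tests as an implementation-independent
#' reference for [radon()]; it is too slow for production use.
#'
#' @param image square `ct_image` or matrix.
#' @param theta view angle in radians.
#' @param r signed distance of the line to the isocenter, pixel units.
#' @param supersample samples per pixel of path length (default 100).
#' @return the approximate line integral (a scalar).
#' @export
line_integral_oracle <- function(image, theta, r, supersample = 100) {
  if (!inherits(image, "ct_image")) image <- ct_image(as.matrix(image))
  n <- nrow(image)
  ic <- floor(n / 2)
  step <- 1 / supersample
  t <- seq(-n, n, by = step)
  x <- r * cos(theta) - t * sin(theta)
  y <- r * sin(theta) + t * cos(theta)
  i <- round(x) + ic + 1
  j <- round(y) + ic + 1
  ok <- i >= 1 & i <= n & j >= 1 & j <= n
  if (!any(ok)) return(0)
  sum(.as_image_matrix(image)[cbind(i[ok], j[ok])]) * step
}
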