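# Synthetic phantoms, noise injection and image-quality metrics.

#' Ellipse phantom
#'
#' Builds a square test object as a sum of (possibly rotated) ellipses on a
#' normalized `[-1, 1]` coordinate grid: for every pixel, the intensities of
#' all ellipses covering it are added, negatives are clipped at zero and the
#' result is normalized to the display window `[0, 1]`.
#'
#' @param n image side length (>= 16).
#' @param ellipses data frame with one row per ellipse and columns
#'   `x`, `y` (center, normalized units), `a`, `b` (semi-axes, > 0),
#'   `phi` (rotation, radians) and `value` (additive intensity).
#' @param normalize normalize the result to `[0, 1]` (default `TRUE`).
#' @return a `ct_image`.
#' @examples
#' disk <- ellipse_phantom(64, data.frame(x = 0, y = 0, a = 0.5, b = 0.5,
#'                                        phi = 0, value = 1))
#' @export
ellipse_phantom <- function(n, ellipses, normalize = TRUE) {
  n <- as.integer(n)
  if (n < 16) .stop_typed("tomowiener_value_error", "n must be >= 16")
  if (!is.data.frame(ellipses) || nrow(ellipses) == 0) {
    .stop_typed("tomowiener_value_error", "ellipses must be a non-empty data frame")
  }
  need <- c("x", "y", "a", "b", "phi", "value")
  if (!all(need %in% names(ellipses))) {
    .stop_typed("tomowiener_value_error",
                paste("ellipses needs columns:", paste(need, collapse = ", ")))
  }
  if (any(ellipses$a <= 0 | ellipses$b <= 0)) {
    .stop_typed("tomowiener_value_error", "semi-axes must be positive")
  }
  xy <- (seq_len(n) - 1 - floor(n / 2)) / (n / 2)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  f <- matrix(0, n, n)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    xr <- (X - e$x) * cos(e$phi) + (Y - e$y) * sin(e$phi)
    yr <- -(X - e$x) * sin(e$phi) + (Y - e$y) * cos(e$phi)
    f <- f + e$value * ((xr / e$a)^2 + (yr / e$b)^2 <= 1)
  }
  if (normalize) {
    f <- pmax(f, 0)
    mx <- max(f)
    if (mx > 0) f <- f / mx
  }
  ct_image(f)
}

.preset_simple <- data.frame(
  x     = c(0,     0,    0.25, -0.25,  0,     0),
  y     = c(0,     0,    0.2,   0.15, -0.45,  0.45),
  a     = c(0.72,  0.65, 0.18,  0.14,  0.2,   0.05),
  b     = c(0.95,  0.87, 0.3,   0.25,  0.12,  0.05),
  phi   = c(0,     0,    0.3,  -0.3,   0,     0),
  value = c(1,    -0.4,  0.35,  0.25,  0.3,   0.45)
)

.preset_complex <- local({
  k <- 0:11
  ring <- data.frame(
    x = 0.55 * cos(2 * pi * k / 12), y = 0.55 * sin(2 * pi * k / 12),
    a = 0.06, b = 0.10, phi = 2 * pi * k / 12,
    value = 0.3 + 0.15 * (k %% 3)
  )
  g <- expand.grid(x = c(-0.25, 0, 0.25), y = c(-0.25, 0, 0.25))
  dots <- data.frame(x = g$x, y = g$y, a = 0.025, b = 0.025, phi = 0, value = 0.5)
  rbind(
    data.frame(x = 0, y = 0, a = 0.9, b = 0.9, phi = 0, value = 0.8),
    data.frame(x = 0, y = 0, a = 0.82, b = 0.82, phi = 0, value = -0.3),
    ring, dots
  )
})

#' Named phantom presets
#'
#' Two deterministic presets emulating a simple and a complex test object:
#' `"simple"` is a handful of large nested ellipses (smooth anatomy-like
#' features); `"complex"` adds a ring of small rotated ellipses, a grid of
#' high-contrast dots and a sinusoidal texture inside the body, giving much
#' more high-frequency content.  Both are pure geometry (plus a fixed
#' sinusoid), so a preset at a given `n` is bit-identical across runs and
#' platforms.
#'
#' @param preset `"simple"` or `"complex"`.
#' @param n image side length.
#' @return a `ct_image` with values in `[0, 1]`.
#' @export
phantom_preset <- function(preset = c("simple", "complex"), n = 512) {
  preset <- match.arg(preset)
  if (preset == "simple") return(ellipse_phantom(n, .preset_simple))
  img <- ellipse_phantom(n, .preset_complex, normalize = FALSE)
  f <- .as_image_matrix(img)
  xy <- (seq_len(n) - 1 - floor(n / 2)) / (n / 2)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  body <- X^2 + Y^2 <= 0.9^2
  f <- f + 0.08 * sin(14 * pi * X) * sin(14 * pi * Y) * body
  f <- pmax(f, 0)
  ct_image(f / max(f))
}

#' Add Gaussian noise to an image
#'
#' i.i.d. Gaussian noise, reproducible under a fixed seed.  The caller's RNG
#' state is left untouched when a seed is given.
#'
#' @param image a `ct_image` or matrix.
#' @param variance noise variance (>= 0).
#' @param mean noise mean (default 0).
#' @param seed optional integer seed.
#' @return a `ct_image`.
#' @export
add_noise <- function(image, variance = 0.01, mean = 0, seed = NULL) {
  if (!inherits(image, "ct_image")) image <- ct_image(as.matrix(image))
  if (!is.finite(variance) || variance < 0) {
    .stop_typed("tomowiener_value_error", "variance must be finite and >= 0")
  }
  if (variance == 0 && mean == 0) return(image)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- nrow(image)
  noisy <- .as_image_matrix(image) +
    matrix(stats::rnorm(n * n, mean, sqrt(variance)), n, n)
  ct_image(noisy, pixel_size = attr(image, "pixel_size"))
}

#' Signal-to-noise ratio in decibels
#'
#' `10 log10( sum(reference^2) / sum((reference - recon)^2) )`.  A perfect
#' reconstruction would be infinite and is reported as the sentinel 300 dB.
#'
#' @param recon reconstructed image (matrix or `ct_image`).
#' @param reference ground-truth image of the same size; must not be all
#'   zero.
#' @return SNR in dB.
#' @export
snr_db <- function(recon, reference) {
  recon <- as.matrix(recon)
  reference <- as.matrix(reference)
  if (!all(dim(recon) == dim(reference))) {
    .stop_typed("tomowiener_geometry_error", "image sizes differ")
  }
  sig <- sum(reference^2)
  if (sig == 0) .stop_typed("tomowiener_value_error", "reference is all zero")
  err <- sum((reference - recon)^2)
  if (err == 0) return(300)
  min(10 * log10(sig / err), 300)
}

#' Mean-density change in percent
#'
#' Reconstruction filters tend to attenuate the mean density of the image;
#' this reports `100 * (mean(reference) - mean(recon)) / mean(reference)`
#' (positive = attenuation, negative = gain).
#'
#' @param recon reconstructed image.
#' @param reference ground-truth image, nonzero mean.
#' @return percent change.
#' @export
mean_density_change <- function(recon, reference) {
  recon <- as.matrix(recon)
  reference <- as.matrix(reference)
  if (!all(dim(recon) == dim(reference))) {
    .stop_typed("tomowiener_geometry_error", "image sizes differ")
  }
  mr <- mean(reference)
  if (mr == 0) .stop_typed("tomowiener_value_error", "reference has zero mean")
  100 * (mr - mean(recon)) / mr
}
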