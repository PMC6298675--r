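# Frequency-domain operators: the 1D ramp and its apodized variants for FBP,
# the 2D ramp |R|, the trajectory weight matrix M, the weighted ramp
# W = (alpha * M + 1) |R|, and the backprojection point spread function whose
# spectrum is 1 / |R|.
#
# 2D filters are stored DC-centered (DC at 0-based index floor(N/2) on both
# axes, frequencies in DFT index units, i.e. cycles per field of view) and
# converted to DFT order at application time.

# --- fft layout helpers ------------------------------------------------------

.ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

.fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  m[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

# inverse 2D DFT with real-part extraction; asserts the imaginary residue is
# numerical noise (guards against accidentally non-Hermitian filters)
.ifft2_real <- function(z) {
  out <- stats::fft(z, inverse = TRUE) / length(z)
  re <- Re(out)
  nrm <- sqrt(sum(re^2))
  if (nrm > 0 && sqrt(sum(Im(out)^2)) > 1e-8 * nrm) {
    .stop_typed("tomowiener_numeric_error",
                "imaginary residue exceeds 1e-8 of the result norm")
  }
  re
}

.new_filter2d <- function(response) {
  structure(response, class = c("spectral_filter_2d", "matrix", "array"))
}

#' @export
print.spectral_filter_2d <- function(x, ...) {
  cat(sprintf("<spectral_filter_2d> %d x %d (DC-centered), range [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# --- 1D ramp for FBP ---------------------------------------------------------

#' Band-limited spatial-domain ramp kernel (Ram-Lak sequence)
#'
#' The discrete ramp filter is constructed in the spatial domain and then
#' transformed, rather than sampled directly in the frequency domain; direct
#' sampling of `|omega|` zeroes the DC coefficient and produces a DC-shift
#' bias in the reconstruction.  For unit bin spacing the kernel is 1/4 at lag
#' zero, `-1 / (pi k)^2` at odd lags `k`, and 0 at even nonzero lags.
#'
#' @param n_bins number of detector bins (>= 2).
#' @return numeric vector of length `2 * n_bins - 1`, lags
#'   `-(n_bins - 1) .. (n_bins - 1)`.
#' @export
ramp_kernel_1d <- function(n_bins) {
  if (n_bins < 2) .stop_typed("tomowiener_value_error", "n_bins must be >= 2")
  k <- -(n_bins - 1):(n_bins - 1)
  ifelse(k == 0, 0.25, ifelse(k %% 2 != 0, -1 / (pi * k)^2, 0))
}

#' Frequency response of the 1D ramp filter
#'
#' Embeds the Ram-Lak kernel of [ramp_kernel_1d()] circularly in a buffer of
#' `pad_to` samples (default: next power of two at least `2 * n_bins`, which
#' suppresses circular wrap-around when filtering projections) and returns
#' its DFT.  The response is real, nonnegative up to rounding, laid out
#' DC-first in standard DFT order.
#'
#' @param n_bins number of detector bins.
#' @param pad_to DFT length, at least `n_bins`.
#' @return a `spectral_filter_1d`: list with `response` (length `pad_to`)
#'   and `frequencies` (cycles per sample, DFT order).
#' @export
ramp_response_1d <- function(n_bins, pad_to = NULL) {
  if (is.null(pad_to)) pad_to <- 2^ceiling(log2(2 * n_bins))
  if (pad_to < n_bins) .stop_typed("tomowiener_value_error", "pad_to must be >= n_bins")
  h <- ramp_kernel_1d(n_bins)
  kern <- numeric(pad_to)
  kern[seq_len(n_bins)] <- h[n_bins:(2 * n_bins - 1)]          # lags 0..n_bins-1
  kern[(pad_to - n_bins + 2):pad_to] <- h[seq_len(n_bins - 1)] # lags -(n_bins-1)..-1
  response <- Re(stats::fft(kern))
  freq <- c(seq(0, floor(pad_to / 2)), seq(-(ceiling(pad_to / 2) - 1), -1)) / pad_to
  structure(list(response = response, frequencies = freq),
            class = "spectral_filter_1d")
}

#' @export
print.spectral_filter_1d <- function(x, ...) {
  cat(sprintf("<spectral_filter_1d> length %d, DC-first, response range [%.4g, %.4g]\n",
              length(x$response), min(x$response), max(x$response)))
  invisible(x)
}

#' Apodization window names
#'
#' The ramp filter passes (and magnifies) high-frequency noise; the classical
#' apodization windows roll off its high end at the cost of resolution.
#' `"ramp"` means no window.
#' @export
filter_windows <- c("ramp", "shepp-logan", "cosine", "hamming", "hann")

# window transfer function evaluated at |frequencies| (cycles/sample),
# Nyquist at 0.5
.window_gain <- function(window, freq) {
  af <- abs(freq)
  wn <- 0.5
  switch(window,
    "ramp"        = rep(1, length(af)),
    "shepp-logan" = ifelse(af == 0, 1, sin(pi * af / (2 * wn)) / (pi * af / (2 * wn))),
    "cosine"      = cos(pi * af / (2 * wn)),
    "hamming"     = 0.54 + 0.46 * cos(pi * af / wn),
    "hann"        = 0.5 * (1 + cos(pi * af / wn)),
    .stop_typed("tomowiener_value_error",
                sprintf("unknown window '%s' (use one of: %s)",
                        window, paste(filter_windows, collapse = ", ")))
  )
}

#' Apodize a 1D spectral filter
#'
#' Multiplies the filter response by a named window evaluated over its DFT
#' frequencies: Shepp-Logan `sinc(omega / 2 omega_N)`, cosine
#' `cos(pi omega / 2 omega_N)`, Hamming `0.54 + 0.46 cos(pi omega / omega_N)`,
#' Hann `0.5 (1 + cos(pi omega / omega_N))`, with `omega_N` the Nyquist
#' frequency.  `window = "ramp"` returns the input unchanged.
#'
#' @param filter a `spectral_filter_1d` from [ramp_response_1d()].
#' @param window one of [filter_windows] (case-insensitive).
#' @return an apodized `spectral_filter_1d`.
#' @export
apodize_1d <- function(filter, window = "ramp") {
  if (!inherits(filter, "spectral_filter_1d")) {
    .stop_typed("tomowiener_type_error", "filter must be a spectral_filter_1d")
  }
  window <- tolower(window)
  filter$response <- filter$response * .window_gain(window, filter$frequencies)
  filter
}

# --- 2D filters --------------------------------------------------------------

#' Two-dimensional ramp filter
#'
#' `response(u, v) = sqrt(u^2 + v^2)` over the DC-centered DFT index grid,
#' with the DC point set to 0 exactly.  Frequencies are in DFT index units
#' (cycles per field of view); the reconstruction routines absorb the global
#' scale.
#'
#' @param n grid side (>= 2).
#' @return a `spectral_filter_2d` (DC-centered `n` x `n` matrix).
#' @export
ramp_filter_2d <- function(n) {
  n <- as.integer(n)
  if (n < 2) .stop_typed("tomowiener_value_error", "n must be >= 2")
  u <- seq_len(n) - 1 - floor(n / 2)
  .new_filter2d(sqrt(outer(u^2, u^2, `+`)))
}

#' Trajectory weight matrix
#'
#' By the projection slice theorem each acquired view samples the 2D spectrum
#' along the radial line at its angle; frequency points off every such
#' trajectory are only ever filled by interpolation.  This routine rasterizes
#' each trajectory on the DC-centered frequency grid — the nearest grid point
#' at each integer radius, in both directions from DC — and counts how often
#' every grid point is sampled.  DC is touched once per view, so its count
#' equals the number of projections; a point on exactly one trajectory gets
#' count 1; untouched (interpolated) points get 0.
#'
#' @param n frequency grid side (>= 2).
#' @param angles view angles (radians).
#' @return a `weight_matrix`: list with integer matrix `counts` and
#'   `normalized = counts / n_views` (so DC maps to 1).
#' @export
trajectory_weights <- function(n, angles) {
  n <- as.integer(n)
  if (n < 2) .stop_typed("tomowiener_value_error", "n must be >= 2")
  angles <- .validate_angles(angles)
  counts <- trajectory_counts_cpp(n, angles)
  structure(list(counts = counts, normalized = counts / length(angles)),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d x %d, DC count %d, max normalized %g\n",
              nrow(x$counts), ncol(x$counts),
              x$counts[floor(nrow(x$counts) / 2) + 1, floor(ncol(x$counts) / 2) + 1],
              max(x$normalized)))
  invisible(x)
}

#' Trajectory-weighted 2D ramp filter
#'
#' `W = (alpha * M + 1) . |R|` elementwise, with `M` the normalized
#' trajectory weight matrix of [trajectory_weights()] and `|R|` the plain 2D
#' ramp.  `alpha` controls how strongly really-sampled frequency points are
#' boosted over interpolated ones (base weight 1); `alpha = 0` recovers the
#' common ramp filter exactly.  `W` is 0 at DC for any `alpha`.
#'
#' @param n grid side.
#' @param angles view angles (radians).
#' @param alpha nonnegative weighting strength.
#' @return a `spectral_filter_2d`.
#' @export
weighted_ramp_2d <- function(n, angles, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha < 0) {
    .stop_typed("tomowiener_value_error", "alpha must be a finite nonnegative scalar")
  }
  R <- ramp_filter_2d(n)
  if (alpha == 0) return(R)
  M <- trajectory_weights(n, angles)$normalized
  .new_filter2d((alpha * M + 1) * unclass(R))
}

#' Point spread function of plain backprojection
#'
#' Backprojecting without any filter convolves the object with a kernel
#' whose frequency response is `1 / |R|`.  This routine inverts a
#' nonnegative 2D filter elementwise — replacing any zero response (the DC
#' point) by machine epsilon so the inverse stays finite — and returns the
#' spatial-domain kernel, DC-centered (origin at 0-based index
#' `floor(n/2)`).
#'
#' @param filter2d a nonnegative `spectral_filter_2d` (typically
#'   [ramp_filter_2d()] or [weighted_ramp_2d()]).
#' @return a `ct_psf`: real `n` x `n` kernel matrix with even symmetry.
#' @export
psf_from_filter <- function(filter2d) {
  if (!inherits(filter2d, "spectral_filter_2d")) {
    .stop_typed("tomowiener_type_error", "filter2d must be a spectral_filter_2d")
  }
  resp <- unclass(filter2d)
  if (any(resp < 0)) {
    .stop_typed("tomowiener_value_error", "filter response must be nonnegative")
  }
  resp[resp == 0] <- .Machine$double.eps
  inv <- 1 / resp
  kernel <- .ifft2_real(.ifftshift2(inv))
  structure(.fftshift2(kernel), class = c("ct_psf", "matrix", "array"))
}

#' @export
print.ct_psf <- function(x, ...) {
  cat(sprintf("<ct_psf> %d x %d, center value %.4g\n",
              nrow(x), ncol(x), x[floor(nrow(x) / 2) + 1, floor(ncol(x) / 2) + 1]))
  invisible(x)
}

#' Frequency response of a spatial PSF kernel
#'
#' @param psf a `ct_psf` (DC-centered kernel).
#' @return a `spectral_filter_2d` holding the real part of its DFT
#'   (DC-centered).
#' @export
psf_response <- function(psf) {
  z <- stats::fft(.ifftshift2(unclass(psf)))
  .new_filter2d(.fftshift2(Re(z)))
}
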