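# The three reconstructors.  All share the backprojection of the sinogram;
# they differ in where and how the ramp filter enters:
#   FBP  — filter each projection row with the (apodized) 1D ramp, then
#          backproject;
#   BPF  — backproject, then multiply the 2D spectrum by the ramp |R|
#          (optionally trajectory-weighted);
#   BPWD — backproject, then Wiener-deconvolve with the point spread
#          function whose spectrum is 1/|R| (or 1/W), which reconstructs
#          and denoises in one linear step.
#
# 2D filtering grid: by default ("extended") the backprojection is formed on
# the full detector-extent grid (side = number of bins) and the filtered
# image is cropped back to N x N.  The backprojection blur reaches well
# beyond the reconstructed field of view; filtering on the bare N x N grid
# ("image") wraps those tails circularly and annihilates the image mean,
# which visibly degrades BPF/BPWD.  The "image" grid is kept as an option
# because it is the cheapest and matches the direct product form.

#' Reconstruction parameter set
#'
#' Bundles the knobs shared by [reconstruct()] and the CLI.  Defaults follow
#' the simulation protocol: `alpha = 1` and `sigma = 7` are the universal
#' choices for the weighted filter and the Wiener noise level (`sigma` is
#' only meaningful for `method = "bpwd"`; `alpha > 0` engages the
#' trajectory-weighted ramp for bpf/bpwd).
#'
#' @param method `"fbp"`, `"bpf"` or `"bpwd"`.
#' @param window apodization window for FBP, one of [filter_windows].
#' @param alpha trajectory weighting strength (0 disables).
#' @param sigma Wiener noise-to-signal ratio (0 = noise-free; BPWD only).
#' @param mask if `TRUE`, zero all pixels outside the inscribed circle.
#' @param interp backprojection interpolation, `"nearest"` or `"linear"`.
#' @param grid 2D filtering grid for bpf/bpwd, `"extended"` or `"image"`.
#' @return a `recon_params` list.
#' @export
recon_params <- function(method = c("bpwd", "fbp", "bpf"),
                         window = "ramp",
                         alpha = 1,
                         sigma = 7,
                         mask = FALSE,
                         interp = c("nearest", "linear"),
                         grid = c("extended", "image")) {
  method <- match.arg(method)
  window <- tolower(window)
  if (!window %in% filter_windows) {
    .stop_typed("tomowiener_value_error",
                sprintf("unknown window '%s'", window))
  }
  if (alpha < 0) .stop_typed("tomowiener_value_error", "alpha must be >= 0")
  if (sigma < 0) .stop_typed("tomowiener_value_error", "sigma must be >= 0")
  structure(list(method = method, window = window, alpha = alpha,
                 sigma = sigma, mask = isTRUE(mask),
                 interp = match.arg(interp), grid = match.arg(grid)),
            class = "recon_params")
}

.out_size_of <- function(sino, out_size) {
  if (!is.null(out_size)) return(as.integer(out_size))
  n <- attr(sino, "image_size")
  if (is.null(n)) n <- floor(ncol(sino) / sqrt(2))
  as.integer(n)
}

.check_sino <- function(sino) {
  if (!inherits(sino, "ct_sinogram")) {
    .stop_typed("tomowiener_type_error", "sino must be a ct_sinogram")
  }
  if (nrow(sino) < 1 || ncol(sino) < 1) {
    .stop_typed("tomowiener_value_error", "empty sinogram")
  }
  invisible(sino)
}

.crop_center <- function(m, n) {
  i0 <- floor(nrow(m) / 2) - floor(n / 2)
  m[i0 + seq_len(n), i0 + seq_len(n)]
}

#' Filtered backprojection (FBP)
#'
#' Each projection row is filtered with the band-limited ramp (built in the
#' spatial domain, see [ramp_kernel_1d()]) apodized by `window`, using
#' zero-padded FFT convolution; the filtered sinogram is then backprojected.
#'
#' @param sino a `ct_sinogram`.
#' @param window apodization window, one of [filter_windows].
#' @param out_size output side length (default: geometry-implied).
#' @param interp backprojection interpolation.
#' @return a `ct_image`.
#' @export
fbp <- function(sino, window = "ramp", out_size = NULL,
                interp = c("nearest", "linear")) {
  .check_sino(sino)
  interp <- match.arg(interp)
  n <- .out_size_of(sino, out_size)
  nb <- ncol(sino)
  filt <- apodize_1d(ramp_response_1d(nb), window)
  L <- length(filt$response)
  pad <- matrix(0, nrow(sino), L)
  pad[, seq_len(nb)] <- unclass(sino)
  ft <- stats::mvfft(t(pad))                       # columns = padded rows
  q <- Re(stats::mvfft(ft * filt$response, inverse = TRUE)) / L
  filtered <- ct_sinogram(t(q[seq_len(nb), , drop = FALSE]),
                          attr(sino, "angles"),
                          bin_spacing = attr(sino, "bin_spacing"),
                          image_size = n)
  backproject(filtered, n, interp)
}

# shared 2D-filter application for bpf/bpwd: backproject on the chosen grid,
# multiply the spectrum by `response_of(m)` (DC-centered), crop to n x n.
.recon_2d <- function(sino, n, interp, grid, response_of) {
  m <- if (grid == "extended") ncol(sino) else n
  b <- backproject(sino, m, interp)
  G <- .ifftshift2(response_of(m))
  out <- .ifft2_real(stats::fft(.as_image_matrix(b)) * G)
  ct_image(.crop_center(out, n), pixel_size = attr(sino, "bin_spacing"))
}

#' Backprojection then filtering (BPF)
#'
#' Backprojects the sinogram and multiplies its 2D spectrum by the ramp
#' filter `|R|` (trajectory-weighted when `alpha > 0`), i.e. the direct
#' inversion `F(u, v) = B(u, v) . |R|`.  The DC component of `|R|` is zero,
#' so the output mean is annihilated on the filtering grid (one reason the
#' `"extended"` grid, which crops afterwards, is the default).
#'
#' @param sino a `ct_sinogram`.
#' @param alpha trajectory weighting strength (0 = plain ramp).
#' @param out_size output side length.
#' @param interp backprojection interpolation.
#' @param grid filtering grid, `"extended"` (detector extent, then crop) or
#'   `"image"` (bare N x N).
#' @return a `ct_image`.
#' @export
bpf <- function(sino, alpha = 0, out_size = NULL,
                interp = c("nearest", "linear"),
                grid = c("extended", "image")) {
  .check_sino(sino)
  interp <- match.arg(interp)
  grid <- match.arg(grid)
  n <- .out_size_of(sino, out_size)
  angles <- attr(sino, "angles")
  .recon_2d(sino, n, interp, grid, function(m) {
    unclass(weighted_ramp_2d(m, angles, alpha)) / m
  })
}

#' Wiener filter from a real frequency response
#'
#' `G = (1/H) * (H* H) / (H* H + Z)` evaluated elementwise; for real `H`
#' this is `H / (H^2 + Z)`.  `Z` is the scalar noise-to-signal power ratio:
#' `Z = 0` gives the plain inverse filter, larger `Z` attenuates frequencies
#' where `H` is small.
#'
#' @param H a `spectral_filter_2d` or numeric matrix (real response).
#' @param Z nonnegative scalar noise-to-signal ratio.
#' @return a `spectral_filter_2d` with the same layout as `H`.
#' @export
wiener_filter <- function(H, Z) {
  if (!is.numeric(Z) || length(Z) != 1 || !is.finite(Z) || Z < 0) {
    .stop_typed("tomowiener_value_error", "Z must be a finite nonnegative scalar")
  }
  h <- if (inherits(H, "spectral_filter_2d")) unclass(H) else as.matrix(H)
  .new_filter2d(h / (h^2 + Z))
}

#' Wiener deconvolution of an image
#'
#' The deconvolution stage of BPWD, usable on its own: given an observed
#' image `g ~ f (x) h + noise` (circular convolution) and the PSF's real
#' frequency response `H`, returns the real part of
#' `IDFT( DFT(g) . G )` with `G = wiener_filter(H, Z)`.
#'
#' @param image observed `ct_image` or matrix.
#' @param H `spectral_filter_2d` (DC-centered) or `ct_psf` (converted via
#'   [psf_response()]); must match the image size.
#' @param Z nonnegative noise-to-signal ratio.
#' @return deconvolved `ct_image`.
#' @export
wiener_deconvolve <- function(image, H, Z = 0) {
  if (!inherits(image, "ct_image")) image <- ct_image(as.matrix(image))
  if (inherits(H, "ct_psf")) H <- psf_response(H)
  if (!inherits(H, "spectral_filter_2d")) {
    .stop_typed("tomowiener_type_error", "H must be a spectral_filter_2d or ct_psf")
  }
  if (nrow(H) != nrow(image)) {
    .stop_typed("tomowiener_geometry_error", "filter and image sizes differ")
  }
  G <- .ifftshift2(unclass(wiener_filter(H, Z)))
  out <- .ifft2_real(stats::fft(.as_image_matrix(image)) * G)
  ct_image(out, pixel_size = attr(image, "pixel_size"))
}

#' Backprojection Wiener deconvolution (BPWD)
#'
#' Backprojects the sinogram, then deconvolves the blurred result with the
#' point spread function of plain backprojection: `H = 1 / |R|` (or `1 / W`
#' when `alpha > 0`), with the zero DC of the ramp replaced by machine
#' epsilon so the inverse stays finite.  The Wiener filter
#' `G = H / (H^2 + sigma)` attenuates frequencies where the noise dominates,
#' so reconstruction and denoising happen in one pass; with `sigma = 0` BPWD
#' is equivalent to BPF.
#'
#' @param sino a `ct_sinogram`.
#' @param sigma nonnegative noise-to-signal ratio (0 = noise-free limit).
#' @param alpha trajectory weighting strength (0 = plain ramp).
#' @param out_size output side length.
#' @param interp backprojection interpolation.
#' @param grid filtering grid, as in [bpf()].
#' @return a `ct_image`.
#' @export
bpwd <- function(sino, sigma = 7, alpha = 0, out_size = NULL,
                 interp = c("nearest", "linear"),
                 grid = c("extended", "image")) {
  .check_sino(sino)
  if (sigma < 0) .stop_typed("tomowiener_value_error", "sigma must be >= 0")
  interp <- match.arg(interp)
  grid <- match.arg(grid)
  n <- .out_size_of(sino, out_size)
  angles <- attr(sino, "angles")
  .recon_2d(sino, n, interp, grid, function(m) {
    resp <- unclass(weighted_ramp_2d(m, angles, alpha)) / m
    resp[resp == 0] <- .Machine$double.eps
    H <- 1 / resp
    unclass(wiener_filter(H, sigma))
  })
}

#' Mask of the inscribed circle
#'
#' @param n image side length.
#' @return logical `n` x `n` matrix, `TRUE` inside the circle of radius
#'   `n / 2` centered at the isocenter.
#' @export
inscribed_circle_mask <- function(n) {
  xy <- seq_len(n) - 1 - floor(n / 2)
  outer(xy^2, xy^2, `+`) <= (n / 2)^2
}

#' Reconstruct a sinogram with a parameter set
#'
#' Routes to [fbp()], [bpf()] or [bpwd()] according to `params$method` and
#' optionally applies the inscribed-circle mask.
#'
#' @param sino a `ct_sinogram`.
#' @param params a [recon_params()] list.
#' @param out_size output side length.
#' @return a `ct_image`.
#' @export
reconstruct <- function(sino, params = recon_params(), out_size = NULL) {
  if (!inherits(params, "recon_params")) {
    .stop_typed("tomowiener_type_error", "params must come from recon_params()")
  }
  out <- switch(params$method,
    fbp  = fbp(sino, params$window, out_size, params$interp),
    bpf  = bpf(sino, params$alpha, out_size, params$interp, params$grid),
    bpwd = bpwd(sino, params$sigma, params$alpha, out_size, params$interp,
                params$grid),
    .stop_typed("tomowiener_value_error",
                sprintf("unknown method '%s'", params$method))
  )
  if (params$mask) {
    m <- .as_image_matrix(out)
    m[!inscribed_circle_mask(nrow(m))] <- 0
    out <- ct_image(m, pixel_size = attr(out, "pixel_size"))
  }
  out
}
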