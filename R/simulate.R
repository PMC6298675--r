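# Simulation protocol: phantom -> (optional Gaussian noise) -> projection.
#
# Noise is added to the ground-truth image before projection by default
# (approximating a noisy object / detector chain as seen through the
# projector); `noise_on = "sinogram"` adds it to the projections instead.

#' Simulate a CT acquisition
#'
#' Generates a phantom (or takes a supplied image), optionally adds
#' zero-mean Gaussian noise, and projects it over uniformly spaced angles in
#' `[0, pi)`.
#'
#' @param preset phantom preset name (see [phantom_preset()]), ignored when
#'   `image` is given.
#' @param n image side length.
#' @param views number of projection angles.
#' @param noise_var Gaussian noise variance (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param noise_on `"image"` (default) or `"sinogram"`.
#' @param image optional ground-truth `ct_image` overriding the preset.
#' @param interp forward projector bin assignment (see [radon()]).
#' @param supersample forward projector subpixel factor.
#' @return list with elements `truth` (clean phantom), `noisy` (noisy
#'   phantom, equals `truth` for sinogram noise or `noise_var = 0`),
#'   `sinogram`, `angles`, and the call parameters; class `ct_simulation`.
#' @export
simulate_ct <- function(preset = "simple", n = 512, views = 180,
                        noise_var = 0.01, seed = 42,
                        noise_on = c("image", "sinogram"),
                        image = NULL,
                        interp = c("nearest", "linear"), supersample = 1L) {
  noise_on <- match.arg(noise_on)
  interp <- match.arg(interp)
  truth <- if (is.null(image)) phantom_preset(preset, n) else ct_image(as.matrix(image))
  n <- nrow(truth)
  angles <- uniform_angles(views)
  noisy <- truth
  if (noise_var > 0 && noise_on == "image") {
    noisy <- add_noise(truth, noise_var, seed = seed)
  }
  sino <- radon(noisy, angles, interp = interp, supersample = supersample)
  if (noise_var > 0 && noise_on == "sinogram") {
    noisy_s <- add_noise(unclass(sino), noise_var, seed = seed)
    sino <- ct_sinogram(as.matrix(noisy_s), angles,
                        bin_spacing = attr(sino, "bin_spacing"), image_size = n)
  }
  structure(list(truth = truth, noisy = noisy, sinogram = sino,
                 angles = angles, preset = if (is.null(image)) preset else NA,
                 n = n, views = views, noise_var = noise_var, seed = seed,
                 noise_on = noise_on, interp = interp,
                 supersample = as.integer(supersample)),
            class = "ct_simulation")
}

#' @export
print.ct_simulation <- function(x, ...) {
  cat(sprintf("<ct_simulation> %s %d^2, %d views, noise var %g on %s, seed %s\n",
              x$preset, x$n, x$views, x$noise_var, x$noise_on, x$seed))
  invisible(x)
}

.method_recon <- function(sino, method, window, alpha, sigma, interp, grid) {
  switch(method,
    "fbp"    = fbp(sino, window, interp = interp),
    "bpf"    = bpf(sino, 0, interp = interp, grid = grid),
    "bpf-w"  = bpf(sino, alpha, interp = interp, grid = grid),
    "bpwd"   = bpwd(sino, sigma, 0, interp = interp, grid = grid),
    "bpwd-w" = bpwd(sino, sigma, alpha, interp = interp, grid = grid),
    .stop_typed("tomowiener_value_error", sprintf("unknown method '%s'", method))
  )
}

#' Compare reconstruction methods across view counts
#'
#' For every combination of view count and method, simulates an acquisition
#' of the chosen phantom (fixed seed, so every method sees the same noisy
#' projections), reconstructs, and records SNR against the clean phantom,
#' mean-density change and wall time.
#'
#' @param views integer vector of projection counts.
#' @param methods subset of `c("fbp", "bpf", "bpf-w", "bpwd", "bpwd-w")`
#'   (`"-w"` = trajectory-weighted ramp).
#' @param preset,n,noise_var,seed,noise_on,image,interp,supersample
#'   simulation settings, see [simulate_ct()]; `interp` is used for both
#'   projection and backprojection.
#' @param window FBP apodization window.
#' @param alpha,sigma weighted-filter strength and Wiener noise level for
#'   the `-w`/`bpwd` methods.
#' @param grid 2D filtering grid for bpf/bpwd.
#' @return a tibble with columns `views`, `method`, `snr_db`,
#'   `density_change_pct`, `seconds`; class `ct_compare`.
#' @export
run_compare <- function(views = c(60, 180),
                        methods = c("fbp", "bpf", "bpwd", "bpwd-w"),
                        preset = "simple", n = 256, noise_var = 0.01,
                        seed = 42, noise_on = "image", image = NULL,
                        window = "shepp-logan", alpha = 1, sigma = 7,
                        interp = "nearest", supersample = 1L,
                        grid = "extended") {
  if (length(views) < 1) .stop_typed("tomowiener_value_error", "need at least one view count")
  rows <- list()
  for (v in views) {
    sim <- simulate_ct(preset, n, v, noise_var, seed, noise_on, image,
                       interp, supersample)
    for (m in methods) {
      t0 <- proc.time()[["elapsed"]]
      rec <- .method_recon(sim$sinogram, m, window, alpha, sigma, interp, grid)
      dt <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1]] <- tibble::tibble(
        views = as.integer(v), method = m,
        snr_db = snr_db(rec, sim$truth),
        density_change_pct = mean_density_change(rec, sim$truth),
        seconds = dt
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ct_compare", class(out))
  attr(out, "params") <- list(preset = preset, n = n, noise_var = noise_var,
                              seed = seed, window = window, alpha = alpha,
                              sigma = sigma, interp = interp,
                              supersample = supersample, grid = grid)
  out
}
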