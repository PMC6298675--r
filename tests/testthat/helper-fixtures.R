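# Shared fixtures, all built in code.

# smooth radial blob: projector accuracy tests need a phantom whose
# projections have bounded derivatives (a binary disk does not)
gaussian_blob <- function(n, sigma_px = n / 5) {
  xy <- seq_len(n) - 1 - floor(n / 2)
  X <- matrix(xy, n, n)
  Y <- matrix(xy, n, n, byrow = TRUE)
  ct_image(exp(-(X^2 + Y^2) / (2 * sigma_px^2)))
}

unit_disk <- function(n, radius_frac = 0.4) {
  ellipse_phantom(n, data.frame(x = 0, y = 0, a = radius_frac, b = radius_frac,
                                phi = 0, value = 1))
}

# single bright pixel at a 0-based offset from the isocenter
point_image <- function(n, dx = 0, dy = 0) {
  m <- matrix(0, n, n)
  ic <- floor(n / 2)
  m[ic + 1 + dx, ic + 1 + dy] <- 1
  ct_image(m)
}

total_variation <- function(m) {
  m <- as.matrix(m)
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

centered_index <- function(n) floor(n / 2) + 1
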