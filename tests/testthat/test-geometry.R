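# Forward projection and backprojection.

test_that("radon of the zero image is zero and rejects bad geometry", {
  z <- ct_image(matrix(0, 8, 8))
  s <- radon(z, uniform_angles(5))
  expect_equal(dim(s)[1], 5)
  expect_equal(ncol(s), n_detector_bins(8))
  expect_true(all(s == 0))

  expect_error(ct_image(matrix(0, 4, 6)), class = "tomowiener_geometry_error")
  expect_error(radon(matrix(0, 4, 6), uniform_angles(3)),
               class = "tomowiener_geometry_error")
  expect_error(radon(ct_image(matrix(0, 8, 8)), c(0.5, 0.2)),
               class = "tomowiener_value_error")
})

test_that("single-pixel projections land in the geometrically predicted bin", {
  n <- 8
  for (off in list(c(0, 0), c(2, 1), c(-3, 2))) {
    img <- point_image(n, off[1], off[2])
    angles <- c(0, pi / 4, pi / 2)
    s <- radon(img, angles)
    c0 <- centered_index(ncol(s))
    for (i in seq_along(angles)) {
      expect_equal(sum(s[i, ]), 1)                      # mass of one pixel
      r_true <- off[1] * cos(angles[i]) + off[2] * sin(angles[i])
      expect_equal(which.max(s[i, ]), c0 + round(r_true))
    }
  }
})

test_that("projection of a uniform disk approximates the chord length at every angle", {
  n <- 64
  rho <- 0.4 * (n / 2)
  img <- unit_disk(n, 0.4)
  angles <- uniform_angles(6)
  s <- radon(img, angles, interp = "linear", supersample = 4)
  r <- bin_centers(s)
  chord <- ifelse(abs(r) < rho, 2 * sqrt(pmax(rho^2 - r^2, 0)), 0)
  for (i in seq_along(angles)) {
    # compare away from the rim, where the chord derivative blows up
    sel <- abs(r) < 0.8 * rho
    expect_lt(max(abs(s[i, sel] - chord[sel])) / max(chord), 0.04)
  }
  # rows are near-identical across angles for a rotationally symmetric object
  expect_lt(max(abs(sweep(unclass(s), 2, colMeans(unclass(s))))) / max(s), 0.03)
})

test_that("per-view mass is conserved exactly by the pixel-driven projector", {
  set.seed(11)
  img <- ct_image(matrix(runif(32 * 32), 32, 32))
  for (ss in c(1L, 2L, 4L)) {
    for (interp in c("nearest", "linear")) {
      s <- radon(img, uniform_angles(13), interp = interp, supersample = ss)
      expect_equal(rowSums(unclass(s)), rep(sum(img), 13), tolerance = 1e-12)
    }
  }
})

test_that("radon and backprojection are linear operators", {
  set.seed(4)
  a <- ct_image(matrix(runif(16 * 16), 16, 16))
  b <- ct_image(matrix(runif(16 * 16), 16, 16))
  ang <- uniform_angles(7)
  sa <- radon(a, ang); sb <- radon(b, ang)
  s_mix <- radon(ct_image(2 * unclass(a) - 3 * unclass(b)), ang)
  expect_equal(unclass(s_mix)[, ], 2 * unclass(sa)[, ] - 3 * unclass(sb)[, ],
               tolerance = 1e-10)

  mix <- ct_sinogram(2 * unclass(sa) - 3 * unclass(sb), ang, image_size = 16)
  bp_mix <- backproject(mix)
  expect_equal(unclass(bp_mix)[, ],
               2 * unclass(backproject(sa))[, ] - 3 * unclass(backproject(sb))[, ],
               tolerance = 1e-10)
})

test_that("radon rows agree with the supersampled line-integral oracle", {
  n <- 32
  img <- gaussian_blob(n)
  angles <- c(0, 17, 45, 73, 90) * pi / 180
  angles <- sort(unique(pmin(angles, pi - 1e-9)))
  s <- radon(img, angles, interp = "linear", supersample = 4)
  r <- bin_centers(s)
  for (i in seq_along(angles)) {
    oracle <- vapply(r, function(ri) line_integral_oracle(img, angles[i], ri, 100),
                     numeric(1))
    expect_lt(max(abs(s[i, ] - oracle)) / max(oracle), 0.02)
  }
  # oracle trivial cases
  expect_equal(line_integral_oracle(ct_image(matrix(0, 8, 8)), 0.3, 1), 0)
  expect_equal(line_integral_oracle(point_image(9), 0, 0, 200), 1, tolerance = 0.01)
  expect_equal(line_integral_oracle(point_image(9), 0, 30), 0)
})

test_that("backprojection of a zero or single-bin sinogram matches geometry", {
  ang <- uniform_angles(4)
  nb <- n_detector_bins(6)
  z <- ct_sinogram(matrix(0, 4, nb), ang, image_size = 6)
  expect_true(all(backproject(z) == 0))

  # one view at theta = 0 with a single nonzero bin at r = 0 spreads along
  # the central column x = 0 only
  s1 <- matrix(0, 1, nb); s1[1, centered_index(nb)] <- 1
  b <- backproject(ct_sinogram(s1, 0, image_size = 7), 7)
  ic <- centered_index(7)
  expect_true(all(b[ic, ] == b[ic, 1]))     # constant along the line
  expect_true(all(b[-ic, ] == 0))
  expect_gt(b[ic, 1], 0)

  expect_error(backproject(ct_sinogram(matrix(0, 1, 5), 0), 1),
               class = "tomowiener_value_error")
})

test_that("nearest-neighbor radon and backprojection are exact adjoints", {
  # <radon(f), p> == <f, backproject(p)> / dtheta for the shared index map
  set.seed(21)
  n <- 6
  f <- ct_image(matrix(runif(n * n), n, n))
  ang <- uniform_angles(4)
  sf <- radon(f, ang, interp = "nearest", supersample = 1)
  p <- matrix(runif(length(sf)), nrow(sf), ncol(sf))
  bp <- backproject(ct_sinogram(p, ang, image_size = n), n, interp = "nearest")
  dtheta <- pi / length(ang)
  expect_equal(sum(unclass(sf) * p), sum(unclass(f) * unclass(bp)) / dtheta,
               tolerance = 1e-10)
})

test_that("projections are consistent under phantom rotation", {
  # radon of a rotated smooth phantom ~ radon of the original at shifted
  # angles; a smooth blob keeps the pixelation error small
  n <- 64
  phi <- pi / 6
  blob_at <- function(cx, cy) {
    xy <- seq_len(n) - 1 - floor(n / 2)
    X <- matrix(xy, n, n); Y <- matrix(xy, n, n, byrow = TRUE)
    ct_image(exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 6^2)))
  }
  r0 <- 0.25 * n / 2
  img <- blob_at(r0, 0)
  rot <- blob_at(r0 * cos(phi), r0 * sin(phi))
  base <- radon(img, pi / 4, interp = "linear", supersample = 4)
  shifted <- radon(rot, pi / 4 + phi, interp = "linear", supersample = 4)
  expect_lt(max(abs(unclass(base) - unclass(shifted))) / max(base), 0.02)
})

test_that("a point object backprojects to a center-dense radial blur", {
  n <- 33
  s <- radon(point_image(n), uniform_angles(60))
  b <- backproject(s)
  ic <- centered_index(n)
  expect_equal(which(unclass(b) == max(b)), (ic - 1) * n + ic)  # max at center
  # density falls off with radius
  ring <- function(rad) {
    xy <- seq_len(n) - ic
    d <- sqrt(outer(xy^2, xy^2, `+`))
    mean(unclass(b)[d >= rad - 0.5 & d < rad + 0.5])
  }
  expect_gt(ring(2), ring(6))
  expect_gt(ring(6), ring(12))
})
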