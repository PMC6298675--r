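# Spectral operators: 1D/2D ramp, apodization, trajectory weights, PSF.

test_that("Ram-Lak kernel has the textbook values and even symmetry", {
  h <- ramp_kernel_1d(64)
  expect_length(h, 2 * 64 - 1)
  i0 <- 64
  expect_equal(h[i0], 0.25)
  expect_equal(h[i0 + 1], -1 / pi^2)
  expect_equal(h[i0 + 2], 0)
  expect_equal(h[i0 + 3], -1 / (3 * pi)^2)
  expect_equal(h, rev(h))                                  # even symmetry
  # the infinite kernel sums to zero; the finite tail bound
  expect_lt(abs(sum(h)), 1 / (pi^2 * 63))
  expect_error(ramp_kernel_1d(1), class = "tomowiener_value_error")
})

test_that("ramp frequency response approximates |omega| away from DC", {
  for (nb in c(64, 256, 1024)) {
    filt <- ramp_response_1d(nb)
    f <- filt$frequencies
    mid <- abs(f) > 0.05 & abs(f) < 0.45
    relerr <- abs(filt$response[mid] - abs(f[mid])) / abs(f[mid])
    if (nb == 256) expect_lt(max(relerr), 0.01)
    # pointwise convergence: max mid-band error shrinks with kernel length
    assign(paste0("err", nb), max(relerr), envir = environment())
  }
  expect_lt(err1024, err256)
  expect_lt(err256, err64)
  # DC response is far below Nyquist response (no DC shift, but small)
  filt <- ramp_response_1d(256)
  expect_lt(filt$response[1], 0.01 * max(filt$response))
})

test_that("apodization windows scale the ramp as designed", {
  filt <- ramp_response_1d(64)
  expect_identical(apodize_1d(filt, "ramp")$response, filt$response)

  ny <- which.min(abs(abs(filt$frequencies) - 0.5))       # Nyquist bin
  hann <- apodize_1d(filt, "hann")
  expect_equal(hann$response[ny], 0, tolerance = 1e-12)
  hamming <- apodize_1d(filt, "hamming")
  expect_equal(hamming$response[ny], 0.08 * filt$response[ny])
  cosine <- apodize_1d(filt, "cosine")
  expect_equal(cosine$response[ny], 0, tolerance = 1e-12)
  # windows only attenuate
  for (w in setdiff(filter_windows, "ramp")) {
    expect_true(all(apodize_1d(filt, w)$response <= filt$response + 1e-12))
  }
  expect_error(apodize_1d(filt, "boxcar"), class = "tomowiener_value_error")
})

test_that("2D ramp filter is the radial index distance with zero DC", {
  for (n in c(7, 64)) {
    R <- ramp_filter_2d(n)
    c0 <- centered_index(n)
    expect_equal(R[c0, c0], 0)
    if (n > 8) expect_equal(R[c0 + 3, c0 + 4], 5)
    expect_equal(R[c0 + 1, c0 - 2], R[c0 - 1, c0 + 2])     # even symmetry
    u <- seq_len(n) - c0
    expect_equal(unclass(R)[, ], sqrt(outer(u^2, u^2, `+`)))
  }
})

test_that("trajectory weights count radial samples per frequency point", {
  n <- 64
  angles <- uniform_angles(36)
  w <- trajectory_weights(n, angles)
  c0 <- centered_index(n)
  expect_equal(w$counts[c0, c0], 36L)                      # DC hit once per view
  expect_equal(w$normalized[c0, c0], 1)
  expect_equal(max(w$normalized), 1)
  # the theta = 0 trajectory runs along the u axis: its farthest point is
  # sampled by that view alone at this angular spacing
  expect_equal(w$counts[c0 + 31, c0], 1L)
  # interpolated points (touched by no trajectory) carry weight 0
  expect_true(any(w$counts == 0L))
  expect_true(all(w$counts >= 0L))
})

test_that("weighted ramp reduces to the common ramp at alpha 0 and scales with M", {
  angles <- uniform_angles(12)
  for (n in c(64, 257)) {
    expect_identical(unclass(weighted_ramp_2d(n, angles, 0))[, ],
                     unclass(ramp_filter_2d(n))[, ])
  }
  n <- 64
  W <- weighted_ramp_2d(n, angles, 1)
  R <- ramp_filter_2d(n)
  M <- trajectory_weights(n, angles)$normalized
  c0 <- centered_index(n)
  expect_equal(W[c0, c0], 0)                               # DC stays zero
  one <- which(M == 1 & unclass(R) > 0)[1]                 # fully sampled point
  expect_equal(unclass(W)[one], 2 * unclass(R)[one])
  expect_equal(unclass(W)[, ], (1 + M) * unclass(R)[, ])
  expect_error(weighted_ramp_2d(n, angles, -0.5), class = "tomowiener_value_error")
})

test_that("PSF inverts the ramp spectrum with the epsilon DC rule", {
  n <- 64
  c0 <- centered_index(n)
  P <- psf_from_filter(ramp_filter_2d(n))
  H <- psf_response(P)
  expect_equal(H[c0, c0], 1 / .Machine$double.eps, tolerance = 1e-6)
  # the huge DC (1/eps ~ 4.5e15) dominates double precision: the spectrum
  # round-trips only relative to that magnitude
  inv <- 1 / pmax(unclass(ramp_filter_2d(n)), .Machine$double.eps)
  expect_lt(max(abs(unclass(H) - inv)) / max(inv), 1e-10)
  # kernel has even (circular) symmetry about the origin: in DFT order,
  # h[a, b] == h[-a mod n, -b mod n]
  k0 <- tomowiener:::.ifftshift2(unclass(P))
  idx <- c(1, n:2)
  expect_equal(k0, k0[idx, idx], tolerance = 1e-10)
  expect_error(psf_from_filter(structure(matrix(-1, 4, 4),
                                         class = c("spectral_filter_2d", "matrix", "array"))),
               class = "tomowiener_value_error")
})

test_that("PSF spectrum round-trips exactly for a strictly positive filter", {
  # with no degenerate DC the kernel <-> spectrum round trip is tight
  n <- 32
  R <- ramp_filter_2d(n)
  pos <- structure(unclass(R) + 1, class = class(R))
  P <- psf_from_filter(pos)
  H <- psf_response(P)
  expect_equal(unclass(H)[, ], 1 / (unclass(R)[, ] + 1), tolerance = 1e-12)
  # multiplying the filter by its inverse spectrum gives 1 everywhere
  expect_equal(unclass(H)[, ] * (unclass(R)[, ] + 1), matrix(1, n, n),
               tolerance = 1e-10)
})

test_that("spectral filters applied to real images give real images", {
  set.seed(3)
  n <- 32
  img <- matrix(runif(n * n), n, n)
  for (mk in list(function() ramp_filter_2d(n),
                  function() weighted_ramp_2d(n, uniform_angles(9), 1))) {
    resp <- tomowiener:::.ifftshift2(unclass(mk()))
    out <- stats::fft(stats::fft(img) * resp, inverse = TRUE) / n^2
    expect_lt(max(abs(Im(out))), 1e-8 * max(abs(Re(out))))
  }
})
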