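test_that("gaussian window weights follow the evaluated Gaussian", {
  # odd window with sigma = 1 pixel: neighbours of the centre weigh
  # exp(-0.5), next ring exp(-2)
  w <- gaussian_window_weights(9, sigma_scale = 1 / 9)
  expect_equal(w[5], 1)
  expect_equal(w[4], exp(-0.5)); expect_equal(w[6], exp(-0.5))
  expect_equal(w[3], exp(-2))
  # symmetric per axis for every size
  for (n in c(7, 8, 16)) {
    wn <- gaussian_window_weights(n, 0.125)
    expect_equal(wn, rev(wn))
    expect_true(all(wn > 0))
    expect_equal(max(wn), 1)
  }
  # separable in 2D: outer product of the axis profiles
  w2 <- gaussian_window_weights(c(8, 16), 0.125)
  expect_equal(dim(w2), c(8L, 16L))
  p1 <- gaussian_window_weights(8, 0.125)
  p2 <- gaussian_window_weights(16, 0.125)
  expect_equal(w2, outer(p1, p2) / max(outer(p1, p2)))
})

test_that("identity model through tiling reproduces the normalized input", {
  idn <- build_identity_network(dim = 2)
  img <- nd_image(matrix(runif(31 * 33, 0, 500), 31, 33), c("Y", "X"))
  norm <- list(name = "percentile_normalize", lo = 0.5, hi = 99.5)
  want <- apply_transform(img, norm)$data
  for (ov in c(0, 0.25, 0.5)) for (bl in c("gaussian", "uniform")) {
    out <- predict_image(img, idn,
                         list(window_size = c(16, 16), overlap = ov,
                              blend = bl), norm = norm)
    expect_identical(dim(out$data), c(1L, 31L, 33L))
    expect_lt(max(abs(array(out$data[1, , ], c(31, 33)) - want)), 1e-5)
  }
})

test_that("timepoints are processed independently", {
  idn <- build_identity_network(dim = 2)
  arr <- array(runif(3 * 16 * 16), c(3, 16, 16))
  img <- nd_image(arr, c("T", "Y", "X"))
  spec <- list(window_size = c(8, 8), overlap = 0.25)
  norm <- list(name = "minmax_normalize")
  out <- predict_image(img, idn, spec, norm = norm)
  expect_identical(dim(out$data)[1], 3L)
  for (t in 1:3) {
    single <- predict_image(nd_image(arr[t, , ], c("Y", "X")), idn, spec,
                            norm = norm)
    expect_equal(as.vector(out$data[t, 1, , ]), as.vector(single$data),
                 tolerance = 1e-12)
  }
})

test_that("constant models blend seamlessly and stitch clips dtypes", {
  cnet <- build_identity_network(dim = 2, shift = 3.25)
  zero_in <- nd_image(matrix(0, 20, 20), c("Y", "X"))
  out <- predict_image(zero_in, function(x) x * 0 + 3.25,
                       list(window_size = c(8, 8), overlap = 0.4,
                            blend = "gaussian"))
  expect_lt(max(abs(out$data - 3.25)), 1e-10)
  # two half-overlapping windows: closed-form weighted average
  acc <- array(0, c(4, 1)); wacc <- array(0, c(4, 1))
  w <- c(0.3, 1, 1, 0.3)
  p <- 2; q <- 5
  acc[1:3] <- acc[1:3] + w[1:3] * p; wacc[1:3] <- wacc[1:3] + w[1:3]
  acc[2:4] <- acc[2:4] + w[2:4] * q; wacc[2:4] <- wacc[2:4] + w[2:4]
  st <- stitch(acc, wacc)
  expect_equal(st[2], (1 * p + w[3] * q) / (1 + w[3]))
  # dtype saturation
  expect_equal(as.vector(stitch(array(70000, c(2, 2)), array(1, c(2, 2)),
                                "uint")), rep(65535, 4))
  expect_error(stitch(array(1, 4), array(0, 4)), "coverage")
})

test_that("gaussian blending attenuates window-edge artifacts", {
  # model corrupts a 2-pixel border of every window it sees: windows
  # disagree sharply at their edges, the classic stitching-artifact case
  corrupt <- function(x) {
    S <- dim(x)[2:3]
    x[, 1:2, , ] <- 0; x[, (S[1] - 1):S[1], , ] <- 0
    x[, , 1:2, ] <- 0; x[, , (S[2] - 1):S[2], ] <- 0
    x
  }
  img <- nd_image(matrix(runif(48 * 48, 0.5, 1), 48, 48), c("Y", "X"))
  untiled <- corrupt(array(img$data, c(1, 48, 48, 1)))
  err <- function(blend) {
    out <- predict_image(img, corrupt,
                         list(window_size = c(16, 16), overlap = 0.5,
                              blend = blend))
    max(abs(as.vector(out$data) - as.vector(untiled)))
  }
  expect_lt(err("gaussian"), err("uniform"))
})

test_that("3D inference preserves shape including primes", {
  idn <- build_identity_network(dim = 3)
  arr <- array(runif(7 * 31 * 33), c(7, 31, 33))
  img <- nd_image(arr, c("Z", "Y", "X"))
  out <- predict_image(img, idn, list(window_size = c(4, 16, 16),
                                      overlap = 0.25),
                       norm = list(name = "standard_normalize"))
  expect_identical(dim(out$data), c(1L, 7L, 31L, 33L))
  want <- standard_normalize(img)$data
  expect_lt(max(abs(array(out$data[1, , , ], c(7, 31, 33)) - want)), 1e-5)
})

test_that("window sizes exceeding the image shrink to it", {
  idn <- build_identity_network(dim = 2)
  img <- nd_image(matrix(runif(100), 10, 10), c("Y", "X"))
  out <- predict_image(img, idn, list(window_size = c(64, 64)),
                       norm = list(name = "minmax_normalize"))
  expect_identical(dim(out$data), c(1L, 10L, 10L))
})

test_that("un_normalize round-trips inference back to input units", {
  idn <- build_identity_network(dim = 2)
  img <- nd_image(matrix(runif(256, 100, 900), 16, 16), c("Y", "X"))
  out <- predict_image(img, idn,
                       list(window_size = c(8, 8), un_normalize = TRUE),
                       norm = list(name = "minmax_normalize"))
  expect_lt(max(abs(array(out$data[1, , ], c(16, 16)) - img$data)), 1e-6)
})

test_that("a U-Net padded through inference keeps spatial shape", {
  net <- build_unet(dim = 2, depth = 2, base_filters = 4,
                    rng = rng_stream(2))
  img <- nd_image(matrix(runif(31 * 33), 31, 33), c("Y", "X"))
  out <- predict_image(img, net, list(window_size = c(16, 16)),
                       norm = list(name = "standard_normalize"))
  expect_identical(dim(out$data), c(1L, 31L, 33L))
})
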