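test_that("percentile normalization matches the direct formula", {
  img <- nd_image(matrix(0:99, 10, 10), c("Y", "X"))
  out <- percentile_normalize(img, 0, 100, c(-1, 1))
  expect_equal(min(out$data), -1)
  expect_equal(max(out$data), 1)
  expect_equal(unname(out$data[img$data == 49]),
               (49 - 0) / 99 * 2 - 1)
  # random arrays against an independent direct-formula oracle
  set.seed(42)
  for (i in 1:10) {
    a <- array(rnorm(200, sd = runif(1, 0.5, 10)), c(10, 20))
    got <- percentile_normalize(nd_image(a, c("Y", "X")), 0.5, 99.5)$data
    p <- quantile(a, c(0.005, 0.995), names = FALSE, type = 7)
    want <- (pmin(pmax(a, p[1]), p[2]) - p[1]) / (p[2] - p[1]) * 2 - 1
    expect_lt(max(abs(got - want)), 1e-12)
  }
  expect_error(percentile_normalize(nd_image(matrix(5, 4, 4), c("Y", "X"))),
               "degenerate")
})

test_that("standard normalization uses population statistics", {
  img <- nd_image(array(c(1, 3), c(1, 2)), c("Y", "X"))
  out <- standard_normalize(img)
  expect_equal(as.vector(out$data), c(-1, 1))
  a <- array(rnorm(500, 7, 3), c(20, 25))
  out2 <- standard_normalize(nd_image(a, c("Y", "X")))$data
  expect_lt(abs(mean(out2)), 1e-10)
  expect_lt(abs(sqrt(mean((out2 - mean(out2))^2)) - 1), 1e-10)
  # idempotent up to float error
  out3 <- standard_normalize(out2 |> nd_image(c("Y", "X")))$data
  expect_lt(max(abs(out3 - out2)), 1e-10)
  expect_error(standard_normalize(nd_image(matrix(2, 3, 3), c("Y", "X"))),
               "degenerate")
})

test_that("center normalization uses the middle Z chunk", {
  # Z = 4 constant planes {0, 2, 4, 0}, fraction 0.5 -> chunk {2, 4}
  arr <- array(0, c(4, 3, 3))
  arr[2, , ] <- 2; arr[3, , ] <- 4
  img <- nd_image(arr, c("Z", "Y", "X"))
  out <- center_normalize(img, 0.5)
  expect_equal(unique(as.vector(out$data[1, , ])), -3)
  expect_equal(unique(as.vector(out$data[2, , ])), -1)
  expect_equal(unique(as.vector(out$data[3, , ])), 1)
  expect_equal(unique(as.vector(out$data[4, , ])), -3)
  # fraction 1 is exactly standard normalization
  a <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  i2 <- nd_image(a, c("Z", "Y", "X"))
  expect_lt(max(abs(center_normalize(i2, 1)$data -
                    standard_normalize(i2)$data)), 1e-6)
  # degenerate cases
  expect_error(center_normalize(nd_image(array(0, c(1, 4, 4)),
                                         c("Z", "Y", "X"))), "Z extent")
  expect_error(center_normalize(nd_image(matrix(0, 4, 4), c("Y", "X"))),
               "Z axis")
})

test_that("normalizations are invariant to voxel ordering", {
  a <- array(rexp(64), c(8, 8))
  perm <- sample(64)
  b <- array(a[perm], c(8, 8))
  na <- percentile_normalize(nd_image(a, c("Y", "X")), 1, 99)$data
  nb <- percentile_normalize(nd_image(b, c("Y", "X")), 1, 99)$data
  expect_equal(sort(as.vector(na)), sort(as.vector(nb)))
  expect_equal(as.vector(nb), as.vector(na)[perm])
})

test_that("normalization statistics invert exactly", {
  a <- array(runif(100, 10, 500), c(10, 10))
  img <- nd_image(a, c("Y", "X"))
  for (fn in list(percentile_normalize, standard_normalize,
                  minmax_normalize)) {
    out <- fn(img)
    back <- un_normalize(out, attr(out, "norm_stats"))
    # percentile clipping loses the tails; the interior inverts exactly
    q <- quantile(a, c(0.005, 0.995))
    sel <- a >= q[1] & a <= q[2]
    expect_lt(max(abs(back$data[sel] - a[sel])), 1e-9)
  }
})

test_that("stain normalization transfers channel statistics", {
  set.seed(7)
  spec <- fixture_spec("stain", dim = 2, seed = 31, n_images = 1,
                       noise_sd = 0.01)
  w <- make_blob_world(spec, rng_stream(3))
  rngs <- rng_stream(4)
  ref <- render_task_pair(spec, w, rngs)$source
  w2 <- make_blob_world(spec, rng_stream(13))
  tile <- render_task_pair(spec, w2, rng_stream(14))$source
  sref <- fit_stain_reference(ref)
  expect_true(all(sref$sigma > 0))
  # self-normalization is the identity up to colour-space round trip
  self <- apply_stain_norm(ref, sref)
  expect_lt(max(abs(self$data - ref$data)), 0.02)
  # post-hoc channel stats equal the reference stats
  outt <- apply_stain_norm(tile, sref)
  sout <- fit_stain_reference(outt)
  expect_lt(max(abs(sout$mu - sref$mu)), 1e-3)
  expect_lt(max(abs(sout$sigma - sref$sigma)), 1e-3)
  # idempotent against its own reference
  out2 <- apply_stain_norm(outt, sref)
  expect_lt(max(abs(out2$data - outt$data)), 0.02)
  expect_error(fit_stain_reference(nd_image(matrix(1, 4, 4), c("Y", "X"))),
               "3-channel")
})

test_that("pad_to_valid pads reflectively to the down-sampling multiple", {
  img <- nd_image(matrix(runif(900), 30, 30), c("Y", "X"))
  pv <- pad_to_valid(img, c(8, 8))
  expect_identical(dim(pv$img$data), c(32L, 32L))
  back <- crop_from_pad(pv$img, pv$crop)
  expect_identical(back$data, img$data)
  # already valid: identity
  img2 <- nd_image(matrix(runif(1024), 32, 32), c("Y", "X"))
  pv2 <- pad_to_valid(img2, c(8, 8))
  expect_identical(pv2$img$data, img2$data)
  # anisotropic factors: pad only where the factor demands it
  arr <- array(runif(5 * 30 * 30), c(5, 30, 30))
  pv3 <- pad_to_valid(nd_image(arr, c("Z", "Y", "X")), c(1, 8, 8))
  expect_identical(dim(pv3$img$data), c(5L, 32L, 32L))
  expect_identical(crop_from_pad(pv3$img, pv3$crop)$data, arr)
})
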