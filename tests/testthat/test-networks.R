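test_that("backprop matches finite differences on 2D and 3D U-Nets", {
  for (d in 2:3) {
    S <- if (d == 2) c(8, 8) else c(4, 8, 8)
    net <- build_unet(dim = d, in_channels = 1, out_channels = 2,
                      depth = 2, base_filters = 3,
                      z_factors = if (d == 3) 1L,
                      norm = "instance", rng = rng_stream(7))
    set.seed(d)
    x <- array(rnorm(2 * prod(S)), c(2, S, 1))
    t <- array(rnorm(2 * prod(S) * 2), c(2, S, 2))
    fw <- net_forward(net, x, with_cache = TRUE)
    dy <- 2 * (fw$y - t) / length(t)
    bw <- net_backward(net, dy, fw$cache)
    lossfn <- function(n) mean((net_forward(n, x) - t)^2)
    eps <- 1e-5
    ids <- sample(names(net$params), 4)
    for (id in ids) for (nm in names(net$params[[id]])) {
      i <- sample(length(net$params[[id]][[nm]]), 1)
      np <- net
      np$params[[id]][[nm]][i] <- np$params[[id]][[nm]][i] + eps
      l1 <- lossfn(np)
      np$params[[id]][[nm]][i] <- np$params[[id]][[nm]][i] - 2 * eps
      l0 <- lossfn(np)
      fd <- (l1 - l0) / (2 * eps)
      an <- bw$grads[[id]][[nm]][i]
      expect_lt(abs(fd - an), 1e-6 + 1e-4 * abs(fd))
    }
    # input gradient
    i <- 11
    xe <- x; xe[i] <- x[i] + eps; l1 <- mean((net_forward(net, xe) - t)^2)
    xe[i] <- x[i] - eps; l0 <- mean((net_forward(net, xe) - t)^2)
    expect_lt(abs((l1 - l0) / (2 * eps) - bw$dx[i]), 1e-6)
  }
})

test_that("U-Net forward obeys shape and activation contracts", {
  net <- build_unet(dim = 2, depth = 2, base_filters = 4,
                    final_activation = "tanh", rng = rng_stream(1))
  y <- net_forward(net, array(rnorm(32 * 32), c(1, 32, 32, 1)))
  expect_identical(dim(y), c(1L, 32L, 32L, 1L))
  expect_true(all(y > -1 & y < 1))
  # depth 1: plain conv blocks, no pooling, any extent works
  n1 <- build_unet(dim = 2, depth = 1, base_filters = 4, rng = rng_stream(2))
  expect_identical(net_down_factors(n1), c(1L, 1L))
  y1 <- net_forward(n1, array(rnorm(13 * 17), c(1, 13, 17, 1)))
  expect_identical(dim(y1), c(1L, 13L, 17L, 1L))
  expect_false(isTRUE(all.equal(as.vector(y1), rnorm(13 * 17))))
  # indivisible extent errors name the axis
  expect_error(net_forward(net, array(0, c(1, 31, 32, 1))),
               "shape-contract.*axis 1")
  expect_error(net_forward(net, array(0, c(1, 32, 32, 2))), "channels")
})

test_that("anisotropic factors gate the Z divisibility requirement", {
  # four down-sampling steps, Z factors (1,1,2,2): total Z 4, XY 16
  net <- build_unet(dim = 3, depth = 5, base_filters = 2,
                    z_factors = c(1L, 1L, 2L, 2L), rng = rng_stream(3))
  expect_identical(net_down_factors(net), c(4L, 16L, 16L))
  y <- net_forward(net, array(rnorm(8 * 16 * 16), c(1, 8, 16, 16, 1)))
  expect_identical(dim(y), c(1L, 8L, 16L, 16L, 1L))
  # an isotropic net of the same depth would demand Z >= 16
  iso <- build_unet(dim = 3, depth = 5, base_filters = 2,
                    z_factors = c(2L, 2L, 2L, 2L), rng = rng_stream(3))
  expect_identical(net_down_factors(iso)[1], 16L)
  expect_error(net_forward(iso, array(0, c(1, 8, 16, 16, 1))),
               "shape-contract")
  # all-Z-factor-1: a 4-slice stack passes through a deep network
  flat <- build_unet(dim = 3, depth = 4, base_filters = 2,
                     z_factors = c(1L, 1L, 1L), rng = rng_stream(4))
  yf <- net_forward(flat, array(rnorm(4 * 64 * 64), c(1, 4, 64, 64, 1)))
  expect_identical(dim(yf), c(1L, 4L, 64L, 64L, 1L))
})

test_that("patch discriminator emits a spatial logit grid", {
  D <- build_patch_discriminator(dim = 2, in_channels = 2,
                                 n_blocks = 3, rng = rng_stream(5))
  y <- net_forward(D, array(rnorm(2 * 64 * 64), c(1, 64, 64, 2)))
  expect_identical(dim(y), c(1L, 8L, 8L, 1L))
  expect_gt(prod(dim(y)[2:3]), 1)                # patch-wise, not scalar
  y2 <- net_forward(D, array(1e3, c(1, 64, 64, 2)))
  expect_true(all(is.finite(y2)))
  y3 <- net_forward(D, array(-1e3, c(1, 64, 64, 2)))
  expect_true(all(is.finite(y3)))
  # unconditional variant accepts single-image channel counts
  Du <- build_patch_discriminator(dim = 2, in_channels = 1,
                                  rng = rng_stream(6))
  expect_identical(dim(net_forward(Du, array(0, c(1, 32, 32, 1)))),
                   c(1L, 4L, 4L, 1L))
})

test_that("architecture and initialization are deterministic", {
  n1 <- build_unet(dim = 2, depth = 3, base_filters = 16,
                   rng = rng_stream(11))
  n2 <- build_unet(dim = 2, depth = 3, base_filters = 16,
                   rng = rng_stream(11))
  expect_identical(net_n_params(n1), net_n_params(n2))
  expect_identical(unname(lapply(n1$params, unname)),
                   unname(lapply(n2$params, unname)))
  # eval-mode forward is deterministic
  x <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  expect_identical(net_forward(n1, x), net_forward(n1, x))
})
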