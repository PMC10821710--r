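test_that("FCN loss hits its floor for perfect and constant predictions", {
  net <- build_unet(dim = 2, depth = 2, base_filters = 4,
                    rng = rng_stream(1))
  x <- array(rnorm(2 * 16 * 16), c(2, 16, 16, 1))
  # perfect prediction: target equals the network's own output
  tgt <- net_forward(net, x)
  r <- fcn_step(list(source = x, target = tgt), net,
                list(recon_loss = "mae"))
  expect_equal(r$loss, 0)
  # all-zero network against a constant-1 target: MAE exactly 1
  z <- zero_net(net)
  r2 <- fcn_step(list(source = x, target = array(1, dim(x))), z,
                 list(recon_loss = "mae"))
  expect_equal(r2$loss, 1)
})

test_that("pix2pix with zero adversarial weight degenerates to the FCN", {
  G <- build_unet(dim = 2, depth = 2, base_filters = 4, rng = rng_stream(2))
  D <- build_patch_discriminator(dim = 2, in_channels = 2,
                                 rng = rng_stream(3))
  x <- array(rnorm(2 * 16 * 16), c(2, 16, 16, 1))
  t <- array(rnorm(2 * 16 * 16), c(2, 16, 16, 1))
  batch <- list(source = x, target = t)
  cfg <- list(recon_weight = 1, adv_weight = 0, recon_loss = "mae")
  rp <- pix2pix_step(batch, G, D, cfg, phase = "gen")
  rf <- fcn_step(batch, G, list(recon_loss = "mae"))
  expect_equal(rp$loss, rf$loss)
  for (id in names(rf$grads))
    for (nm in names(rf$grads[[id]]))
      expect_lt(max(abs(rp$grads[[id]][[nm]] - rf$grads[[id]][[nm]])), 1e-6)
})

test_that("lsgan discriminator loss is 0.25 when D outputs 0.5 everywhere", {
  G <- build_unet(dim = 2, depth = 1, base_filters = 2, rng = rng_stream(4))
  D <- zero_net(build_patch_discriminator(dim = 2, in_channels = 2,
                                          rng = rng_stream(5)),
                final_bias = 0.5)
  x <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  t <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  r <- pix2pix_step(list(source = x, target = t), G, D,
                    list(gan_objective = "lsgan"), phase = "disc")
  expect_equal(r$loss, 0.5 * ((0.5 - 1)^2 + (0.5 - 0)^2))
})

test_that("phase gradients touch only the phase's own network", {
  G <- build_unet(dim = 2, depth = 2, base_filters = 4, rng = rng_stream(6))
  D <- build_patch_discriminator(dim = 2, in_channels = 2,
                                 rng = rng_stream(7))
  x <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  t <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  batch <- list(source = x, target = t)
  cfg <- list(recon_weight = 1, adv_weight = 1, gan_objective = "lsgan",
              recon_loss = "mae")
  rg <- pix2pix_step(batch, G, D, cfg, phase = "gen")
  expect_true(all(names(rg$grads) %in% names(G$params)))
  rd <- pix2pix_step(batch, G, D, cfg, phase = "disc")
  expect_true(all(names(rd$grads) %in% names(D$params)))
  expect_length(intersect(names(rg$grads), names(rd$grads)), 0)
})

test_that("generator pre-initialization reproduces the FCN bitwise", {
  G0 <- build_unet(dim = 2, depth = 2, base_filters = 4,
                   rng = rng_stream(8))
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(ck, list(G = G0))
  G1 <- build_unet(dim = 2, depth = 2, base_filters = 4,
                   rng = rng_stream(999))     # different init
  G1 <- init_generator_from(G1, ck)
  x <- array(rnorm(16 * 16), c(1, 16, 16, 1))
  expect_identical(net_forward(G1, x), net_forward(G0, x))
})

test_that("CycleGAN at the identity has zero cycle and identity losses", {
  idn <- build_identity_network(dim = 2)
  nets <- list(G_AB = idn, G_BA = idn,
               D_A = build_patch_discriminator(dim = 2, in_channels = 1,
                                               rng = rng_stream(9)),
               D_B = build_patch_discriminator(dim = 2, in_channels = 1,
                                               rng = rng_stream(10)))
  a <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  b <- array(rnorm(32 * 32), c(1, 32, 32, 1))
  r <- cyclegan_step(list(a = a, b = b), nets,
                     list(adv_weight = 0, cycle_weight = 10,
                          identity_weight = 5), phase = "gen")
  expect_equal(r$loss, 0)
})

test_that("CycleGAN cycle term has the L1 closed form for constant shifts", {
  # G_AB adds c, G_BA adds 0: both cycle directions miss by exactly c
  cshift <- 0.37
  nets <- list(G_AB = build_identity_network(dim = 2, shift = cshift),
               G_BA = build_identity_network(dim = 2))
  a <- array(0.2, c(1, 16, 16, 1))
  b <- array(-0.4, c(1, 16, 16, 1))
  r <- cyclegan_step(list(a = a, b = b), nets,
                     list(adv_weight = 0, cycle_weight = 1,
                          identity_weight = 0), phase = "gen")
  expect_equal(r$loss, 2 * cshift, tolerance = 1e-12)
})

test_that("all framework steps stay finite on [-1, 1] inputs", {
  G <- build_unet(dim = 2, depth = 2, base_filters = 4,
                  final_activation = "tanh", rng = rng_stream(11))
  D <- build_patch_discriminator(dim = 2, in_channels = 2,
                                 rng = rng_stream(12))
  x <- array(runif(2 * 16 * 16, -1, 1), c(2, 16, 16, 1))
  t <- array(runif(2 * 16 * 16, -1, 1), c(2, 16, 16, 1))
  b <- list(source = x, target = t)
  expect_true(is.finite(fcn_step(b, G, list(recon_loss = "mae"))$loss))
  cfg <- list(recon_weight = 100, adv_weight = 1, gan_objective = "lsgan",
              recon_loss = "mae")
  expect_true(is.finite(pix2pix_step(b, G, D, cfg, "gen")$loss))
  expect_true(is.finite(pix2pix_step(b, G, D, cfg, "disc")$loss))
  cfgv <- cfg; cfgv$gan_objective <- "vanilla"
  expect_true(is.finite(pix2pix_step(b, G, D, cfgv, "gen")$loss))
})

test_that("a tiny FCN learns a synthetic inversion task", {
  # target = -source: loss must drop by at least half over the schedule
  net <- build_unet(dim = 2, depth = 2, base_filters = 4,
                    rng = rng_stream(20))
  opt <- adam_init(net$params)
  st <- rng_stream(21)
  losses <- numeric(80)
  for (i in seq_len(80)) {
    x <- with_rng(st, array(rnorm(2 * 16 * 16), c(2, 16, 16, 1)))
    r <- fcn_step(list(source = x, target = -x), net,
                  list(recon_loss = "mse"))
    u <- adam_step(net$params, r$grads, opt, lr = 5e-3)
    net$params <- u$params; opt <- u$state
    losses[i] <- r$loss
  }
  expect_lt(mean(tail(losses, 5)), 0.5 * losses[1])
})

test_that("checkpoints resume with continuous epoch counting", {
  dir <- make_fixture_dir(n_images = 4, seed = 40)
  cfg <- tiny_fcn_cfg(dir, seed = 3, epochs = 1, steps = 4)
  out1 <- tempfile("run_")
  r1 <- fit_run(cfg, out_dir = out1)
  expect_identical(r1$history$epoch, 1L)
  r2 <- fit_run(cfg, out_dir = tempfile("run_"),
                resume_from = r1$last_path)
  expect_identical(r2$history$epoch, 2L)
})
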