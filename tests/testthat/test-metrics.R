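test_that("pearson handles the exact and the noisy closed form", {
  g <- array(rnorm(1000), c(10, 100))
  expect_equal(pearson(g, g), 1)
  expect_equal(pearson(-g, g), -1)
  expect_error(pearson(array(1, c(4, 4)), g[1:4, 1:4]), "constant")
  # pred = gt + iid noise at SNR 4: rho = 1/sqrt(1 + 1/SNR)
  set.seed(12)
  gt <- rnorm(2e5)
  snr <- 4
  pred <- gt + rnorm(2e5, sd = sqrt(1 / snr))
  expect_equal(pearson(pred, gt), 1 / sqrt(1 + 1 / snr), tolerance = 0.01)
})

test_that("ssim matches a naive per-window oracle", {
  set.seed(3)
  x <- matrix(runif(20 * 20), 20, 20)
  expect_equal(ssim(x, x, data_range = 1), 1)
  # constant shift: closed form via the oracle
  y <- x + 0.5
  expect_equal(ssim(x, y, data_range = 1), oracle_ssim(x, y, 1),
               tolerance = 1e-10)
  # arbitrary pair
  z <- matrix(runif(20 * 20), 20, 20)
  expect_equal(ssim(x, z, data_range = 1), oracle_ssim(x, z, 1),
               tolerance = 1e-10)
  # independent noise: near zero
  a <- matrix(rnorm(64 * 64), 64, 64); b <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(abs(ssim(a, b, data_range = max(a, b) - min(a, b))), 0.05)
  # 3D: plane-averaged 2D
  v1 <- array(runif(3 * 16 * 16), c(3, 16, 16))
  v2 <- array(runif(3 * 16 * 16), c(3, 16, 16))
  planes <- vapply(1:3, function(z) ssim(v1[z, , ], v2[z, , ], 1), 0)
  expect_equal(ssim(v1, v2, 1), mean(planes))
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4), 1), "window")
})

test_that("psnr follows its formula and conventions", {
  g <- matrix(0, 10, 10)
  p <- g; p[] <- 0.1                           # MSE = 0.01, range 1
  expect_equal(psnr(p, g, data_range = 1), 20)
  expect_identical(psnr(g, g, 1), Inf)
  expect_equal(psnr(p, g, data_range = 2) - psnr(p, g, data_range = 1),
               20 * log10(2))
})

test_that("pixel F1 counts overlaps correctly", {
  a <- matrix(0, 4, 4); b <- a
  expect_equal(f1_pixel(a, b), 1)              # empty vs empty
  a[1, 1:4] <- 1                                # 4 px
  b[1, 3:4] <- 1; b[2, 1:2] <- 1                # 4 px, overlap 2
  expect_equal(f1_pixel(a, b), 0.5)
  expect_equal(f1_pixel(matrix(0, 4, 4), b), 0)
  expect_equal(f1_pixel(a, a), 1)
})

test_that("average precision reproduces hand-computed matchings", {
  m <- array(0L, c(10, 10)); m[2:4, 2:4] <- 1L; m[7:9, 7:9] <- 2L
  expect_equal(average_precision(m, m), 1)
  expect_equal(average_precision(array(0L, c(10, 10)),
                                 array(0L, c(10, 10))), 1)
  disj <- array(0L, c(10, 10)); disj[5:6, 5:6] <- 1L
  shifted <- array(0L, c(10, 10)); shifted[1, 1] <- 1L
  expect_equal(average_precision(shifted, disj), 0)
  # 2 gt vs 2 pred: one pair IoU 0.6, the other 0.2 -> TP=1,FP=1,FN=1
  gt <- array(0L, c(20, 20)); gt[1:5, 1:2] <- 1L; gt[11:15, 1:2] <- 2L
  pr <- array(0L, c(20, 20))
  pr[1:3, 1:2] <- 1L                           # IoU 6/10 = 0.6 with gt 1
  pr[15:16, 1:2] <- 2L                         # IoU 1/11 with gt 2
  expect_equal(average_precision(pr, gt), 1 / 3)
})

test_that("greedy matching equals the optimal assignment on small maps", {
  set.seed(77)
  for (trial in 1:12) {
    S <- c(24, 24)
    mk <- function(k) {
      m <- array(0L, S)
      for (j in seq_len(k)) {
        cy <- sample(3:21, 1); cx <- sample(3:21, 1)
        m[max(1, cy - 2):min(24, cy + 2),
          max(1, cx - 2):min(24, cx + 2)] <- j
      }
      m
    }
    gt <- mk(sample(1:4, 1)); pr <- mk(sample(1:4, 1))
    expect_equal(average_precision(pr, gt), oracle_ap(pr, gt),
                 info = paste("trial", trial))
  }
})

test_that("metric reports aggregate with population statistics", {
  per <- data.frame(id = c("a", "b", "c"),
                    metric = "pearson",
                    value = c(0.9, 0.8, 0.7))
  rep <- metric_report(per)
  expect_equal(rep$summary$mean, 0.8)
  expect_equal(rep$summary$sd, sqrt(mean((per$value - 0.8)^2)))
  expect_equal(rep$summary$n, 3L)
  # serialization round trip
  pre <- file.path(tempfile("rep_"))
  dir.create(dirname(pre), showWarnings = FALSE, recursive = TRUE)
  write_metric_report(rep, pre)
  back <- read.csv(paste0(pre, "_per_image.csv"))
  expect_equal(back$value, per$value)
  js <- jsonlite::read_json(paste0(pre, "_summary.json"))
  expect_equal(js$pearson, 0.8)
})

test_that("regression metrics are invariant to joint affine rescaling", {
  x <- matrix(runif(144), 12, 12); y <- matrix(runif(144), 12, 12)
  expect_equal(pearson(2 * x + 3, 2 * y + 3), pearson(x, y))
  expect_equal(ssim(2 * x, 2 * y, data_range = 2),
               ssim(x, y, data_range = 1), tolerance = 1e-10)
  expect_equal(psnr(2 * x + 3, 2 * y + 3, data_range = 2),
               psnr(x, y, data_range = 1))
  # symmetry where it holds mathematically
  expect_equal(pearson(x, y), pearson(y, x))
  expect_equal(ssim(x, y, 1), ssim(y, x, 1))
})
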