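test_that("instance centers match brute-force centroid and medoid", {
  # 3x3 square: both centers are its middle pixel
  m <- array(0L, c(9, 9)); m[4:6, 4:6] <- 1L
  for (mode in c("centroid", "medoid")) {
    tc <- compute_centers(m, mode)
    expect_equal(unname(tc$centers[1, ]), c((5 - 0.5) / 9, (5 - 0.5) / 9))
  }
  # L-shaped 3-pixel instance: brute-force oracle
  m2 <- array(0L, c(4, 4))
  m2[1, 1] <- 1L; m2[1, 2] <- 1L; m2[2, 1] <- 1L
  pos <- arrayInd(which(m2 == 1), c(4, 4))
  nc <- sweep(pos - 0.5, 2, c(4, 4), `/`)
  expect_equal(unname(compute_centers(m2, "centroid")$centers[1, ]),
               colMeans(nc))
  dd <- as.matrix(dist(nc))
  expect_equal(unname(compute_centers(m2, "medoid")$centers[1, ]),
               nc[which.min(rowSums(dd)), ])
  # empty map: zero instances
  te <- compute_centers(array(0L, c(4, 4)))
  expect_length(te$labels, 0)
})

test_that("embedseg loss gradients match finite differences", {
  S <- c(12, 12)
  m <- array(0L, S); m[3:6, 3:6] <- 1L; m[8:10, 8:11] <- 2L
  tgt <- compute_centers(m, "medoid")
  set.seed(5)
  raw <- array(rnorm(prod(S) * 4, sd = 0.3), c(1, S, 4))
  raw[, , , 3] <- raw[, , , 3] - 1.5          # sigma in a sane band
  eps <- 1e-6
  # offsets and sigma channels: the seed target detaches phi, so check
  # with the seed term switched off
  cfg_ns <- list(w_instance = 1, w_smooth = 10, w_seed = 0, margin = 3)
  r <- embedseg_loss_grad(raw, tgt, cfg_ns)
  for (ch in 1:3) for (rep in 1:3) {
    i <- sample(prod(S), 1)
    idx <- cbind(1, arrayInd(i, S), ch)
    r2 <- raw; r2[idx] <- r2[idx] + eps
    l1 <- embedseg_loss_grad(r2, tgt, cfg_ns)$loss
    r2[idx] <- r2[idx] - 2 * eps
    l0 <- embedseg_loss_grad(r2, tgt, cfg_ns)$loss
    fd <- (l1 - l0) / (2 * eps)
    expect_lt(abs(fd - r$draw[idx]), 1e-5 + 1e-3 * abs(fd))
  }
  # seed channel: full objective (phi is constant w.r.t. the seed head)
  cfg_full <- list(w_instance = 1, w_smooth = 10, w_seed = 1, margin = 3)
  rs <- embedseg_loss_grad(raw, tgt, cfg_full)
  for (rep in 1:3) {
    i <- sample(prod(S), 1)
    idx <- cbind(1, arrayInd(i, S), 4)
    r2 <- raw; r2[idx] <- r2[idx] + eps
    l1 <- embedseg_loss_grad(r2, tgt, cfg_full)$loss
    r2[idx] <- r2[idx] - 2 * eps
    l0 <- embedseg_loss_grad(r2, tgt, cfg_full)$loss
    fd <- (l1 - l0) / (2 * eps)
    expect_lt(abs(fd - rs$draw[idx]), 1e-6 + 1e-3 * abs(fd))
  }
})

test_that("analytically optimal fields reach the loss floor", {
  S <- c(16, 16)
  m <- array(0L, S); m[4:8, 4:8] <- 1L
  tgt <- compute_centers(m, "centroid")
  coords <- array(im2im:::.norm_coords(S), c(prod(S), 2))
  raw <- array(0, c(1, S, 4))
  # offsets: exactly center - coordinate on the instance
  for (a in 1:2) {
    o <- numeric(prod(S))
    o[tgt$pixels[[1]]] <- tgt$centers[1, a] - coords[tgt$pixels[[1]], a]
    raw[, , , a] <- array(o, S)
  }
  # background embeddings pushed far away: their affinity is exactly 0
  for (a in 1:2) {
    o <- array(raw[1, , , a], S)
    o[m == 0L] <- 10
    raw[, , , a] <- o
  }
  raw[, , , 3] <- log(0.5)                     # sigma ample: phi ~ 1 inside
  raw[, , , 4] <- 100                          # seed saturated at 1 (fg)
  sat <- embedseg_loss_grad(raw, tgt,
                            list(w_instance = 1, w_smooth = 10, w_seed = 0,
                                 margin = 2))
  # constant sigma: smoothness term exactly 0 -> compare w_smooth on/off
  off <- embedseg_loss_grad(raw, tgt,
                            list(w_instance = 1, w_smooth = 0, w_seed = 0,
                                 margin = 2))
  expect_equal(sat$loss, off$loss)
  # perfect embeddings: phi = 1 on every instance pixel
  eo <- embed_output_from_raw(raw)
  em <- array(eo$offsets, c(prod(S), 2)) + coords
  d2 <- rowSums(sweep(em[tgt$pixels[[1]], ], 2, tgt$centers[1, ])^2)
  expect_lt(max(d2), 1e-20)
  # loss far below that of unstructured fields
  rnd <- array(rnorm(prod(S) * 4), c(1, S, 4))
  worse <- embedseg_loss_grad(rnd, tgt,
                              list(w_instance = 1, w_smooth = 0,
                                   w_seed = 0, margin = 2))
  expect_lt(off$loss, 0.05 * worse$loss)
})

test_that("exclusion masking equals computing the loss on the complement", {
  S <- c(12, 24)
  m <- array(0L, S); m[4:8, 4:8] <- 1L        # instance in the left half
  tgt_full <- compute_centers(m, "medoid")
  excl <- array(0L, S); excl[, 13:24] <- 1L   # exclude the right half
  set.seed(9)
  raw <- array(rnorm(prod(S) * 4, sd = 0.2), c(1, S, 4))
  cfg <- list(w_instance = 1, w_smooth = 10, w_seed = 1, margin = 2)
  masked <- embedseg_loss_grad(raw, tgt_full, cfg, exclusion = excl)
  # cropped version: same pixels, offsets adjusted so embeddings agree
  Sc <- c(12, 12)
  mc <- m[, 1:12]
  tgt_crop <- compute_centers(mc, "medoid")
  # instance pixel coordinates rescale: translate center and offsets into
  # the cropped frame so that phi, sigma and seed are identical
  full_coords <- array(im2im:::.norm_coords(S), c(prod(S), 2))
  crop_coords <- array(im2im:::.norm_coords(Sc), c(prod(Sc), 2))
  raw_c <- array(0, c(1, Sc, 4))
  raw_c[, , , 3] <- array(raw[1, , 1:12, 3], Sc)
  raw_c[, , , 4] <- array(raw[1, , 1:12, 4], Sc)
  # embeddings in the full frame restricted to the left half:
  e_full <- full_coords + array(raw[1, , , 1:2], c(prod(S), 2))
  sel <- as.vector(col(array(0, S)) <= 12)
  e_left <- e_full[sel, ]
  # target center of the cropped instance must equal the full one for the
  # comparison to be meaningful: express cropped offsets in full coords
  raw_c[, , , 1] <- array(e_left[, 1] - crop_coords[, 1], Sc)
  raw_c[, , , 2] <- array(e_left[, 2] - crop_coords[, 2], Sc)
  tgt_crop$centers <- tgt_full$centers
  cropped <- embedseg_loss_grad(raw_c, tgt_crop, cfg)
  expect_equal(masked$loss, cropped$loss, tolerance = 1e-10)
})

test_that("decode matches the brute-force assignment oracle", {
  set.seed(31)
  n_match <- 0
  trial <- 0
  while (n_match < 16 && trial < 300) {
    trial <- trial + 1
    S <- c(sample(24:64, 1), sample(24:64, 1))
    k <- sample(1:5, 1)
    centers <- matrix(runif(2 * k, 0.15, 0.85), k, 2)
    # enforce separation so affinities are unambiguous
    if (k > 1 && min(dist(centers)) <= 0.3) next
    blobs <- lapply(seq_len(k), function(j) {
      cy <- round(centers[j, 1] * S[1]); cx <- round(centers[j, 2] * S[2])
      ys <- pmax(1, cy - 2):pmin(S[1], cy + 2)
      xs <- pmax(1, cx - 2):pmin(S[2], cx + 2)
      pix <- as.vector(outer(ys, (xs - 1) * S[1], `+`))
      list(center = centers[j, ], pixels = pix)
    })
    eo <- make_embed_fixture(S, blobs, sigma = 0.04)
    got <- decode_instances(eo, list(fg_threshold = 0.5,
                                     seed_threshold = 0.9, min_size = 2))
    want <- oracle_decode(eo, centers)
    expect_true(same_partition(got, want),
                info = sprintf("trial %d S=%s k=%d", trial,
                               paste(S, collapse = "x"), k))
    n_match <- n_match + 1
  }
  expect_gte(n_match, 16)
})

test_that("one embedding center can own multiple connected components", {
  S <- c(32, 32)
  ctr <- c(0.5, 0.5)
  pix1 <- as.vector(outer(4:7, (4:7 - 1) * S[1], `+`))
  pix2 <- as.vector(outer(24:27, (24:27 - 1) * S[1], `+`))
  eo <- make_embed_fixture(S, list(list(center = ctr,
                                        pixels = c(pix1, pix2))),
                           sigma = 0.05)
  m <- decode_instances(eo, list(fg_threshold = 0.5, seed_threshold = 0.9,
                                 min_size = 2))
  expect_identical(sort(unique(m[m > 0])), 1L)
  expect_identical(which(m == 1L), as.integer(sort(c(pix1, pix2))))
})

test_that("decode degenerate cases and determinism", {
  S <- c(16, 16)
  eo <- make_embed_fixture(S, list(), seed_bg = 0.1)
  expect_identical(decode_instances(eo), array(0L, S))
  blobs <- list(list(center = c(0.3, 0.3),
                     pixels = as.vector(outer(3:6, (3:6 - 1) * 16, `+`))))
  eo2 <- make_embed_fixture(S, blobs)
  expect_identical(decode_instances(eo2), decode_instances(eo2))
  # instances below min_size are discarded
  tiny <- list(list(center = c(0.7, 0.7), pixels = 200L))
  eo3 <- make_embed_fixture(S, tiny)
  expect_identical(decode_instances(eo3, list(min_size = 2)),
                   array(0L, S))
})

test_that("window merging keeps instance identity across overlaps", {
  full <- array(0L, c(16, 32))
  full[6:10, 12:20] <- 1L                     # spans the window overlap
  w1 <- full[, 1:20, drop = FALSE]
  w2 <- full[, 13:32, drop = FALSE]
  w2[w2 == 1L] <- 7L                          # window-local label
  merged <- merge_instance_windows(
    list(list(map = w1, origin = c(1L, 1L)),
         list(map = w2, origin = c(1L, 13L))), c(16L, 32L))
  expect_identical(sort(unique(merged[merged > 0])), 1L)
  expect_identical(which(merged > 0), which(full > 0))
  expect_equal(average_precision(merged, full), 1)
})
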