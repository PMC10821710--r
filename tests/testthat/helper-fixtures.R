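# Shared fixtures, built in code at test time.

# write a labelled image stack plus manifest layouts under a fresh dir
make_fixture_dir <- function(task = "labelfree", n_images = 4, seed = 7,
                             dim = 2, n_objects = c(2L, 4L)) {
  dir <- tempfile("fx_")
  spec <- fixture_spec(task, dim = dim, n_images = n_images, seed = seed,
                       n_objects = n_objects)
  make_task_pairs(spec, dir)
  dir
}

# zero all parameters of a network; optionally set the final conv bias
zero_net <- function(net, final_bias = NULL) {
  for (id in names(net$params))
    for (nm in names(net$params[[id]]))
      net$params[[id]][[nm]][] <- 0
  if (!is.null(final_bias)) {
    id <- if (net$kind == "unet") net$final$id else
      net$layers[[length(net$layers)]]$id
    net$params[[id]]$b[] <- final_bias
  }
  net
}

# synthetic EmbedSeg output with embeddings collapsed onto given centers
make_embed_fixture <- function(S, blobs, sigma = 0.05,
                               seed_fg = 0.95, seed_bg = 0.01) {
  # blobs: list of list(center = c(y, x) normalized, pixels = linear idx)
  d <- length(S)
  n <- prod(S)
  coords <- array(im2im:::.norm_coords(S), c(n, d))
  off <- matrix(0, n, d)
  seedv <- rep(seed_bg, n)
  for (b in blobs) {
    for (a in seq_len(d)) off[b$pixels, a] <- b$center[a] - coords[b$pixels, a]
    seedv[b$pixels] <- seed_fg
  }
  offsets <- array(off, c(S, d))
  structure(list(offsets = offsets, sigma = array(sigma, S),
                 seed = array(seedv, S), S = S, d = d),
            class = "embed_output")
}

# brute-force decode oracle: assign candidates to the nearest true center
# with Gaussian affinity > 0.5
oracle_decode <- function(eo, centers, fg_threshold = 0.5) {
  S <- eo$S; d <- eo$d
  n <- prod(S)
  emat <- array(eo$offsets, c(n, d)) + array(im2im:::.norm_coords(S), c(n, d))
  sig <- as.vector(eo$sigma)
  out <- array(0L, S)
  cand <- which(as.vector(eo$seed) > fg_threshold)
  for (i in cand) {
    phis <- vapply(seq_len(nrow(centers)), function(k)
      exp(-sum((emat[i, ] - centers[k, ])^2) / (2 * sig[i]^2)), 0)
    k <- which.max(phis)
    if (phis[k] > 0.5) out[i] <- k
  }
  out
}

# do two integer maps define the same partition of labelled pixels?
same_partition <- function(a, b) {
  sa <- lapply(sort(unique(a[a > 0])), function(l) which(a == l))
  sb <- lapply(sort(unique(b[b > 0])), function(l) which(b == l))
  if (length(sa) != length(sb)) return(FALSE)
  key <- function(s) paste(s, collapse = ",")
  setequal(vapply(sa, key, ""), vapply(sb, key, ""))
}

# naive SSIM oracle: explicit loops over valid 7x7 windows
oracle_ssim <- function(x, y, data_range, win = 7) {
  C1 <- (0.01 * data_range)^2; C2 <- (0.03 * data_range)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    xs <- x[i:(i + win - 1), j:(j + win - 1)]
    ys <- y[i:(i + win - 1), j:(j + win - 1)]
    mx <- mean(xs); my <- mean(ys)
    vx <- stats::var(as.vector(xs)); vy <- stats::var(as.vector(ys))
    cxy <- stats::cov(as.vector(xs), as.vector(ys))
    vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mean(vals)
}

# optimal-assignment AP oracle (exhaustive over <= 5 instances)
oracle_ap <- function(pred, gt, thr = 0.5) {
  iou <- im2im:::.iou_matrix(pred, gt)
  ng <- nrow(iou); np <- ncol(iou)
  if (ng == 0 && np == 0) return(1)
  if (ng == 0 || np == 0) return(0)
  best <- 0
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  k <- min(ng, np)
  for (gs in utils::combn(ng, k, simplify = FALSE))
    for (ps in perms(seq_len(np))) {
      tp <- sum(vapply(seq_len(k), function(i)
        iou[gs[i], ps[i]] >= thr, TRUE))
      best <- max(best, tp)
    }
  best / (best + (np - best) + (ng - best))
}

tiny_fcn_cfg <- function(data_dir, seed = 1, epochs = 1, steps = 10) {
  load_config("train_labelfree_2d", overrides = c(
    paste0("data.data_path=", file.path(data_dir, "manifest.csv")),
    paste0("trainer.seed=", seed),
    paste0("trainer.max_epochs=", epochs),
    paste0("trainer.steps_per_epoch=", steps)))
}
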