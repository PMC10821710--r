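# Embedding-based instance segmentation (EmbedSeg-type): targets are
# prepared on the fly from integer instance maps (no precropping, no
# precalculated center images), the spatial-embedding loss supports
# exclusion masks, and the decoder clusters pixel embeddings around
# high-seed centers so instances may comprise multiple connected
# components and arbitrary (even holed) shapes.
#
# Conventions: pixel coordinates are normalized per axis to (0, 1)
# (coordinate of voxel i along axis a = (i - 0.5) / S_a); the network emits
# d offset channels (raw), one sigma channel (positivity via exp) and one
# seed channel (squashed by a sigmoid).

.norm_coords <- function(S) {
  d <- length(S)
  grids <- lapply(seq_len(d), function(a) (seq_len(S[a]) - 0.5) / S[a])
  out <- array(0, c(S, d))
  for (a in seq_len(d)) {
    rep_each <- prod(S[seq_len(a - 1L)])
    rep_times <- prod(S[-seq_len(a)])
    v <- rep(rep(grids[[a]], each = rep_each), times = rep_times)
    idx <- c(rep(list(quote(expr = )), d), list(a))
    out <- do.call(`[<-`, c(list(out), idx, list(v)))
  }
  out
}

#' Compute per-instance centers from an instance map
#'
#' Centers are expressed in normalized coordinates.  `centroid` is the mean
#' voxel coordinate; `medoid` is the instance voxel minimizing the summed
#' Euclidean distance to all voxels of the instance (always inside the
#' instance, even for non-convex shapes; ties broken by ascending linear
#' voxel index).
#'
#' @param instances integer array, 0 = background, positive labels =
#'   instances (possibly multi-component).
#' @param mode `"medoid"` (default) or `"centroid"`.
#' @return list of class `instance_target`: `labels`, `centers` (matrix,
#'   one row per label, normalized coordinates), `instances`.
#' @export
compute_centers <- function(instances, mode = c("medoid", "centroid")) {
  mode <- match.arg(mode)
  S <- dim(instances)
  labs <- sort(unique(instances[instances > 0]))
  centers <- matrix(0, length(labs), length(S))
  pix <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lin <- which(instances == labs[i])
    pos <- arrayInd(lin, S)
    pix[[i]] <- lin
    nc <- sweep(pos - 0.5, 2, S, `/`)
    if (mode == "centroid") {
      centers[i, ] <- colMeans(nc)
    } else {
      dd <- as.matrix(stats::dist(nc))
      centers[i, ] <- nc[which.min(rowSums(dd)), ]
    }
  }
  structure(list(labels = labs, centers = centers, pixels = pix,
                 shape = S, mode = mode),
            class = "instance_target")
}

#' Initialize the output head of an EmbedSeg backbone
#'
#' Zero-initializes the final convolution and sets the sigma-channel bias
#' so that, at the start of training, embeddings equal pixel coordinates
#' (offsets 0), the clustering bandwidth starts at `sigma0` (normalized
#' units, roughly an object radius) and seediness starts at 0.5.  Without
#' this, random initial offsets put every embedding far from its center and
#' the Gaussian affinity term starts in a vanishing-gradient regime.
#'
#' @param net an `im2im_network` with `d + 2` output channels.
#' @param sigma0 initial clustering bandwidth in normalized coordinates.
#' @return the network with its head re-initialized.
#' @export
embedseg_head_init <- function(net, sigma0 = 0.2) {
  stopifnot(inherits(net, "im2im_network"), net$kind == "unet")
  id <- net$final$id
  d <- net$dim
  net$params[[id]]$W[] <- 0
  b <- numeric(net$out_channels)
  b[d + 1L] <- log(sigma0)
  net$params[[id]]$b <- b
  net
}

.embed_fields <- function(raw) {
  # raw: (1, S..., C) with C = d + 2
  dn <- dim(raw)
  d <- length(dn) - 2L
  S <- dn[1 + seq_len(d)]
  arr <- array(raw, c(S, d + 2L))
  idx <- rep(list(quote(expr = )), d)
  pick <- function(ch) {
    a <- do.call(`[`, c(list(arr), idx, list(ch), list(drop = FALSE)))
    array(a, if (length(ch) > 1L) c(S, length(ch)) else S)
  }
  list(offsets = pick(seq_len(d)),
       sigma_raw = pick(d + 1L),
       seed_raw = pick(d + 2L), S = S, d = d)
}

#' Interpret a raw network output as an EmbedSeg output
#'
#' @param raw channels-last array `(1, S..., d+2)` as produced by a
#'   `d+2`-channel backbone.
#' @return list of class `embed_output`: `offsets` `(S..., d)`, `sigma`
#'   (positive, via exp), `seed` (in `[0,1]`, via sigmoid).
#' @export
embed_output_from_raw <- function(raw) {
  f <- .embed_fields(raw)
  structure(list(offsets = f$offsets, sigma = exp(f$sigma_raw),
                 seed = 1 / (1 + exp(-f$seed_raw)), S = f$S, d = f$d),
            class = "embed_output")
}

# Lovász hinge on scores s with binary labels y: a convex surrogate of the
# Jaccard loss whose minimum puts the s = 0 contour on the mask boundary.
# Returns the loss and its subgradient w.r.t. s (the sorted-permutation
# weights are treated as constant, the standard subgradient).
.lovasz_hinge_grad <- function(s, y) {
  signs <- 2 * y - 1
  errors <- 1 - s * signs
  ord <- order(errors, decreasing = TRUE)
  e_sorted <- errors[ord]
  y_sorted <- y[ord]
  gts <- sum(y_sorted)
  inter <- gts - cumsum(y_sorted)
  union <- gts + cumsum(1 - y_sorted)
  jacc <- 1 - inter / union
  w <- diff(c(0, jacc))
  relu <- pmax(e_sorted, 0)
  loss <- sum(relu * w)
  ds_sorted <- w * (e_sorted > 0) * (-signs[ord])
  ds <- numeric(length(s))
  ds[ord] <- ds_sorted
  list(loss = loss, ds = ds)
}

# windows: per instance, bounding box dilated by `margin` voxels
.instance_window <- function(pos, S, margin) {
  lo <- pmax(apply(pos, 2, min) - margin, 1L)
  hi <- pmin(apply(pos, 2, max) + margin, S)
  lapply(seq_along(S), function(a) lo[a]:hi[a])
}

#' EmbedSeg loss and its gradient w.r.t. the raw network output
#'
#' Per instance k with center C_k: each pixel's embedding is its normalized
#' coordinate plus the predicted offset; the Gaussian
#' `phi = exp(-||e - C_k||^2 / (2 sigma_k^2))` (sigma_k = mean predicted
#' sigma over the instance) is regressed against instance membership over
#' the instance plus nearby background (bounding box dilated by
#' `cfg$margin`).  A sigma-smoothness term penalizes the within-instance
#' variance of sigma, and the seed map is regressed toward `phi` (detached)
#' on foreground and 0 on background.  All terms respect the exclusion
#' mask.
#'
#' @param raw channels-last `(1, S..., d+2)` raw network output.
#' @param target an [compute_centers()] result for the patch.
#' @param cfg embed config: `w_instance`, `w_smooth`, `w_seed`, `margin`.
#' @param exclusion optional binary array (1 = excluded).
#' @return `list(loss, draw)` with `draw` shaped like `raw`.
#' @export
embedseg_loss_grad <- function(raw, target, cfg = list(), exclusion = NULL) {
  w_inst <- cfg$w_instance %||% 1
  w_smooth <- cfg$w_smooth %||% 10
  w_seed <- cfg$w_seed %||% 1
  margin <- cfg$margin %||% 5
  f <- .embed_fields(raw)
  S <- f$S; d <- f$d
  n_sp <- prod(S)
  X <- .norm_coords(S)
  offs <- f$offsets
  e <- X + offs                           # (S..., d)
  emat <- array(e, c(n_sp, d))
  s <- exp(f$sigma_raw)
  seed <- 1 / (1 + exp(-f$seed_raw))
  keep <- if (is.null(exclusion)) rep(TRUE, n_sp) else
    as.vector(exclusion == 0)
  loss <- 0
  d_e <- matrix(0, n_sp, d)
  d_sraw <- numeric(n_sp)
  seed_target <- numeric(n_sp)
  fg <- rep(FALSE, n_sp)
  nk <- length(target$labels)
  for (k in seq_len(nk)) {
    pk <- target$pixels[[k]]
    pk <- pk[keep[pk]]
    if (!length(pk)) next
    fg[pk] <- TRUE
    pos <- arrayInd(pk, S)
    win <- .instance_window(arrayInd(target$pixels[[k]], S), S, margin)
    wlin <- as.vector(do.call(`[<-`, c(
      list(array(FALSE, S)), win, list(TRUE))))
    wlin <- which(wlin & keep)
    y <- as.numeric(wlin %in% pk)
    sig_k <- mean(s[pk])
    diff <- sweep(emat[wlin, , drop = FALSE], 2, target$centers[k, ])
    r2 <- rowSums(diff * diff)
    phi <- exp(-r2 / (2 * sig_k^2))
    # Lovász hinge on 2*phi - 1 against instance membership: calibrates
    # the phi = 0.5 decoding contour to the instance boundary, robust to
    # the strong foreground/background imbalance of microscopy patches
    lh <- .lovasz_hinge_grad(2 * phi - 1, y)
    loss <- loss + w_inst * lh$loss
    dphi <- w_inst * 2 * lh$ds
    # embedding gradient
    d_e[wlin, ] <- d_e[wlin, ] + (dphi * phi / sig_k^2) * (-diff)
    # sigma gradient through sig_k
    dsig <- sum(dphi * phi * r2 / sig_k^3)
    d_sraw[pk] <- d_sraw[pk] + dsig * s[pk] / length(pk)
    # sigma smoothness: population variance of s over the instance
    mu_s <- sig_k
    loss <- loss + w_smooth * mean((s[pk] - mu_s)^2)
    d_sraw[pk] <- d_sraw[pk] +
      w_smooth * 2 * (s[pk] - mu_s) / length(pk) * s[pk]
    # seed regression target on the instance (phi detached)
    phi_on_k <- phi[match(pk, wlin)]
    seed_target[pk] <- phi_on_k
  }
  # seed term over non-excluded pixels; foreground pixels carry an extra
  # weight (default 10) so the sparse foreground regression toward phi is
  # not drowned, while the dense background keeps firm pressure toward 0
  nkeep <- sum(keep)
  if (nkeep == 0) stop("exclusion mask covers the whole patch")
  w_fg <- cfg$fg_seed_weight %||% 10
  wseedv <- numeric(n_sp)
  wseedv[keep] <- 1 / nkeep
  wseedv[fg & keep] <- w_fg / nkeep
  serr <- seed - seed_target
  loss <- loss + w_seed * sum(wseedv * serr^2)
  d_seedraw <- w_seed * 2 * wseedv * serr * seed * (1 - seed)
  draw <- array(0, c(S, d + 2L))
  idx <- rep(list(quote(expr = )), d)
  for (a in seq_len(d))
    draw <- do.call(`[<-`, c(list(draw), idx, list(a), list(d_e[, a])))
  draw <- do.call(`[<-`, c(list(draw), idx, list(d + 1L), list(d_sraw)))
  draw <- do.call(`[<-`, c(list(draw), idx, list(d + 2L),
                           list(as.vector(d_seedraw))))
  dim(draw) <- dim(raw)
  list(loss = loss, draw = draw)
}

#' Decode an EmbedSeg output into an instance map
#'
#' Iterative clustering: candidate pixels are those with seed above
#' `fg_threshold`; while any unassigned candidate's seed exceeds
#' `seed_threshold`, the highest-seed candidate becomes a cluster center
#' (its embedding and sigma), and every unassigned candidate whose Gaussian
#' affinity to the center exceeds 0.5 joins the instance.  Instances
#' smaller than `min_size` voxels are discarded.  Deterministic: ties break
#' by ascending voxel index.
#'
#' @param pred an [embed_output_from_raw()] result.
#' @param cfg list: `fg_threshold` (0.5), `seed_threshold` (0.9),
#'   `min_size` (2).
#' @return integer instance map (array of the prediction's spatial shape).
#' @export
decode_instances <- function(pred, cfg = list()) {
  fg_t <- cfg$fg_threshold %||% 0.5
  seed_t <- cfg$seed_threshold %||% 0.9
  min_size <- cfg$min_size %||% 2L
  S <- pred$S; d <- pred$d
  n_sp <- prod(S)
  out <- array(0L, S)
  seedv <- as.vector(pred$seed)
  cand <- which(seedv > fg_t)
  if (!length(cand)) return(out)
  emat <- array(pred$offsets, c(n_sp, d)) + array(.norm_coords(S), c(n_sp, d))
  sig <- as.vector(pred$sigma)
  assigned <- rep(FALSE, length(cand))
  labels <- integer(length(cand))
  next_lab <- 0L
  repeat {
    un <- which(!assigned)
    if (!length(un)) break
    top <- un[which.max(seedv[cand[un]])]
    if (seedv[cand[top]] <= seed_t) break
    next_lab <- next_lab + 1L
    ctr <- emat[cand[top], ]
    s0 <- sig[cand[top]]
    diff <- sweep(emat[cand[un], , drop = FALSE], 2, ctr)
    phi <- exp(-rowSums(diff * diff) / (2 * s0^2))
    take <- un[phi > 0.5]
    if (!length(take)) take <- top
    assigned[take] <- TRUE
    labels[take] <- next_lab
  }
  keep_labs <- which(tabulate(labels, next_lab) >= min_size)
  relab <- integer(next_lab)
  relab[keep_labs] <- seq_along(keep_labs)
  sel <- labels > 0L
  out[cand[sel]] <- relab[labels[sel]]
  out
}

#' Merge per-window instance maps into one map
#'
#' Windows decoded independently during sliding-window inference are pasted
#' onto the full canvas; a window instance overlapping an existing canvas
#' instance with IoU (computed over the window region) >= `iou_merge` takes
#' that instance's label, otherwise it receives a fresh label.
#'
#' @param windows list of `list(map = integer array, origin = integer
#'   vector)` window decodes.
#' @param shape full spatial shape.
#' @param iou_merge merge threshold, default 0.5.
#' @return integer instance map of `shape`.
#' @export
merge_instance_windows <- function(windows, shape, iou_merge = 0.5) {
  canvas <- array(0L, shape)
  next_lab <- 0L
  d <- length(shape)
  for (w in windows) {
    wm <- w$map
    idx <- lapply(seq_len(d), function(a)
      w$origin[a] + seq_len(dim(wm)[a]) - 1L)
    reg <- do.call(`[`, c(list(canvas), idx, list(drop = FALSE)))
    for (lab in sort(unique(wm[wm > 0]))) {
      sel <- wm == lab
      ex <- reg[sel]
      ex_tab <- table(ex[ex > 0])
      new_lab <- NA_integer_
      if (length(ex_tab)) {
        best <- as.integer(names(ex_tab)[which.max(ex_tab)])
        inter <- max(ex_tab)
        uni <- sum(sel) + sum(reg == best) - inter
        if (inter / uni >= iou_merge) new_lab <- best
      }
      if (is.na(new_lab)) { next_lab <- next_lab + 1L; new_lab <- next_lab }
      reg[sel & reg == 0L] <- new_lab
    }
    canvas <- do.call(`[<-`, c(list(canvas), idx, list(as.vector(reg))))
    next_lab <- max(next_lab, max(canvas))
  }
  canvas
}

#' Average precision at IoU 0.5 for a set of predictions
#' @param pred_maps,gt_maps lists of integer instance maps.
#' @param iou_thresh IoU threshold, default 0.5.
#' @return numeric vector, one AP value per image.
#' @export
embedseg_validate <- function(pred_maps, gt_maps, iou_thresh = 0.5) {
  mapply(function(p, g) average_precision(p, g, iou_thresh),
         pred_maps, gt_maps)
}
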