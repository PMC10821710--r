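# The shared training engine: one loop serving all frameworks, driven
# entirely by the run config.  Builds manifest -> cached dataset -> patch
# sampler -> framework step -> Adam, with per-epoch validation through the
# sliding-window inference path and best/last checkpointing.

# nd_image -> channels-last spatial array (S..., C); C added when absent
.to_train_array <- function(img) {
  if (is.null(img)) return(NULL)
  img <- nd_canonicalize(img)
  axes <- img$axes
  arr <- img$data
  if ("T" %in% axes) stop("training records must not have a T axis")
  if ("C" %in% axes) {
    ci <- match("C", axes)
    arr <- aperm(arr, c(setdiff(seq_along(axes), ci), ci))
  } else {
    arr <- array(arr, c(dim(arr), 1L))
  }
  arr
}

# spatial-only array (collapse a channel axis if present)
.to_spatial_array <- function(img) {
  if (is.null(img)) return(NULL)
  a <- .to_train_array(img)
  d <- length(dim(a)) - 1L
  if (dim(a)[d + 1L] > 1L) {
    dim(a) <- c(prod(dim(a)[seq_len(d)]), dim(a)[d + 1L])
    a <- rowSums(a)
  }
  array(a, dim(.to_train_array(img))[seq_len(d)])
}

.stack_patches <- function(patches, field) {
  items <- lapply(patches, `[[`, field)
  if (is.null(items[[1]])) return(NULL)
  d1 <- dim(items[[1]])
  out <- array(0, c(length(items), d1))
  for (i in seq_along(items)) {
    idx <- c(list(i), rep(list(quote(expr = )), length(d1)))
    out <- do.call(`[<-`, c(list(out), idx, list(as.vector(items[[i]]))))
  }
  out
}

.build_networks <- function(cfg, rng) {
  nw <- cfg$network
  kind <- cfg$framework$kind
  d <- nw$dim
  nets <- list()
  if (kind == "embedseg") {
    nw$out_channels <- d + 2L
    nets$G <- resolve_network(nw, rng = rng)
    if (inherits(nets$G, "im2im_network"))
      nets$G <- embedseg_head_init(nets$G)
  } else if (kind == "cyclegan") {
    nets$G_AB <- resolve_network(nw, rng = rng)
    nw_ba <- nw
    nw_ba$in_channels <- nw$out_channels
    nw_ba$out_channels <- nw$in_channels
    nets$G_BA <- resolve_network(nw_ba, rng = rng)
    nets$D_A <- build_patch_discriminator(dim = d,
                                          in_channels = nw$in_channels,
                                          rng = rng)
    nets$D_B <- build_patch_discriminator(dim = d,
                                          in_channels = nw$out_channels,
                                          rng = rng)
  } else {
    nets$G <- resolve_network(nw, rng = rng)
    if (kind == "pix2pix")
      nets$D <- build_patch_discriminator(
        dim = d, in_channels = nw$in_channels + nw$out_channels, rng = rng)
  }
  gi <- cfg$framework$generator_init
  if (!is.null(gi) && nzchar(gi))
    nets$G <- init_generator_from(nets$G, gi)
  nets
}

# one optimization step for the configured framework; returns loss
.framework_step <- function(kind, nets, opts, batch, cfg, lr) {
  fw <- cfg$framework
  loss <- NA_real_
  if (kind == "fcn") {
    r <- fcn_step(batch, nets$G, fw)
    u <- adam_step(nets$G$params, r$grads, opts$G, lr = lr)
    nets$G$params <- u$params; opts$G <- u$state
    loss <- r$loss
  } else if (kind == "pix2pix") {
    rd <- pix2pix_step(batch, nets$G, nets$D, fw, phase = "disc")
    ud <- adam_step(nets$D$params, rd$grads, opts$D, lr = lr,
                    beta1 = 0.5)
    nets$D$params <- ud$params; opts$D <- ud$state
    rg <- pix2pix_step(batch, nets$G, nets$D, fw, phase = "gen")
    ug <- adam_step(nets$G$params, rg$grads, opts$G, lr = lr, beta1 = 0.5)
    nets$G$params <- ug$params; opts$G <- ug$state
    loss <- rg$loss
  } else if (kind == "cyclegan") {
    rd <- cyclegan_step(batch, nets, fw, phase = "disc")
    for (nm in c("D_A", "D_B")) {
      u <- adam_step(nets[[nm]]$params, rd$grads[[nm]], opts[[nm]],
                     lr = lr, beta1 = 0.5)
      nets[[nm]]$params <- u$params; opts[[nm]] <- u$state
    }
    rg <- cyclegan_step(batch, nets, fw, phase = "gen")
    for (nm in c("G_AB", "G_BA")) {
      u <- adam_step(nets[[nm]]$params, rg$grads[[nm]], opts[[nm]],
                     lr = lr, beta1 = 0.5)
      nets[[nm]]$params <- u$params; opts[[nm]] <- u$state
    }
    loss <- rg$loss
  } else if (kind == "embedseg") {
    r <- embedseg_batch_step(batch, nets$G, fw)
    u <- adam_step(nets$G$params, r$grads, opts$G, lr = lr)
    nets$G$params <- u$params; opts$G <- u$state
    loss <- r$loss
  }
  list(nets = nets, opts = opts, loss = loss)
}

#' One EmbedSeg training step over a batch of patches
#'
#' Targets (instance centers) are computed on the fly per patch after
#' cropping, so they stay consistent with any patch geometry.
#'
#' @param batch list with `source` `(N, S..., C)`, `instances` (list of N
#'   integer patches) and optional `exclusion` (list of N binary patches).
#' @param net backbone emitting `d + 2` channels.
#' @param cfg framework config (its `embed` sub-list).
#' @return `list(loss, grads)`.
#' @export
embedseg_batch_step <- function(batch, net, cfg) {
  fw <- net_forward(net, batch$source, with_cache = TRUE)
  N <- dim(batch$source)[1]
  d <- length(dim(batch$source)) - 2L
  draw <- array(0, dim(fw$y))
  loss <- 0
  ecfg <- cfg$embed %||% list()
  for (n in seq_len(N)) {
    idx <- c(list(n), rep(list(quote(expr = )), d + 1L))
    raw_n <- do.call(`[`, c(list(fw$y), idx, list(drop = FALSE)))
    tgt <- compute_centers(batch$instances[[n]],
                           mode = ecfg$center_mode %||% "medoid")
    ex <- if (!is.null(batch$exclusion)) batch$exclusion[[n]]
    r <- embedseg_loss_grad(raw_n, tgt, ecfg, exclusion = ex)
    loss <- loss + r$loss / N
    draw <- do.call(`[<-`, c(list(draw), idx, list(as.vector(r$draw / N))))
  }
  bw <- net_backward(net, draw, fw$cache)
  list(loss = loss, grads = bw$grads)
}

#' Validate one epoch on the val split
#'
#' Runs full-image sliding-window inference per validation record and
#' computes the framework's metrics: Pearson/SSIM/PSNR for regression
#' frameworks, pixel F1 for semantic targets, AP at IoU 0.5 for EmbedSeg.
#'
#' @param val_records manifest records with `split == "val"`.
#' @param nets trained networks.
#' @param cfg run config.
#' @return a [metric_report()].
#' @export
validate_epoch <- function(val_records, nets, cfg) {
  if (!length(val_records)) stop("validation set is empty")
  kind <- cfg$framework$kind
  det <- split_transforms(cfg$preprocess)$deterministic
  norm <- if (length(det)) det[[1]]
  rows <- list()
  add <- function(id, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(id = id, metric = metric,
                                             value = value)
  for (r in val_records) {
    src <- read_image(r$source)
    gt <- read_image(r$target)
    if (kind == "embedseg") {
      inf <- cfg$inference
      inf$decode <- cfg$framework$embed
      pm <- predict_instances(src, nets$G, inf, norm = norm)
      add(r$id, "ap50", average_precision(pm$data, .to_spatial_array(gt)))
    } else {
      pred <- predict_image(src, nets$G %||% nets$G_AB, cfg$inference,
                            norm = norm)
      gt_arr <- if (gt$dtype_kind == "float" && !is.null(norm))
        .to_train_array(apply_transform(gt, norm)) else .to_train_array(gt)
      pr_arr <- .to_train_array(pred)
      if (gt$dtype_kind %in% c("uint", "int") &&
          length(unique(as.vector(gt_arr))) <= 2) {
        add(r$id, "f1", f1_pixel(pr_arr > 0.5, gt_arr))
      } else {
        rng_v <- max(gt_arr) - min(gt_arr)
        add(r$id, "pearson", pearson(pr_arr, gt_arr))
        d <- length(dim(gt_arr)) - 1L
        g2 <- array(gt_arr, dim(gt_arr)[seq_len(d)])
        p2 <- array(pr_arr[seq_along(g2)], dim(g2))
        add(r$id, "ssim", ssim(p2, g2, data_range = rng_v))
        add(r$id, "psnr", psnr(pr_arr, gt_arr, data_range = rng_v))
      }
    }
  }
  metric_report(do.call(rbind, rows))
}

#' Train a model according to a run configuration
#'
#' The whole pipeline: manifest, cached deterministic transforms, epoch
#' portioning, weighted patch sampling, the configured framework's
#' optimization steps, per-epoch validation and best/last checkpoints with
#' a run record.
#'
#' @param cfg a [load_config()] result.
#' @param out_dir output directory for checkpoints and the run record
#'   (defaults to `cfg$trainer$out_dir` or a temp dir).
#' @param resume_from optional checkpoint to continue from.
#' @param quiet suppress progress output.
#' @return list: `nets`, `history` (per-epoch data frame), `record_path`,
#'   `best_path`, `last_path`.
#' @export
fit_run <- function(cfg, out_dir = NULL, resume_from = NULL, quiet = TRUE) {
  seed <- cfg$trainer$seed
  streams <- seed_everything(seed)
  if (is.null(out_dir))
    out_dir <- if (nzchar(cfg$trainer$out_dir)) cfg$trainer$out_dir else
      file.path(tempdir(), paste0("run_", spec_digest(cfg)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- build_manifest(cfg$data, seed = seed)
  trs <- split_transforms(cfg$preprocess)
  ds <- cached_dataset(manifest, trs$deterministic,
                       cache_dir = if (nzchar(cfg$data$cache_dir))
                         cfg$data$cache_dir else
                         file.path(out_dir, "cache"))
  train_idx <- which(vapply(manifest$records, `[[`, "", "split") == "train")
  val_recs <- manifest_split(manifest, "val")
  loader <- portion_loader(length(train_idx), cfg$data$portion_fraction,
                           cfg$data$reload_every, seed = seed)
  kind <- cfg$framework$kind
  nets <- .build_networks(cfg, streams$init)
  opts <- lapply(nets, function(n) adam_init(n$params))
  epoch0 <- 0L
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from, nets)
    nets <- ck$nets
    if (!is.null(ck$opt_states)) opts <- ck$opt_states
    epoch0 <- ck$epoch
  }
  lr <- cfg$trainer$learning_rate
  hist <- list()
  best <- -Inf
  best_path <- file.path(out_dir, "best.ckpt")
  last_path <- file.path(out_dir, "last.ckpt")
  for (epoch in (epoch0 + 1L):(epoch0 + cfg$trainer$max_epochs)) {
    portion <- loader(epoch)
    ep_loss <- 0
    for (step in seq_len(cfg$trainer$steps_per_epoch)) {
      # each batch slot draws its own record: per-step diversity matters
      # more than per-record patch count on small collections
      nb <- cfg$trainer$batch_size
      d <- length(cfg$sampling$patch_size)
      spec_s <- cfg$sampling
      spec_s$patches_per_image <- 1L
      patches <- vector("list", nb)
      for (j in seq_len(nb)) {
        ri <- train_idx[portion[((step - 1L) * nb + j - 1L) %%
                                  length(portion) + 1L]]
        item <- ds$get(ri)
        pair <- list(source = .to_train_array(item$source),
                     target = if (kind == "embedseg")
                       .to_spatial_array(item$target) else
                       .to_train_array(item$target),
                     exclusion = .to_spatial_array(item$exclusion),
                     weight = .to_spatial_array(item$weight))
        patches[j] <- sample_patches(pair, spec_s, streams$sampler)
      }
      patches <- augment_patches(patches, d, trs$augment, streams$augment)
      batch <- list(source = .stack_patches(patches, "source"))
      if (kind == "embedseg") {
        batch$instances <- lapply(patches, function(p)
          array(as.integer(round(p$target)), dim(p$target)[seq_len(d)]))
        if (!is.null(patches[[1]]$exclusion))
          batch$exclusion <- lapply(patches, `[[`, "exclusion")
      } else if (kind == "cyclegan") {
        opatches <- vector("list", nb)
        for (j in seq_len(nb)) {
          rj <- train_idx[portion[with_rng(streams$sampler,
                                           sample.int(length(portion), 1L))]]
          other <- ds$get(rj)
          opair <- list(source = .to_train_array(other$target))
          opatches[j] <- sample_patches(opair, spec_s, streams$sampler)
        }
        opatches <- augment_patches(opatches, d, trs$augment,
                                    streams$augment)
        batch <- list(a = batch$source,
                      b = .stack_patches(opatches, "source"))
      } else {
        batch$target <- .stack_patches(patches, "target")
        if (!is.null(patches[[1]]$exclusion)) {
          ex <- .stack_patches(patches, "exclusion")
          # broadcast spatial mask across target channels
          ct <- dim(batch$target)[length(dim(batch$target))]
          if (ct > 1) ex <- array(rep(as.vector(ex), ct), dim(batch$target))
          else dim(ex) <- dim(batch$target)
          batch$mask <- ex
        }
      }
      st <- .framework_step(kind, nets, opts, batch, cfg, lr)
      nets <- st$nets; opts <- st$opts
      ep_loss <- ep_loss + st$loss / cfg$trainer$steps_per_epoch
    }
    row <- data.frame(epoch = epoch, loss = ep_loss)
    if (length(val_recs)) {
      vrep <- validate_epoch(val_recs, nets, cfg)
      for (i in seq_len(nrow(vrep$summary)))
        row[[paste0("val_", vrep$summary$metric[i])]] <- vrep$summary$mean[i]
      lead <- vrep$summary$mean[1]
      if (lead > best) {
        best <- lead
        save_checkpoint(best_path, nets, opts, cfg, epoch)
      }
    }
    hist[[length(hist) + 1L]] <- row
    save_checkpoint(last_path, nets, opts, cfg, epoch)
    if (!quiet)
      message(sprintf("epoch %d  loss %.5f", epoch, ep_loss))
  }
  history <- do.call(rbind, lapply(hist, function(h) {
    miss <- setdiff(unique(unlist(lapply(hist, names))), names(h))
    for (m in miss) h[[m]] <- NA_real_
    h
  }))
  record <- list(config_digest = spec_digest(cfg), seed = seed,
                 started = format(Sys.time()),
                 epochs = nrow(history),
                 best_checkpoint = if (file.exists(best_path)) best_path,
                 last_checkpoint = last_path)
  record_path <- file.path(out_dir, "run_record.json")
  jsonlite::write_json(record, record_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  list(nets = nets, history = history, record_path = record_path,
       best_path = if (file.exists(best_path)) best_path else last_path,
       last_path = last_path)
}
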