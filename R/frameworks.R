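# Training-step logic for the image-regression frameworks: FCN (supervised
# pixel regression), pix2pix (FCN + conditional adversarial head) and
# CycleGAN (unpaired bidirectional translation).  Each step returns the
# scalar loss together with parameter gradients for exactly one optimizer's
# parameter set; generator and discriminator parameters are never mixed.

# ---- reconstruction losses -------------------------------------------------

# value and d(value)/d(pred) of the masked mean reconstruction loss
recon_loss_grad <- function(pred, target, mask = NULL, kind = "mae") {
  e <- pred - target
  lm <- switch(kind,
    mae = abs(e),
    mse = e * e,
    smooth_mae = ifelse(abs(e) < 1, 0.5 * e * e, abs(e) - 0.5),
    stop("unknown recon loss ", kind))
  dl <- switch(kind,
    mae = sign(e),
    mse = 2 * e,
    smooth_mae = pmin(pmax(e, -1), 1))
  w <- excl_grad_factor(mask, dim(pred))
  g <- dl * w
  dim(g) <- dim(pred)
  list(loss = apply_exclusion(lm, mask), dpred = g)
}

# adversarial objective on a logit/score map toward label `real`
adv_loss_grad <- function(scores, real = TRUE, objective = "lsgan") {
  n <- length(scores)
  if (objective == "lsgan") {
    t <- if (real) 1 else 0
    list(loss = mean((scores - t)^2), dscores = 2 * (scores - t) / n)
  } else {  # vanilla: binary cross-entropy with logits
    s <- 1 / (1 + exp(-scores))
    if (real) list(loss = -mean(log(pmax(s, 1e-12))),
                   dscores = (s - 1) / n)
    else list(loss = -mean(log(pmax(1 - s, 1e-12))),
              dscores = s / n)
  }
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (id in names(b)) {
    a[[id]] <- if (is.null(a[[id]])) b[[id]] else
      mapply(`+`, a[[id]], b[[id]], SIMPLIFY = FALSE)
  }
  a
}

grads_scale <- function(g, s) {
  if (s == 1) return(g)
  lapply(g, function(p) lapply(p, function(a) a * s))
}

# ---- FCN -------------------------------------------------------------------

#' One FCN training step
#'
#' Supervised pixel regression: masked mean reconstruction loss between
#' `net(source)` and `target`.
#'
#' @param batch list with channels-last arrays `source`, `target` and
#'   optional binary `mask` (1 = excluded).
#' @param net generator network.
#' @param cfg framework config (uses `recon_loss`).
#' @return `list(loss, grads, pred)`.
#' @export
fcn_step <- function(batch, net, cfg) {
  fw <- net_forward(net, batch$source, with_cache = TRUE)
  r <- recon_loss_grad(fw$y, batch$target, batch$mask,
                       cfg$recon_loss %||% "mae")
  bw <- net_backward(net, r$dpred, fw$cache)
  list(loss = r$loss, grads = bw$grads, pred = fw$y)
}

# ---- pix2pix ---------------------------------------------------------------

#' One pix2pix training step (generator or discriminator phase)
#'
#' Generator phase: `recon_weight * masked recon + adv_weight * adv(D(source,
#' G(source)) -> real)`; discriminator phase: `0.5 * [adv(D(source, target)
#' -> real) + adv(D(source, G(source)) -> fake)]` with the generator output
#' detached.  Gradients are returned only for the phase's own network.
#'
#' @param batch list `source`, `target`, optional `mask`.
#' @param G generator, `D` conditional patch discriminator.
#' @param cfg framework config (`recon_weight`, `adv_weight`,
#'   `gan_objective`, `recon_loss`).
#' @param phase `"gen"` or `"disc"`.
#' @return `list(loss, grads, pred)`; `grads` for G in gen phase, for D in
#'   disc phase.
#' @export
pix2pix_step <- function(batch, G, D, cfg, phase = c("gen", "disc")) {
  phase <- match.arg(phase)
  lam_rec <- cfg$recon_weight %||% 100
  lam_adv <- cfg$adv_weight %||% 1
  obj <- cfg$gan_objective %||% "lsgan"
  if (phase == "gen") {
    fw <- net_forward(G, batch$source, with_cache = TRUE)
    r <- recon_loss_grad(fw$y, batch$target, batch$mask,
                         cfg$recon_loss %||% "mae")
    loss <- lam_rec * r$loss
    dyhat <- lam_rec * r$dpred
    if (lam_adv > 0) {
      din <- .concat_ch(batch$source, fw$y)
      dfw <- net_forward(D, din, with_cache = TRUE)
      a <- adv_loss_grad(dfw$y, real = TRUE, objective = obj)
      loss <- loss + lam_adv * a$loss
      ds <- a$dscores; dim(ds) <- dim(dfw$y)
      dbw <- net_backward(D, ds, dfw$cache)  # D grads discarded: not updated
      sp <- .split_ch(dbw$dx, ncol_last(batch$source))
      dyhat <- dyhat + lam_adv * sp[[2]]
    }
    bw <- net_backward(G, dyhat, fw$cache)
    list(loss = loss, grads = bw$grads, pred = fw$y)
  } else {
    yhat <- net_forward(G, batch$source)   # detached: no G cache kept
    fr <- net_forward(D, .concat_ch(batch$source, batch$target),
                      with_cache = TRUE)
    ar <- adv_loss_grad(fr$y, real = TRUE, objective = obj)
    ff <- net_forward(D, .concat_ch(batch$source, yhat), with_cache = TRUE)
    af <- adv_loss_grad(ff$y, real = FALSE, objective = obj)
    dr <- 0.5 * ar$dscores; dim(dr) <- dim(fr$y)
    df <- 0.5 * af$dscores; dim(df) <- dim(ff$y)
    gr <- net_backward(D, dr, fr$cache)$grads
    gf <- net_backward(D, df, ff$cache)$grads
    list(loss = 0.5 * (ar$loss + af$loss), grads = grads_add(gr, gf),
         pred = yhat)
  }
}

# ---- CycleGAN --------------------------------------------------------------

#' One CycleGAN training step (generator or discriminator phase)
#'
#' Generator phase: adversarial terms on both mapping directions plus L1
#' cycle-consistency (`cycle_weight`) and L1 identity (`identity_weight`)
#' terms; discriminator phase: per-domain real/fake objective with detached
#' generator outputs.
#'
#' @param batch list with unpaired arrays `a` (domain A) and `b` (domain B).
#' @param nets list `G_AB`, `G_BA`, `D_A`, `D_B`.
#' @param cfg framework config.
#' @param phase `"gen"` or `"disc"`.
#' @return `list(loss, grads)`; `grads` is `list(G_AB=, G_BA=)` in gen phase
#'   and `list(D_A=, D_B=)` in disc phase.
#' @export
cyclegan_step <- function(batch, nets, cfg, phase = c("gen", "disc")) {
  phase <- match.arg(phase)
  lam_adv <- cfg$adv_weight %||% 1
  lam_cyc <- cfg$cycle_weight %||% 10
  lam_id <- cfg$identity_weight %||% 5
  obj <- cfg$gan_objective %||% "lsgan"
  a <- batch$a; b <- batch$b
  if (phase == "gen") {
    loss <- 0
    gAB <- NULL; gBA <- NULL
    # A -> B -> A
    fab <- net_forward(nets$G_AB, a, with_cache = TRUE)
    dfab <- array(0, dim(fab$y))
    if (lam_adv > 0) {
      sc <- net_forward(nets$D_B, fab$y, with_cache = TRUE)
      ad <- adv_loss_grad(sc$y, real = TRUE, objective = obj)
      loss <- loss + lam_adv * ad$loss
      ds <- ad$dscores; dim(ds) <- dim(sc$y)
      dfab <- dfab + lam_adv * net_backward(nets$D_B, ds, sc$cache)$dx
    }
    if (lam_cyc > 0) {
      rec <- net_forward(nets$G_BA, fab$y, with_cache = TRUE)
      rc <- recon_loss_grad(rec$y, a, NULL, "mae")
      loss <- loss + lam_cyc * rc$loss
      bwc <- net_backward(nets$G_BA, lam_cyc * rc$dpred, rec$cache)
      gBA <- grads_add(gBA, bwc$grads)
      dfab <- dfab + bwc$dx
    }
    gAB <- grads_add(gAB, net_backward(nets$G_AB, dfab, fab$cache)$grads)
    # B -> A -> B
    fba <- net_forward(nets$G_BA, b, with_cache = TRUE)
    dfba <- array(0, dim(fba$y))
    if (lam_adv > 0) {
      sc <- net_forward(nets$D_A, fba$y, with_cache = TRUE)
      ad <- adv_loss_grad(sc$y, real = TRUE, objective = obj)
      loss <- loss + lam_adv * ad$loss
      ds <- ad$dscores; dim(ds) <- dim(sc$y)
      dfba <- dfba + lam_adv * net_backward(nets$D_A, ds, sc$cache)$dx
    }
    if (lam_cyc > 0) {
      rec <- net_forward(nets$G_AB, fba$y, with_cache = TRUE)
      rc <- recon_loss_grad(rec$y, b, NULL, "mae")
      loss <- loss + lam_cyc * rc$loss
      bwc <- net_backward(nets$G_AB, lam_cyc * rc$dpred, rec$cache)
      gAB <- grads_add(gAB, bwc$grads)
      dfba <- dfba + bwc$dx
    }
    gBA <- grads_add(gBA, net_backward(nets$G_BA, dfba, fba$cache)$grads)
    # identity terms
    if (lam_id > 0) {
      idb <- net_forward(nets$G_AB, b, with_cache = TRUE)
      ri <- recon_loss_grad(idb$y, b, NULL, "mae")
      loss <- loss + lam_id * ri$loss
      gAB <- grads_add(gAB,
                       net_backward(nets$G_AB, lam_id * ri$dpred,
                                    idb$cache)$grads)
      ida <- net_forward(nets$G_BA, a, with_cache = TRUE)
      ra <- recon_loss_grad(ida$y, a, NULL, "mae")
      loss <- loss + lam_id * ra$loss
      gBA <- grads_add(gBA,
                       net_backward(nets$G_BA, lam_id * ra$dpred,
                                    ida$cache)$grads)
    }
    list(loss = loss, grads = list(G_AB = gAB, G_BA = gBA))
  } else {
    disc_half <- function(D, real_x, fake_x) {
      fr <- net_forward(D, real_x, with_cache = TRUE)
      ar <- adv_loss_grad(fr$y, real = TRUE, objective = obj)
      ff <- net_forward(D, fake_x, with_cache = TRUE)
      af <- adv_loss_grad(ff$y, real = FALSE, objective = obj)
      dr <- 0.5 * ar$dscores; dim(dr) <- dim(fr$y)
      df <- 0.5 * af$dscores; dim(df) <- dim(ff$y)
      list(loss = 0.5 * (ar$loss + af$loss),
           grads = grads_add(net_backward(D, dr, fr$cache)$grads,
                             net_backward(D, df, ff$cache)$grads))
    }
    fab <- net_forward(nets$G_AB, a)
    fba <- net_forward(nets$G_BA, b)
    hB <- disc_half(nets$D_B, b, fab)
    hA <- disc_half(nets$D_A, a, fba)
    list(loss = hA$loss + hB$loss, grads = list(D_A = hA$grads,
                                                D_B = hB$grads))
  }
}

# ---- checkpoints -----------------------------------------------------------

#' Save a training checkpoint
#' @param path destination `.rds` file.
#' @param nets named list of networks.
#' @param opt_states named list of Adam states (may be NULL).
#' @param cfg run config snapshot.
#' @param epoch epoch counter.
#' @export
save_checkpoint <- function(path, nets, opt_states = NULL, cfg = NULL,
                            epoch = 0L) {
  saveRDS(list(params = lapply(nets, `[[`, "params"),
               opt_states = opt_states, cfg = cfg, epoch = epoch), path)
}

#' Load checkpoint parameters into freshly built networks
#'
#' @param path checkpoint file.
#' @param nets named list of networks with the same architecture.
#' @return `list(nets, opt_states, cfg, epoch)`; parameters are restored
#'   bitwise.
#' @export
load_checkpoint <- function(path, nets) {
  ck <- readRDS(path)
  for (nm in names(nets)) {
    if (!nm %in% names(ck$params)) next
    saved <- ck$params[[nm]]
    # match by position: ids differ across sessions but order is structural
    if (!identical(names(nets[[nm]]$params), names(saved))) {
      stopifnot(length(nets[[nm]]$params) == length(saved))
      names(saved) <- names(nets[[nm]]$params)
      # optimizer moments are keyed by the same ids
      if (!is.null(ck$opt_states[[nm]])) {
        names(ck$opt_states[[nm]]$m) <- names(nets[[nm]]$params)
        names(ck$opt_states[[nm]]$v) <- names(nets[[nm]]$params)
      }
    }
    nets[[nm]]$params <- saved
  }
  list(nets = nets, opt_states = ck$opt_states, cfg = ck$cfg,
       epoch = ck$epoch)
}

#' Initialize a generator from an FCN checkpoint
#'
#' The pix2pix generator can be pre-initialized from a model trained under
#' the FCN framework; before the first optimizer step its outputs equal the
#' FCN model's bitwise.
#'
#' @param G generator network (same architecture as the FCN model).
#' @param path FCN checkpoint path.
#' @return G with restored parameters.
#' @export
init_generator_from <- function(G, path) {
  ck <- readRDS(path)
  saved <- ck$params[["G"]] %||% ck$params[[1]]
  if (!identical(names(G$params), names(saved))) {
    stopifnot(length(G$params) == length(saved))
    names(saved) <- names(G$params)
  }
  G$params <- saved
  G
}
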