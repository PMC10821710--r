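# Minimal dimension-generic neural-network engine.
#
# Tensors are plain R arrays in channels-last layout: (N, S1..Sd, C) with d
# spatial axes (2 or 3).  Convolutions are evaluated as im2col matrix
# products against BLAS; gradients are hand-derived reverse mode.  The
# engine is deliberately small: conv, average-pool, nearest upsample,
# instance/batch normalization, pointwise activations, channel concat —
# enough to express U-Nets and patch discriminators.  Correctness is
# guarded by finite-difference gradient checks in the test suite.

# ---- small tensor helpers --------------------------------------------------

# slice spatial axes of an (N, S..., C) array with a list of index vectors
.slice_sp <- function(x, idx) {
  do.call(`[`, c(list(x), list(TRUE), idx, list(TRUE), drop = FALSE))
}

.slice_sp_add <- function(x, idx, value) {
  cur <- do.call(`[`, c(list(x), list(TRUE), idx, list(TRUE), drop = FALSE))
  do.call(`[<-`, c(list(x), list(TRUE), idx, list(TRUE),
                   list(cur + as.vector(value))))
}

.pad_sp <- function(x, pad) {
  # zero-pad each spatial axis by `pad[a]` on both sides
  d <- length(pad)
  dn <- dim(x)
  if (all(pad == 0)) return(x)
  nd <- dn
  nd[1 + seq_len(d)] <- dn[1 + seq_len(d)] + 2L * pad
  xp <- array(0, nd)
  idx <- lapply(seq_len(d), function(a) pad[a] + seq_len(dn[1 + a]))
  do.call(`[<-`, c(list(xp), list(TRUE), idx, list(TRUE), list(as.vector(x))))
}

.crop_sp <- function(x, pad, target) {
  d <- length(pad)
  if (all(pad == 0)) return(x)
  idx <- lapply(seq_len(d), function(a) pad[a] + seq_len(target[a]))
  do.call(`[`, c(list(x), list(TRUE), idx, list(TRUE), drop = FALSE))
}

# kernel offset grid, column-major (first axis fastest), k per-axis sizes
.offset_grid <- function(k) {
  as.matrix(do.call(expand.grid, lapply(k, function(ki) 0:(ki - 1L))))
}

# ---- layer constructors ----------------------------------------------------

.layer_counter <- local({
  n <- 0L
  function() { n <<- n + 1L; n }
})

.mk_id <- function(prefix) paste0(prefix, "_", .layer_counter())

# Convolution: weights stored as matrix (prod(k)*Cin, Cout); bias length Cout.
nn_conv <- function(in_ch, out_ch, k, dim, stride = 1L, pad = NULL,
                    rng = NULL, gain = 1) {
  k <- rep(as.integer(k), length.out = dim)
  stride <- rep(as.integer(stride), length.out = dim)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  pad <- rep(as.integer(pad), length.out = dim)
  fan_in <- prod(k) * in_ch
  sd <- gain * sqrt(2 / fan_in)
  W <- if (is.null(rng)) matrix(0, fan_in, out_ch) else
    with_rng(rng, matrix(stats::rnorm(fan_in * out_ch, 0, sd), fan_in, out_ch))
  list(id = .mk_id("conv"), type = "conv", dim = dim, in_ch = in_ch,
       out_ch = out_ch, k = k, stride = stride, pad = pad,
       params = list(W = W, b = numeric(out_ch)))
}

nn_norm <- function(kind, ch) {
  if (kind == "none") return(NULL)
  list(id = .mk_id("norm"), type = "norm", kind = kind, ch = ch,
       params = list(g = rep(1, ch), b = numeric(ch)))
}

nn_act <- function(kind) {
  list(id = .mk_id("act"), type = "act", kind = kind, params = list())
}

nn_pool <- function(factors) {
  list(id = .mk_id("pool"), type = "pool", f = as.integer(factors),
       params = list())
}

nn_up <- function(factors) {
  list(id = .mk_id("up"), type = "up", f = as.integer(factors),
       params = list())
}

# ---- primitive forward/backward -------------------------------------------

.conv_fwd <- function(lay, x) {
  d <- lay$dim
  dn <- dim(x)
  N <- dn[1]; S <- dn[1 + seq_len(d)]; Cin <- dn[length(dn)]
  stopifnot(Cin == lay$in_ch)
  xp <- .pad_sp(x, lay$pad)
  So <- (S + 2L * lay$pad - lay$k) %/% lay$stride + 1L
  if (any(So < 1)) stop("conv: input smaller than kernel")
  off <- .offset_grid(lay$k)
  nof <- nrow(off)
  rows <- N * prod(So)
  cols <- matrix(0, rows, nof * Cin)
  idxl <- vector("list", nof)
  for (j in seq_len(nof)) {
    idx <- lapply(seq_len(d), function(a)
      seq.int(off[j, a] + 1L, by = lay$stride[a], length.out = So[a]))
    idxl[[j]] <- idx
    blk <- .slice_sp(xp, idx)
    dim(blk) <- c(rows, Cin)
    cols[, (j - 1L) * Cin + seq_len(Cin)] <- blk
  }
  y <- cols %*% lay$params$W
  y <- y + rep(lay$params$b, each = rows)
  dim(y) <- c(N, So, lay$out_ch)
  list(y = y, cache = list(cols = cols, idxl = idxl, dimxp = dim(xp),
                           S = S, N = N, So = So, Cin = Cin))
}

.conv_bwd <- function(lay, dy, cache) {
  rows <- cache$N * prod(cache$So)
  dY <- dy; dim(dY) <- c(rows, lay$out_ch)
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  dcols <- tcrossprod(dY, lay$params$W)
  dxp <- array(0, cache$dimxp)
  Cin <- cache$Cin
  for (j in seq_along(cache$idxl)) {
    blk <- dcols[, (j - 1L) * Cin + seq_len(Cin), drop = FALSE]
    dxp <- .slice_sp_add(dxp, cache$idxl[[j]], blk)
  }
  dx <- .crop_sp(dxp, lay$pad, cache$S)
  list(dx = dx, grads = list(W = dW, b = db))
}

.pool_fwd <- function(lay, x) {
  f <- lay$f
  d <- length(f)
  dn <- dim(x)
  S <- dn[1 + seq_len(d)]
  if (any(S %% f != 0))
    stop("pool: extent (", paste(S, collapse = "x"),
         ") not divisible by factor (", paste(f, collapse = "x"), ")")
  So <- S %/% f
  off <- .offset_grid(f)
  acc <- NULL
  idxl <- vector("list", nrow(off))
  for (j in seq_len(nrow(off))) {
    idx <- lapply(seq_len(d), function(a)
      seq.int(off[j, a] + 1L, by = f[a], length.out = So[a]))
    idxl[[j]] <- idx
    blk <- .slice_sp(x, idx)
    acc <- if (is.null(acc)) blk else acc + blk
  }
  y <- acc / nrow(off)
  list(y = y, cache = list(idxl = idxl, dimx = dn, nof = nrow(off)))
}

.pool_bwd <- function(lay, dy, cache) {
  dx <- array(0, cache$dimx)
  g <- dy / cache$nof
  for (idx in cache$idxl) dx <- .slice_sp_add(dx, idx, g)
  list(dx = dx, grads = list())
}

.up_fwd <- function(lay, x) {
  f <- lay$f
  d <- length(f)
  dn <- dim(x)
  S <- dn[1 + seq_len(d)]
  So <- S * f
  nd <- dn; nd[1 + seq_len(d)] <- So
  y <- array(0, nd)
  off <- .offset_grid(f)
  idxl <- vector("list", nrow(off))
  for (j in seq_len(nrow(off))) {
    idx <- lapply(seq_len(d), function(a)
      seq.int(off[j, a] + 1L, by = f[a], length.out = S[a]))
    idxl[[j]] <- idx
    y <- do.call(`[<-`, c(list(y), list(TRUE), idx, list(TRUE),
                          list(as.vector(x))))
  }
  list(y = y, cache = list(idxl = idxl, dimx = dn))
}

.up_bwd <- function(lay, dy, cache) {
  dx <- array(0, cache$dimx)
  for (idx in cache$idxl) {
    blk <- .slice_sp(dy, idx)
    dx <- dx + blk
  }
  list(dx = dx, grads = list())
}

# Normalization over groups: instance = per (sample, channel) over spatial;
# batch = per channel over (sample, spatial).  Batch variant always uses the
# current-batch statistics (deterministic; no running-average state).
.norm_fwd <- function(lay, x) {
  dn <- dim(x)
  N <- dn[1]; C <- dn[length(dn)]
  m <- prod(dn[-c(1, length(dn))])
  eps <- 1e-5
  if (lay$kind == "instance") {
    xc <- aperm(array(x, c(N, m, C)), c(2, 1, 3))  # (m, N, C)
    dim(xc) <- c(m, N * C)
    gv <- rep(lay$params$g, each = N)
    bv <- rep(lay$params$b, each = N)
  } else {
    xc <- array(x, c(N * m, C))
    gv <- lay$params$g
    bv <- lay$params$b
  }
  mu <- colMeans(xc)
  xm <- sweep(xc, 2, mu, `-`)
  v <- colMeans(xm * xm)
  isd <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2, isd, `*`)
  yc <- sweep(xhat, 2, gv, `*`)
  yc <- sweep(yc, 2, bv, `+`)
  if (lay$kind == "instance") {
    y <- aperm(array(yc, c(m, N, C)), c(2, 1, 3))
    dim(y) <- dn
  } else {
    y <- yc; dim(y) <- dn
  }
  list(y = y, cache = list(xhat = xhat, isd = isd, gv = gv, N = N, C = C,
                           m = m, dn = dn))
}

.norm_bwd <- function(lay, dy, cache) {
  dn <- cache$dn; N <- cache$N; C <- cache$C; m <- cache$m
  if (lay$kind == "instance") {
    dyc <- aperm(array(dy, c(N, m, C)), c(2, 1, 3))
    dim(dyc) <- c(m, N * C)
    rows <- m
  } else {
    dyc <- array(dy, c(N * m, C))
    rows <- N * m
  }
  xhat <- cache$xhat
  # per-channel parameter grads
  dg_cols <- colSums(dyc * xhat)
  db_cols <- colSums(dyc)
  if (lay$kind == "instance") {
    dg <- colSums(matrix(dg_cols, N, C))
    db <- colSums(matrix(db_cols, N, C))
  } else {
    dg <- dg_cols; db <- db_cols
  }
  dxhat <- sweep(dyc, 2, cache$gv, `*`)
  s1 <- colMeans(dxhat)
  s2 <- colMeans(dxhat * xhat)
  dxc <- sweep(dxhat, 2, s1, `-`) - sweep(xhat, 2, s2, `*`)
  dxc <- sweep(dxc, 2, cache$isd, `*`)
  if (lay$kind == "instance") {
    dx <- aperm(array(dxc, c(m, N, C)), c(2, 1, 3))
    dim(dx) <- dn
  } else {
    dx <- dxc; dim(dx) <- dn
  }
  list(dx = dx, grads = list(g = dg, b = db))
}

.act_fwd <- function(lay, x) {
  y <- switch(lay$kind,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, 0.2 * x),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x)),
    none = x)
  if (lay$kind %in% c("relu", "lrelu")) dim(y) <- dim(x)
  list(y = y, cache = list(x = x, y = y))
}

.act_bwd <- function(lay, dy, cache) {
  dx <- switch(lay$kind,
    relu = dy * (cache$x > 0),
    lrelu = dy * ifelse(cache$x > 0, 1, 0.2),
    tanh = dy * (1 - cache$y^2),
    sigmoid = dy * cache$y * (1 - cache$y),
    none = dy)
  dim(dx) <- dim(dy)
  list(dx = dx, grads = list())
}

layer_forward <- function(lay, params, x) {
  lay$params <- params
  switch(lay$type,
    conv = .conv_fwd(lay, x),
    norm = .norm_fwd(lay, x),
    act = .act_fwd(lay, x),
    pool = .pool_fwd(lay, x),
    up = .up_fwd(lay, x),
    stop("unknown layer type ", lay$type))
}

layer_backward <- function(lay, params, dy, cache) {
  lay$params <- params
  switch(lay$type,
    conv = .conv_bwd(lay, dy, cache),
    norm = .norm_bwd(lay, dy, cache),
    act = .act_bwd(lay, dy, cache),
    pool = .pool_bwd(lay, dy, cache),
    up = .up_bwd(lay, dy, cache),
    stop("unknown layer type ", lay$type))
}

# ---- sequential blocks -----------------------------------------------------

block_forward <- function(layers, params, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], params[[layers[[i]]$id]], x)
    x <- r$y; caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

block_backward <- function(layers, params, dy, caches, grads_env) {
  for (i in rev(seq_along(layers))) {
    lay <- layers[[i]]
    r <- layer_backward(lay, params[[lay$id]], dy, caches[[i]])
    dy <- r$dx
    if (length(r$grads)) {
      g0 <- grads_env$g[[lay$id]]
      grads_env$g[[lay$id]] <- if (is.null(g0)) r$grads else
        mapply(`+`, g0, r$grads, SIMPLIFY = FALSE)
    }
  }
  dy
}

collect_block_params <- function(layers) {
  p <- list()
  for (lay in layers) if (length(lay$params)) p[[lay$id]] <- lay$params
  p
}

# channel concat (last axis); returns combined array
.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-length(da)], db[-length(db)]))
  y <- c(a, b)
  dim(y) <- c(da[-length(da)], da[length(da)] + db[length(db)])
  y
}

.split_ch <- function(dy, ca) {
  dn <- dim(dy)
  n1 <- prod(dn[-length(dn)]) * ca
  a <- dy[seq_len(n1)]
  b <- dy[-seq_len(n1)]
  dim(a) <- c(dn[-length(dn)], ca)
  dim(b) <- c(dn[-length(dn)], dn[length(dn)] - ca)
  list(a, b)
}

# ---- Adam ------------------------------------------------------------------

#' Initialize Adam optimizer state for a parameter set
#' @param params named list (layer id -> named list of arrays), e.g.
#'   `net$params` of an `im2im_network`.
#' @return optimizer state (first/second moment trees and step counter).
#' @export
adam_init <- function(params) {
  zero <- function(p) lapply(p, function(a) a * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

#' One Adam update
#' @param params parameter tree (layer id -> named arrays).
#' @param grads gradient tree with the same structure (may cover a subset
#'   of layers).
#' @param state an [adam_init()] state.
#' @param lr learning rate; `beta1`, `beta2`, `eps` as usual.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @return `list(params, state)` with updated values.
#' @export
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      m <- beta1 * state$m[[id]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[id]][[nm]] + (1 - beta2) * g * g
      state$m[[id]][[nm]] <- m
      state$v[[id]][[nm]] <- v
      params[[id]][[nm]] <- params[[id]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# checksum used by tests to verify parameter isolation between optimizers
params_checksum <- function(params) {
  sum(vapply(params, function(p) sum(vapply(p, sum, 0)), 0))
}
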