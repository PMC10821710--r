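# Built-in backbones: 2D/3D U-Net, anisotropic 3D U-Net and a PatchGAN-style
# discriminator.  All are dimension-generic over the layer engine in nn.R and
# shape-checked with probe tensors at resolution time.
#
# `depth` counts resolution levels; a depth-L U-Net has L-1 down-sampling
# steps.  For 3D nets each down-sampling step has a per-axis factor
# (z, y, x); anisotropic nets keep the Z factor at 1 on early levels so
# volumes with few Z slices still fit through the network.

#' Construct a built-in U-Net backbone
#'
#' @param dim spatial dimensionality, 2 or 3.
#' @param in_channels,out_channels channel counts.
#' @param depth number of resolution levels (`depth = 1` means plain conv
#'   blocks without any pooling).
#' @param base_filters channels at the first level; doubled per level.
#' @param z_factors integer vector of per-step Z down-sampling factors
#'   (length `depth - 1`, 3D only). `1` = down-sample only in YX at that step.
#' @param norm `"instance"`, `"batch"` or `"none"`.
#' @param final_activation `"none"`, `"tanh"` or `"sigmoid"`.
#' @param rng an [rng_stream()] for weight initialization.
#' @return network object of class `im2im_network`.
#' @export
build_unet <- function(dim = 2L, in_channels = 1L, out_channels = 1L,
                       depth = 2L, base_filters = 8L, z_factors = NULL,
                       norm = "instance", final_activation = "none",
                       rng = NULL) {
  stopifnot(dim %in% c(2L, 3L), depth >= 1L)
  if (is.null(rng)) rng <- rng_stream(42L)
  nstep <- depth - 1L
  if (dim == 3L) {
    if (is.null(z_factors) || !length(z_factors))
      z_factors <- rep(2L, nstep)
    z_factors <- rep(as.integer(z_factors), length.out = nstep)
  }
  pool_f <- lapply(seq_len(nstep), function(i)
    if (dim == 2L) c(2L, 2L) else c(z_factors[i], 2L, 2L))
  ch <- pmin(base_filters * 2^(seq_len(depth) - 1L), 512L)

  cblock <- function(cin, cout) {
    layers <- list(nn_conv(cin, cout, 3L, dim, rng = rng),
                   nn_norm(norm, cout), nn_act("relu"),
                   nn_conv(cout, cout, 3L, dim, rng = rng),
                   nn_norm(norm, cout), nn_act("relu"))
    Filter(Negate(is.null), layers)
  }

  enc <- vector("list", depth)
  cin <- in_channels
  for (i in seq_len(depth)) { enc[[i]] <- cblock(cin, ch[i]); cin <- ch[i] }
  pools <- lapply(pool_f, nn_pool)
  ups <- lapply(rev(seq_len(nstep)), function(i) nn_up(pool_f[[i]]))
  upconv <- lapply(rev(seq_len(nstep)), function(i)
    nn_conv(ch[i + 1L], ch[i], 3L, dim, rng = rng))
  dec <- lapply(rev(seq_len(nstep)), function(i) cblock(2L * ch[i], ch[i]))
  final <- nn_conv(ch[1], out_channels, 1L, dim, rng = rng, gain = 0.5)
  fact <- nn_act(final_activation)

  all_layers <- c(unlist(enc, recursive = FALSE), pools,
                  ups, upconv, unlist(dec, recursive = FALSE),
                  list(final, fact))
  params <- collect_block_params(all_layers)

  total_down <- rep(1L, dim)
  for (f in pool_f) total_down <- total_down * f

  structure(list(kind = "unet", dim = dim, depth = depth,
                 in_channels = in_channels, out_channels = out_channels,
                 enc = enc, pools = pools, ups = ups, upconv = upconv,
                 dec = dec, final = final, fact = fact,
                 pool_f = pool_f, down_factors = total_down,
                 params = params),
            class = "im2im_network")
}

#' Construct a PatchGAN-style discriminator
#'
#' Stride-2 convolution blocks followed by a 1-channel scoring convolution;
#' the output is a spatial grid of patch logits, not a single scalar.
#'
#' @param dim spatial dimensionality.
#' @param in_channels input channels (source + candidate concatenated for
#'   conditional use).
#' @param base_filters channels of the first block.
#' @param n_blocks number of stride-2 blocks (default 3).
#' @param norm normalization of inner blocks, default `"batch"`.
#' @param rng an [rng_stream()].
#' @return network object of class `im2im_network`.
#' @export
build_patch_discriminator <- function(dim = 2L, in_channels = 2L,
                                      base_filters = 16L, n_blocks = 3L,
                                      norm = "batch", rng = NULL) {
  if (is.null(rng)) rng <- rng_stream(42L)
  layers <- list()
  cin <- in_channels
  for (i in seq_len(n_blocks)) {
    cout <- base_filters * 2^(i - 1L)
    layers <- c(layers, list(nn_conv(cin, cout, 4L, dim, stride = 2L,
                                     pad = 1L, rng = rng)))
    if (i > 1L) layers <- c(layers, list(nn_norm(norm, cout)))
    layers <- c(layers, list(nn_act("lrelu")))
    cin <- cout
  }
  layers <- c(layers, list(nn_conv(cin, 1L, 3L, dim, rng = rng)))
  layers <- Filter(Negate(is.null), layers)
  structure(list(kind = "convnet", dim = dim, in_channels = in_channels,
                 out_channels = 1L, layers = layers,
                 down_factors = rep(2L^n_blocks, dim),
                 params = collect_block_params(layers)),
            class = "im2im_network")
}

#' Construct a parameter-free identity (or constant-shift) network
#'
#' Maps `x` to `x + shift`.  Useful as a reference model: sliding-window
#' inference through an identity network must reproduce its (normalized)
#' input, and CycleGAN generators at the identity have zero cycle and
#' identity losses.
#'
#' @param dim spatial dimensionality.
#' @param shift constant added to the input (default 0).
#' @param channels channel count (in = out).
#' @return network object of class `im2im_network`.
#' @export
build_identity_network <- function(dim = 2L, shift = 0, channels = 1L) {
  structure(list(kind = "identity", dim = dim, shift = shift,
                 in_channels = channels, out_channels = channels,
                 down_factors = rep(1L, dim), params = list()),
            class = "im2im_network")
}

#' Per-axis total down-sampling factor of a network
#' @param net an `im2im_network`.
#' @return integer vector, one entry per spatial axis (Z,Y,X order for 3D).
#' @export
net_down_factors <- function(net) net$down_factors

# ---- forward / backward ----------------------------------------------------

#' Forward pass through a built-in network
#'
#' @param net an `im2im_network`.
#' @param x array `(N, S..., C)` in channels-last layout; spatial extents
#'   must be divisible by [net_down_factors()].
#' @param with_cache keep layer caches for a subsequent [net_backward()].
#' @return if `with_cache`, `list(y, cache)`; else the output array.
#' @export
net_forward <- function(net, x, with_cache = FALSE) {
  dn <- dim(x)
  d <- net$dim
  if (length(dn) != d + 2L)
    stop("expected a (N, ", paste(rep("S", d), collapse = ","),
         ", C) array, got rank ", length(dn))
  if (dn[length(dn)] != net$in_channels)
    stop("shape-contract error: expected ", net$in_channels,
         " input channels, got ", dn[length(dn)])
  S <- dn[1 + seq_len(d)]
  f <- net$down_factors
  bad <- which(S %% f != 0)
  if (length(bad))
    stop("shape-contract error: spatial axis ", bad[1], " extent ", S[bad[1]],
         " not divisible by down factor ", f[bad[1]])
  if (net$kind == "identity") {
    y <- x + net$shift
    if (with_cache) return(list(y = y, cache = list()))
    return(y)
  }
  if (net$kind == "convnet") {
    r <- block_forward(net$layers, net$params, x)
    if (with_cache) return(list(y = r$y, cache = r))
    return(r$y)
  }
  # unet
  p <- net$params
  skips <- list(); caches <- list()
  h <- x
  depth <- net$depth
  for (i in seq_len(depth)) {
    r <- block_forward(net$enc[[i]], p, h)
    caches[[paste0("enc", i)]] <- r$caches
    h <- r$y
    if (i < depth) {
      skips[[i]] <- h
      rp <- layer_forward(net$pools[[i]], list(), h)
      caches[[paste0("pool", i)]] <- rp$cache
      h <- rp$y
    }
  }
  nstep <- depth - 1L
  for (j in seq_len(nstep)) {
    i <- depth - j                       # level we are decoding back to
    ru <- layer_forward(net$ups[[j]], list(), h)
    caches[[paste0("up", j)]] <- ru$cache
    rc <- layer_forward(net$upconv[[j]], p[[net$upconv[[j]]$id]], ru$y)
    caches[[paste0("upconv", j)]] <- rc$cache
    h <- .concat_ch(rc$y, skips[[i]])
    rd <- block_forward(net$dec[[j]], p, h)
    caches[[paste0("dec", j)]] <- rd$caches
    h <- rd$y
  }
  rf <- layer_forward(net$final, p[[net$final$id]], h)
  caches[["final"]] <- rf$cache
  ra <- layer_forward(net$fact, list(), rf$y)
  caches[["fact"]] <- ra$cache
  if (with_cache) list(y = ra$y, cache = caches) else ra$y
}

#' Backward pass: gradients of a scalar loss w.r.t. parameters and input
#'
#' @param net an `im2im_network`.
#' @param dy gradient of the loss w.r.t. the network output.
#' @param cache the cache returned by `net_forward(..., with_cache = TRUE)`.
#' @return `list(dx, grads)`; `grads` is a named list parallel to
#'   `net$params`.
#' @export
net_backward <- function(net, dy, cache) {
  p <- net$params
  ge <- new.env(); ge$g <- list()
  if (net$kind == "identity")
    return(list(dx = dy, grads = list()))
  if (net$kind == "convnet") {
    dx <- block_backward(net$layers, p, dy, cache$caches, ge)
    return(list(dx = dx, grads = ge$g))
  }
  ra <- layer_backward(net$fact, list(), dy, cache[["fact"]])
  rf <- layer_backward(net$final, p[[net$final$id]], ra$dx, cache[["final"]])
  ge$g[[net$final$id]] <- rf$grads
  dh <- rf$dx
  depth <- net$depth
  nstep <- depth - 1L
  dskips <- vector("list", nstep)
  for (j in rev(seq_len(nstep))) {
    i <- depth - j
    dh <- block_backward(net$dec[[j]], p, dh, cache[[paste0("dec", j)]], ge)
    sp <- .split_ch(dh, ncol_last(dh) %/% 2L)
    dup_in <- sp[[1]]
    dskips[[i]] <- sp[[2]]
    rc <- layer_backward(net$upconv[[j]], p[[net$upconv[[j]]$id]], dup_in,
                         cache[[paste0("upconv", j)]])
    g0 <- ge$g[[net$upconv[[j]]$id]]
    ge$g[[net$upconv[[j]]$id]] <- if (is.null(g0)) rc$grads else
      mapply(`+`, g0, rc$grads, SIMPLIFY = FALSE)
    ru <- layer_backward(net$ups[[j]], list(), rc$dx, cache[[paste0("up", j)]])
    dh <- ru$dx
  }
  for (i in rev(seq_len(depth))) {
    if (i < depth) {
      rp <- layer_backward(net$pools[[i]], list(), dh,
                           cache[[paste0("pool", i)]])
      dh <- rp$dx + dskips[[i]]
    }
    dh <- block_backward(net$enc[[i]], p, dh, cache[[paste0("enc", i)]], ge)
  }
  list(dx = dh, grads = ge$g)
}

ncol_last <- function(x) dim(x)[length(dim(x))]

#' Number of trainable parameters
#' @param net an `im2im_network`.
#' @return integer count.
#' @export
net_n_params <- function(net)
  sum(vapply(net$params, function(p) sum(vapply(p, length, 0L)), 0L))

# ---- resolution ------------------------------------------------------------

#' Resolve a network specification to an instantiated network
#'
#' Built-in names (`unet_2d`, `unet_3d`, `unet_aniso_3d`,
#' `patch_discriminator`) are constructed directly; any other name is
#' treated as a dotted import path `pkg::symbol` (or a bare function name on
#' the search path) and called with `spec$kwargs`.  The instantiated network
#' is probed with a zero tensor of the declared shape; a mismatch raises a
#' shape-contract error reporting expected vs actual channels.
#'
#' @param spec network section of a run config (named list).
#' @param rng optional [rng_stream()] for weight initialization.
#' @param probe run the probe-tensor shape check (default TRUE).
#' @return an `im2im_network` or the object returned by the imported factory.
#' @export
resolve_network <- function(spec, rng = NULL, probe = TRUE) {
  nm <- spec$name
  builtin <- c("unet_2d", "unet_3d", "unet_aniso_3d", "patch_discriminator")
  if (nm %in% builtin) {
    dim <- if (nm == "unet_2d") 2L else 3L
    if (!is.null(spec$dim)) dim <- as.integer(spec$dim)
    if (nm == "patch_discriminator") {
      net <- build_patch_discriminator(dim = dim,
                                       in_channels = spec$in_channels %||% 2L,
                                       base_filters = spec$base_filters %||% 16L,
                                       norm = spec$norm %||% "batch",
                                       rng = rng)
    } else {
      zf <- spec$z_factors
      if (nm == "unet_aniso_3d" && (is.null(zf) || !length(zf)))
        zf <- rep(1L, max(spec$depth %||% 2L - 1L, 0L))
      if (nm == "unet_2d") zf <- NULL
      net <- build_unet(dim = if (nm == "unet_2d") 2L else 3L,
                        in_channels = spec$in_channels %||% 1L,
                        out_channels = spec$out_channels %||% 1L,
                        depth = spec$depth %||% 2L,
                        base_filters = spec$base_filters %||% 8L,
                        z_factors = zf,
                        norm = spec$norm %||% "instance",
                        final_activation = spec$final_activation %||% "none",
                        rng = rng)
    }
  } else {
    fn <- if (grepl("::", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "::", fixed = TRUE)[[1]]
      tryCatch(getExportedValue(parts[1], parts[2]),
               error = function(e) stop("cannot resolve network path '", nm,
                                        "': ", conditionMessage(e),
                                        call. = FALSE))
    } else {
      if (!exists(nm, mode = "function"))
        stop("cannot resolve network path '", nm, "'", call. = FALSE)
      get(nm, mode = "function")
    }
    net <- do.call(fn, spec$kwargs %||% list())
  }
  if (probe) .probe_network(net, spec)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.probe_network <- function(net, spec) {
  d <- if (inherits(net, "im2im_network")) net$dim else spec$dim %||% 2L
  f <- if (inherits(net, "im2im_network")) net_down_factors(net) else
    rep(1L, d)
  S <- pmax(f, 8L)
  S <- S + (f - S %% f) %% f
  cin <- spec$in_channels %||%
    (if (inherits(net, "im2im_network")) net$in_channels else 1L)
  x <- array(0, c(1L, S, cin))
  y <- tryCatch(net_predict(net, x),
                error = function(e) stop("shape-contract error probing ",
                                         "network: ", conditionMessage(e),
                                         call. = FALSE))
  cout <- dim(y)[length(dim(y))]
  want <- spec$out_channels
  if (!is.null(want) && !identical(as.integer(cout), as.integer(want)))
    stop("shape-contract error: network emits ", cout,
         " channels, config declares out_channels=", want, call. = FALSE)
  invisible(net)
}

#' Apply a network (or plain function) to a batch tensor
#'
#' @param net an `im2im_network` or a function `array -> array`.
#' @param x channels-last batch array.
#' @return output array.
#' @export
net_predict <- function(net, x) {
  if (inherits(net, "im2im_network")) net_forward(net, x) else net(x)
}
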