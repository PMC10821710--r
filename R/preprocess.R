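# Intensity normalization for microscopy images and Reinhard-style stain
# normalization for RGB histology tiles.
#
# All intensity normalizations operate per channel over the whole image (the
# per-image convention of the label-free literature).  Standard deviations
# are population standard deviations throughout, so that the Z-center
# variant at fraction 1 coincides with standard normalization exactly.
# Normalization statistics are attached to the result as the
# `"norm_stats"` attribute so inference can invert the transform exactly.

.per_channel <- function(img, fn) {
  ci <- match("C", img$axes)
  if (is.na(ci)) {
    out <- fn(img$data, NULL)
  } else {
    out <- img$data
    stats <- vector("list", dim(img$data)[ci])
    idx <- rep(list(quote(expr = )), length(img$axes))
    for (c in seq_len(dim(img$data)[ci])) {
      idx[[ci]] <- c
      ch <- do.call(`[`, c(list(img$data), idx, list(drop = FALSE)))
      r <- fn(ch, c)
      out <- do.call(`[<-`, c(list(out), idx, list(as.vector(r))))
    }
  }
  res <- nd_image(out, img$axes, voxel_size = img$voxel_size,
                  dtype_kind = "float")
  res
}

.collect_stats <- function() {
  e <- new.env(); e$s <- list(); e
}

#' Percentile intensity normalization
#'
#' Clips voxel intensities to the `[lo, hi]` percentile range (computed per
#' channel over all voxels, linear interpolation between order statistics)
#' and rescales affinely so the low percentile maps to `out_range[1]` and
#' the high percentile to `out_range[2]` (default `[-1, 1]`).
#'
#' @param img an [nd_image()].
#' @param lo,hi percentiles in `[0, 100]`, `lo < hi`.
#' @param out_range numeric length-2, target range `(a, b)` with `a < b`.
#' @return float `nd_image`; normalization statistics in attribute
#'   `"norm_stats"`.
#' @export
percentile_normalize <- function(img, lo = 0.5, hi = 99.5,
                                 out_range = c(-1, 1)) {
  stopifnot(lo < hi, out_range[1] < out_range[2])
  st <- .collect_stats()
  out <- .per_channel(img, function(ch, c) {
    p <- stats::quantile(ch, probs = c(lo, hi) / 100, names = FALSE, type = 7)
    if (p[1] == p[2])
      stop("degenerate-intensity error: percentile range collapsed ",
           "(constant image?)")
    x <- pmin(pmax(ch, p[1]), p[2])
    st$s[[length(st$s) + 1L]] <- list(p_lo = p[1], p_hi = p[2])
    (x - p[1]) / (p[2] - p[1]) * diff(out_range) + out_range[1]
  })
  attr(out, "norm_stats") <- list(method = "percentile",
                                  out_range = out_range, per_channel = st$s)
  out
}

#' Standard (z-score) normalization
#'
#' Subtracts the mean and divides by the population standard deviation of
#' all voxel intensities, per channel.
#'
#' @param img an [nd_image()].
#' @return float `nd_image` with mean 0 and population sd 1 per channel.
#' @export
standard_normalize <- function(img) {
  st <- .collect_stats()
  out <- .per_channel(img, function(ch, c) {
    mu <- mean(ch)
    sg <- sqrt(mean((ch - mu)^2))
    if (sg == 0) stop("degenerate-intensity error: zero standard deviation")
    st$s[[length(st$s) + 1L]] <- list(mu = mu, sigma = sg)
    (ch - mu) / sg
  })
  attr(out, "norm_stats") <- list(method = "standard", per_channel = st$s)
  out
}

#' Z-center normalization
#'
#' Z-scores the whole volume using statistics computed only on a chunk of
#' `ceiling(center_fraction * Z)` planes centred on the middle of the Z
#' axis.  Useful for 3D stacks whose out-of-focus top/bottom planes would
#' otherwise dominate the statistics.
#'
#' @param img an [nd_image()] with a Z axis of extent >= 2.
#' @param center_fraction fraction of planes in `(0, 1]`; 1 recovers
#'   [standard_normalize()].
#' @return float `nd_image`.
#' @export
center_normalize <- function(img, center_fraction = 0.5) {
  zi <- match("Z", img$axes)
  if (is.na(zi)) stop("center_normalize requires a Z axis")
  Z <- dim(img$data)[zi]
  if (Z < 2) stop("center_normalize requires Z extent >= 2")
  stopifnot(center_fraction > 0, center_fraction <= 1)
  m <- ceiling(center_fraction * Z)
  z0 <- floor((Z - m) / 2)
  planes <- z0 + seq_len(m)
  st <- .collect_stats()
  out <- .per_channel(img, function(ch, c) {
    # ch keeps the full axis layout of img (channel extent sliced to 1)
    idx <- rep(list(quote(expr = )), length(img$axes))
    idx[[zi]] <- planes
    chunk <- do.call(`[`, c(list(ch), idx, list(drop = FALSE)))
    mu <- mean(chunk)
    sg <- sqrt(mean((chunk - mu)^2))
    if (sg == 0)
      stop("degenerate-intensity error: center chunk has zero sd")
    st$s[[length(st$s) + 1L]] <- list(mu = mu, sigma = sg)
    (ch - mu) / sg
  })
  attr(out, "norm_stats") <- list(method = "center",
                                  center_fraction = center_fraction,
                                  per_channel = st$s)
  out
}

#' Min-max normalization
#' @param img an [nd_image()].
#' @param out_range target range, default `[-1, 1]`.
#' @return float `nd_image`.
#' @export
minmax_normalize <- function(img, out_range = c(-1, 1)) {
  st <- .collect_stats()
  out <- .per_channel(img, function(ch, c) {
    r <- range(ch)
    if (r[1] == r[2]) stop("degenerate-intensity error: constant image")
    st$s[[length(st$s) + 1L]] <- list(p_lo = r[1], p_hi = r[2])
    (ch - r[1]) / (r[2] - r[1]) * diff(out_range) + out_range[1]
  })
  attr(out, "norm_stats") <- list(method = "minmax",
                                  out_range = out_range, per_channel = st$s)
  out
}

#' Apply a named normalization from a transform spec entry
#' @param img an [nd_image()].
#' @param spec transform entry: `list(name = ..., params...)`.
#' @return transformed `nd_image`.
#' @export
apply_transform <- function(img, spec) {
  switch(spec$name,
    percentile_normalize = percentile_normalize(
      img, lo = spec$lo %||% 0.5, hi = spec$hi %||% 99.5,
      out_range = c(spec$out_lo %||% -1, spec$out_hi %||% 1)),
    standard_normalize = standard_normalize(img),
    center_normalize = center_normalize(
      img, center_fraction = spec$center_fraction %||% 0.5),
    minmax_normalize = minmax_normalize(
      img, out_range = c(spec$out_lo %||% -1, spec$out_hi %||% 1)),
    stain_normalize = {
      ref <- spec$reference
      if (is.null(ref)) stop("stain_normalize needs a fitted 'reference'")
      apply_stain_norm(img, ref)
    },
    none = img,
    stop("unknown transform: ", spec$name))
}

#' Invert an affine normalization using its cached statistics
#'
#' Percentile/minmax normalizations invert through their affine map;
#' standard/center invert through the cached mean and sd.
#'
#' @param img normalized `nd_image` (or plain array).
#' @param stats the `"norm_stats"` attribute captured at normalization time.
#' @return de-normalized `nd_image` or array.
#' @export
un_normalize <- function(img, stats) {
  arr <- if (inherits(img, "nd_image")) img$data else img
  axes <- if (inherits(img, "nd_image")) img$axes else NULL
  inv1 <- function(x, s) {
    if (stats$method %in% c("percentile", "minmax")) {
      a <- stats$out_range[1]; b <- stats$out_range[2]
      (x - a) / (b - a) * (s$p_hi - s$p_lo) + s$p_lo
    } else {
      x * s$sigma + s$mu
    }
  }
  if (length(stats$per_channel) <= 1L || is.null(axes) ||
      !("C" %in% axes)) {
    out <- inv1(arr, stats$per_channel[[1]])
  } else {
    ci <- match("C", axes)
    out <- arr
    idx <- rep(list(quote(expr = )), length(axes))
    for (c in seq_along(stats$per_channel)) {
      idx[[ci]] <- c
      ch <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), idx,
                              list(as.vector(inv1(ch,
                                   stats$per_channel[[c]])))))
    }
  }
  if (inherits(img, "nd_image"))
    nd_image(out, img$axes, voxel_size = img$voxel_size,
             dtype_kind = img$dtype_kind)
  else out
}

# ---- stain normalization ---------------------------------------------------

# Ruderman l-alpha-beta opponent colour space (the space of the classic
# Reinhard statistics-transfer method).
.rgb2lab_ruderman <- function(rgb) {  # rgb: n x 3 in [0,1]
  M1 <- matrix(c(0.3811, 0.5783, 0.0402,
                 0.1967, 0.7244, 0.0782,
                 0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
  lms <- rgb %*% t(M1)
  lms <- log10(pmax(lms, 1e-6))
  M2 <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
    matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
  lms %*% t(M2)
}

.lab2rgb_ruderman <- function(lab) {
  M2i <- solve(diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
               matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE))
  lms <- 10^(lab %*% t(M2i))
  M1i <- solve(matrix(c(0.3811, 0.5783, 0.0402,
                        0.1967, 0.7244, 0.0782,
                        0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE))
  pmin(pmax(lms %*% t(M1i), 0), 1)
}

.tile_to_mat <- function(img) {
  ci <- match("C", img$axes)
  if (is.na(ci) || dim(img$data)[ci] != 3)
    stop("stain normalization expects a 3-channel RGB tile")
  scale <- if (max(img$data) > 1.5) 255 else 1
  arr <- img$data / scale
  perm <- c(setdiff(seq_along(img$axes), ci), ci)
  m <- aperm(arr, perm)
  dim(m) <- c(length(arr) / 3, 3)
  list(m = m, scale = scale, perm = perm, dims = dim(arr)[perm])
}

.mat_to_tile <- function(m, info, img) {
  arr <- array(m, info$dims)
  arr <- aperm(arr, order(info$perm)) * info$scale
  nd_image(arr, img$axes, voxel_size = img$voxel_size,
           dtype_kind = img$dtype_kind)
}

#' Fit a stain-normalization reference from an RGB tile
#'
#' Captures per-channel location and scale in the Ruderman l-alpha-beta
#' opponent colour space (classic Reinhard statistics transfer).
#'
#' @param ref_tile 3-channel RGB [nd_image()] with values in `[0,1]` or
#'   `[0,255]`.
#' @return object of class `stain_reference`: `mu` and `sigma`, 3 numbers
#'   each.
#' @export
fit_stain_reference <- function(ref_tile) {
  info <- .tile_to_mat(ref_tile)
  lab <- .rgb2lab_ruderman(info$m)
  mu <- colMeans(lab)
  sg <- sqrt(colMeans(sweep(lab, 2, mu)^2))
  sg <- pmax(sg, 1e-8)
  structure(list(mu = mu, sigma = sg), class = "stain_reference")
}

#' Map a tile's colour distribution onto a stain reference
#'
#' @param tile 3-channel RGB [nd_image()].
#' @param ref a [fit_stain_reference()] result.
#' @return RGB `nd_image` in the same value range as the input, clipped to
#'   the valid range.
#' @export
apply_stain_norm <- function(tile, ref) {
  stopifnot(inherits(ref, "stain_reference"))
  info <- .tile_to_mat(tile)
  lab <- .rgb2lab_ruderman(info$m)
  mu <- colMeans(lab)
  sg <- pmax(sqrt(colMeans(sweep(lab, 2, mu)^2)), 1e-8)
  lab <- sweep(lab, 2, mu)
  lab <- sweep(lab, 2, ref$sigma / sg, `*`)
  lab <- sweep(lab, 2, ref$mu, `+`)
  .mat_to_tile(.lab2rgb_ruderman(lab), info, tile)
}

# ---- padding ---------------------------------------------------------------

#' Pad spatial extents up to the network's down-sampling multiple
#'
#' Pads each spatial axis (reflect, edge included) at the high end up to the
#' nearest multiple of the per-axis total down factor.  The returned crop
#' record inverts the padding exactly.
#'
#' @param img an [nd_image()] or plain spatial array.
#' @param factors per-spatial-axis integer factors (e.g.
#'   [net_down_factors()]).
#' @return `list(img, crop)`; `crop` holds the original extents.
#' @export
pad_to_valid <- function(img, factors) {
  arr <- if (inherits(img, "nd_image")) img$data else img
  axes <- if (inherits(img, "nd_image")) img$axes else NULL
  sp_idx <- if (is.null(axes)) seq_along(dim(arr)) else
    match(intersect(axes, c("Z", "Y", "X")), axes)
  factors <- rep(as.integer(factors), length.out = length(sp_idx))
  dn <- dim(arr)
  orig <- dn[sp_idx]
  pad <- (factors - orig %% factors) %% factors
  if (any(pad > orig))
    stop("image too small to reflect-pad to factor ",
         paste(factors, collapse = "x"))
  if (any(pad > 0)) {
    for (a in seq_along(sp_idx)) {
      if (pad[a] == 0) next
      ax <- sp_idx[a]
      n <- dim(arr)[ax]
      idx <- rep(list(quote(expr = )), length(dim(arr)))
      idx[[ax]] <- n:(n - pad[a] + 1L)          # mirrored tail, edge included
      tail <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
      nd <- dim(arr); nd[ax] <- n + pad[a]
      out <- array(0, nd)
      idx[[ax]] <- seq_len(n)
      out <- do.call(`[<-`, c(list(out), idx, list(as.vector(arr))))
      idx[[ax]] <- n + seq_len(pad[a])
      out <- do.call(`[<-`, c(list(out), idx, list(as.vector(tail))))
      arr <- out
    }
  }
  res <- if (inherits(img, "nd_image"))
    nd_image(arr, axes, voxel_size = img$voxel_size,
             dtype_kind = img$dtype_kind) else arr
  list(img = res, crop = list(sp_idx = sp_idx, orig = orig))
}

#' Invert [pad_to_valid()]
#' @param img padded `nd_image` or array.
#' @param crop the crop record returned by [pad_to_valid()].
#' @return image cropped back to the original extents.
#' @export
crop_from_pad <- function(img, crop) {
  arr <- if (inherits(img, "nd_image")) img$data else img
  idx <- rep(list(quote(expr = )), length(dim(arr)))
  for (a in seq_along(crop$sp_idx))
    idx[[crop$sp_idx[a]]] <- seq_len(crop$orig[a])
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  if (inherits(img, "nd_image"))
    nd_image(out, img$axes, voxel_size = img$voxel_size,
             dtype_kind = img$dtype_kind) else out
}
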