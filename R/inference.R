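# Full-image prediction for up-to-5D inputs: per-timepoint iteration,
# sliding-window tiling with Gaussian-weighted blending, inversion of the
# training normalization and padding.

#' Gaussian blending weights for a window
#'
#' Separable Gaussian centred on the window, sigma per axis =
#' `sigma_scale * size`, normalized so the centre weight is 1 and floored
#' at 1e-6 so every voxel keeps strictly positive coverage.
#'
#' @param window_size integer vector of per-axis window extents.
#' @param sigma_scale sigma as a fraction of the window size (default
#'   0.125).
#' @return array of weights with dim `window_size`.
#' @export
gaussian_window_weights <- function(window_size, sigma_scale = 0.125) {
  stopifnot(sigma_scale > 0)
  axes <- lapply(window_size, function(n) {
    c0 <- (n + 1) / 2
    s <- sigma_scale * n
    exp(-0.5 * ((seq_len(n) - c0) / s)^2)
  })
  w <- Reduce(function(acc, v) outer(acc, v), axes)
  dim(w) <- as.integer(window_size)
  w <- w / max(w)
  pmax(w, 1e-6)
}

#' Combine weighted prediction and weight accumulators
#'
#' @param accumulator sum of `weight * prediction` over windows.
#' @param weight_accumulator sum of weights; must be positive everywhere.
#' @param output_dtype `"float"`, `"uint"` (clipped to `[0, 65535]`) or
#'   `"int"`.
#' @return voxelwise quotient, cast per `output_dtype`.
#' @export
stitch <- function(accumulator, weight_accumulator, output_dtype = "float") {
  if (any(weight_accumulator <= 0))
    stop("internal coverage error: zero blending weight encountered")
  out <- accumulator / weight_accumulator
  if (output_dtype == "uint") {
    out <- round(pmin(pmax(out, 0), 65535))
  } else if (output_dtype == "int") {
    out <- round(out)
  }
  dim(out) <- dim(accumulator)
  out
}

.window_origins <- function(S, w, overlap) {
  stride <- pmax(1L, as.integer(round(w * (1 - overlap))))
  lapply(seq_along(S), function(a) {
    if (w[a] >= S[a]) return(1L)
    o <- seq.int(1L, S[a] - w[a] + 1L, by = stride[a])
    if (o[length(o)] != S[a] - w[a] + 1L) o <- c(o, S[a] - w[a] + 1L)
    o
  })
}

# core tiled prediction on one spatial volume (S..., C)
.predict_spatial <- function(arr, predictor, spec, down_factors) {
  d <- length(dim(arr)) - 1L
  Cin <- dim(arr)[d + 1L]
  pv <- pad_to_valid(arr, rep(down_factors, length.out = d))
  S <- dim(pv$img)[seq_len(d)]
  w <- spec$window_size
  if (is.null(w) || !length(w)) w <- S
  w <- pmin(rep(as.integer(w), length.out = d), S)
  w <- w + (down_factors - w %% down_factors) %% down_factors
  w <- pmin(w, S)
  wt <- if (identical(spec$blend %||% "gaussian", "gaussian"))
    gaussian_window_weights(w, spec$gaussian_sigma_scale %||% 0.125)
  else array(1, w)
  origins <- .window_origins(S, w, spec$overlap %||% 0.25)
  grid <- as.matrix(do.call(expand.grid, origins))
  acc <- NULL; wacc <- array(0, S)
  for (r in seq_len(nrow(grid))) {
    idx <- lapply(seq_len(d), function(a) grid[r, a] + seq_len(w[a]) - 1L)
    xin <- do.call(`[`, c(list(pv$img), idx, list(quote(expr = )),
                          list(drop = FALSE)))
    xin <- array(xin, c(1L, w, Cin))
    y <- predictor(xin)
    Cout <- dim(y)[length(dim(y))]
    if (is.null(acc)) acc <- array(0, c(S, Cout))
    y <- array(y, c(w, Cout))
    widx <- c(idx, list(quote(expr = )))
    cur <- do.call(`[`, c(list(acc), widx, list(drop = FALSE)))
    wy <- y * as.vector(wt)
    acc <- do.call(`[<-`, c(list(acc), widx, list(as.vector(cur + wy))))
    wcur <- do.call(`[`, c(list(wacc), idx, list(drop = FALSE)))
    wacc <- do.call(`[<-`, c(list(wacc), idx, list(as.vector(wcur + wt))))
  }
  Cout <- dim(acc)[d + 1L]
  out <- stitch(acc, array(rep(as.vector(wacc), Cout), c(S, Cout)), "float")
  crop_from_pad(out, pv$crop)
}

#' Predict a full image with sliding-window inference
#'
#' Accepts up-to-5D images; timepoints are processed independently and all
#' channels are fed jointly.  The image is normalized with the training
#' normalization, tiled into overlapping windows (stride = `window * (1 -
#' overlap)`), each window predicted and blended with Gaussian (or
#' uniform) weights, and the padding inverted.  When `spec$un_normalize`
#' is set and the normalization is invertible from its cached statistics,
#' the output is mapped back to the input intensity scale.
#'
#' @param img an [nd_image()] (axes any subsequence of TCZYX).
#' @param model an `im2im_network` or a function on channels-last arrays.
#' @param spec inference config: `window_size`, `overlap`, `blend`,
#'   `gaussian_sigma_scale`, `output_dtype`, `un_normalize`.
#' @param norm optional normalization transform entry (as in the
#'   `preprocess` config list) applied before prediction.
#' @return predicted [nd_image()].
#' @export
predict_image <- function(img, model, spec = list(), norm = NULL) {
  img <- nd_canonicalize(img)
  down <- if (inherits(model, "im2im_network")) net_down_factors(model)
  else rep(1L, length(intersect(img$axes, c("Z", "Y", "X"))))
  predictor <- function(x) net_predict(model, x)
  tdim <- nd_axis_extent(img, "T")
  frames <- vector("list", tdim)
  has_t <- "T" %in% img$axes
  for (t in seq_len(tdim)) {
    fr <- if (has_t) nd_drop_axis(img, "T", t) else img
    # each timepoint is normalized and predicted independently
    nstats <- NULL
    if (!is.null(norm)) {
      fr <- apply_transform(fr, norm)
      nstats <- attr(fr, "norm_stats")
    }
    has_c <- "C" %in% fr$axes
    arr <- fr$data
    if (has_c) {
      ci <- match("C", fr$axes)
      arr <- aperm(arr, c(setdiff(seq_along(fr$axes), ci), ci))
    } else {
      arr <- array(arr, c(dim(arr), 1L))
    }
    pred <- .predict_spatial(arr, predictor, spec, down)
    # back to canonical C-first layout
    out <- aperm(pred, c(length(dim(pred)), seq_len(length(dim(pred)) - 1L)))
    if (isTRUE(spec$un_normalize) && !is.null(nstats) &&
        length(nstats$per_channel) != dim(out)[1])
      nstats$per_channel <- nstats$per_channel[1]  # channel counts differ
    if (isTRUE(spec$un_normalize) && !is.null(nstats))
      out <- un_normalize(nd_image(out, c("C",
                                          intersect(fr$axes,
                                                    c("Z", "Y", "X")))),
                          nstats)$data
    frames[[t]] <- out
  }
  sp <- intersect(img$axes, c("Z", "Y", "X"))
  axes <- c(if (has_t) "T", "C", sp)
  full <- array(unlist(frames), c(dim(frames[[1]]), tdim))
  perm <- c(length(dim(full)), seq_len(length(dim(full)) - 1L))
  full <- aperm(full, perm)
  if (!has_t) { dim(full) <- dim(full)[-1] }
  out_img <- nd_image(full, axes, voxel_size = img$voxel_size,
                      dtype_kind = spec$output_dtype %||% "float")
  out_img <- nd_canonicalize(out_img)
  if (spec$output_dtype %||% "float" %in% c("uint", "int"))
    out_img$data <- round(out_img$data)
  out_img
}

#' Tiled EmbedSeg inference: decode per window, merge across overlaps
#'
#' @param img source [nd_image()] (2D or 3D, single channel).
#' @param net EmbedSeg backbone (`d+2` output channels).
#' @param spec inference config (window/overlap); `decode` sub-list is
#'   passed to [decode_instances()].
#' @param norm optional normalization entry.
#' @return integer instance map as an [nd_image()].
#' @export
predict_instances <- function(img, net, spec = list(), norm = NULL) {
  img <- nd_canonicalize(img)
  work <- if (!is.null(norm)) apply_transform(img, norm) else img
  sp <- intersect(work$axes, c("Z", "Y", "X"))
  d <- length(sp)
  arr <- work$data
  if ("C" %in% work$axes) {
    ci <- match("C", work$axes)
    arr <- aperm(arr, c(setdiff(seq_along(work$axes), ci), ci))
  } else arr <- array(arr, c(dim(arr), 1L))
  down <- net_down_factors(net)
  pv <- pad_to_valid(arr, rep(down, length.out = d))
  S <- dim(pv$img)[seq_len(d)]
  w <- spec$window_size
  if (is.null(w) || !length(w)) w <- S
  w <- pmin(rep(as.integer(w), length.out = d), S)
  w <- w + (down - w %% down) %% down
  w <- pmin(w, S)
  origins <- .window_origins(S, w, spec$overlap %||% 0.25)
  grid <- as.matrix(do.call(expand.grid, origins))
  wins <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    idx <- lapply(seq_len(d), function(a) grid[r, a] + seq_len(w[a]) - 1L)
    xin <- do.call(`[`, c(list(pv$img), idx, list(quote(expr = )),
                          list(drop = FALSE)))
    xin <- array(xin, c(1L, w, dim(arr)[d + 1L]))
    raw <- net_predict(net, xin)
    inst <- decode_instances(embed_output_from_raw(raw),
                             spec$decode %||% list())
    wins[[r]] <- list(map = inst, origin = grid[r, ])
  }
  full <- merge_instance_windows(wins, S, iou_merge = 0.5)
  full <- crop_from_pad(full, list(sp_idx = seq_len(d),
                                   orig = dim(arr)[seq_len(d)]))
  nd_image(full, sp, voxel_size = img$voxel_size, dtype_kind = "uint")
}
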