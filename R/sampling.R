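# Patch extraction for training: uniform and foreground-weighted spatial
# sampling with identical crop windows across source/target/mask, and the
# exclusion-mask loss contract.

#' Sample training patches from a loaded record
#'
#' Crops `patches_per_image` windows of `patch_size` from spatially
#' congruent source/target (and optional exclusion/weight) arrays.  With
#' `weighting = "foreground_weighted"`, each patch is centred on a positive
#' voxel of the weight map (or of the target, when no weight map is given)
#' with probability `fg_ratio`, else drawn uniformly over all valid
#' origins.  Patches never cross image boundaries.  A patch whose exclusion
#' mask is entirely 1 is re-drawn (up to 10 attempts).
#'
#' @param pair named list with spatial arrays `source`, `target`, and
#'   optionally `exclusion` (binary, 1 = ignore) and `weight`.
#'   Arrays are `(S...)` or `(S..., C)`; spatial extents must agree.
#' @param spec sampling config: `patch_size`, `patches_per_image`,
#'   `weighting`, `fg_ratio`.
#' @param rng an [rng_stream()].
#' @return list of tuples `list(source, target, exclusion, origin)`, all
#'   cropped with the identical window.
#' @export
sample_patches <- function(pair, spec, rng) {
  src <- pair$source
  d <- length(spec$patch_size)
  S <- dim(src)[seq_len(d)]
  p <- as.integer(spec$patch_size)
  if (any(p > S))
    stop("patch size (", paste(p, collapse = "x"),
         ") exceeds image extent (", paste(S, collapse = "x"), ")")
  nvalid <- S - p + 1L
  fgmap <- pair$weight
  if (is.null(fgmap) && identical(spec$weighting, "foreground_weighted"))
    fgmap <- pair$target
  fg_idx <- NULL
  if (identical(spec$weighting, "foreground_weighted")) {
    fgarr <- fgmap
    if (length(dim(fgarr)) > d) {       # collapse channels
      dim(fgarr) <- c(prod(S), length(fgarr) / prod(S))
      fgarr <- rowSums(fgarr)
      dim(fgarr) <- S
    }
    fg_idx <- which(fgarr > 0)
    if (!length(fg_idx)) {
      warning("foreground-weighted sampling requested but the weight map ",
              "is all zero; falling back to uniform sampling")
      fg_idx <- NULL
    }
  }
  crop <- function(arr, orig) {
    idx <- lapply(seq_len(d), function(a) orig[a] + seq_len(p[a]) - 1L)
    if (length(dim(arr)) > d) idx <- c(idx, list(quote(expr = )))
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  draw_origin <- function() {
    use_fg <- !is.null(fg_idx) &&
      with_rng(rng, stats::runif(1)) < (spec$fg_ratio %||% 0.5)
    if (use_fg) {
      v <- fg_idx[with_rng(rng, sample.int(length(fg_idx), 1L))]
      pos <- arrayInd(v, S)[1, ]
      orig <- pos - p %/% 2L
      pmin(pmax(orig, 1L), nvalid)
    } else {
      vapply(seq_len(d), function(a)
        with_rng(rng, sample.int(nvalid[a], 1L)), 0L)
    }
  }
  out <- vector("list", spec$patches_per_image)
  for (i in seq_len(spec$patches_per_image)) {
    orig <- draw_origin()
    if (!is.null(pair$exclusion)) {
      for (attempt in seq_len(10L)) {
        em <- crop(pair$exclusion, orig)
        if (any(em == 0)) break
        orig <- draw_origin()
      }
    }
    out[[i]] <- list(
      source = crop(src, orig),
      target = if (!is.null(pair$target)) crop(pair$target, orig),
      exclusion = if (!is.null(pair$exclusion)) crop(pair$exclusion, orig),
      origin = orig)
  }
  out
}

#' Masked mean loss over non-excluded voxels
#'
#' Returns the mean of `loss_map` over voxels where `mask == 0`.  The
#' gradient of the result with respect to predictions at excluded voxels is
#' identically zero (see [excl_grad_factor()]).
#'
#' @param loss_map per-voxel loss array.
#' @param mask binary array congruent with `loss_map`, 1 = excluded; `NULL`
#'   means nothing excluded.
#' @return scalar loss.
#' @export
apply_exclusion <- function(loss_map, mask = NULL) {
  if (is.null(mask)) return(mean(loss_map))
  stopifnot(length(loss_map) == length(mask))
  keep <- mask == 0
  n <- sum(keep)
  if (n == 0)
    stop("exclusion mask covers the whole patch: no supervised signal")
  sum(loss_map[keep]) / n
}

#' Per-voxel weight of the masked-mean gradient
#'
#' `d apply_exclusion / d loss_map[i]` = `1/n_kept` on kept voxels and 0 on
#' excluded ones.
#'
#' @param mask binary exclusion array or `NULL`.
#' @param dims dims of the loss map (used when `mask` is `NULL`).
#' @return array of gradient weights.
#' @export
excl_grad_factor <- function(mask, dims) {
  if (is.null(mask)) return(array(1 / prod(dims), dims))
  keep <- (mask == 0) * 1
  n <- sum(keep)
  if (n == 0)
    stop("exclusion mask covers the whole patch: no supervised signal")
  out <- keep / n
  dim(out) <- dims
  out
}
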