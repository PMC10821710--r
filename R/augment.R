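# On-the-fly augmentation, applied after patch extraction with a private
# RNG stream.  Augmentation entries live in the same `preprocess` list as
# the deterministic transforms but are flagged `deterministic: false`, so
# they are never cached; geometry is applied jointly to source, target and
# exclusion patches.

.flip_axis <- function(arr, ax) {
  idx <- rep(list(quote(expr = )), length(dim(arr)))
  idx[[ax]] <- dim(arr)[ax]:1
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# one quarter turn in the (a1, a2) plane: transpose, then reverse a1
.rot90_once <- function(arr, a1, a2) {
  perm <- seq_along(dim(arr))
  perm[c(a1, a2)] <- c(a2, a1)
  .flip_axis(aperm(arr, perm), a1)
}

#' Split a transform list into cacheable and augmentation entries
#' @param transforms the `preprocess` config list.
#' @return `list(deterministic = ..., augment = ...)`.
#' @export
split_transforms <- function(transforms) {
  det <- Filter(function(tr) isTRUE(tr$deterministic), transforms)
  aug <- Filter(function(tr) !isTRUE(tr$deterministic), transforms)
  list(deterministic = det, augment = aug)
}

#' Apply augmentation entries to a list of patch tuples
#'
#' Supported entries: `random_flip` (each spatial axis reversed with
#' probability 0.5) and `random_rot90` (0-3 quarter turns in the YX plane;
#' applied only when the two lateral patch extents are equal).  The same
#' geometry is applied to the source, target and exclusion of a tuple.
#'
#' @param patches list of tuples from [sample_patches()].
#' @param d number of spatial dims of the patches.
#' @param augment list of augmentation entries.
#' @param rng an [rng_stream()].
#' @return augmented patch list.
#' @export
augment_patches <- function(patches, d, augment, rng) {
  if (!length(augment)) return(patches)
  apply_geom <- function(p, fn) {
    p$source <- fn(p$source)
    if (!is.null(p$target)) p$target <- fn(p$target)
    if (!is.null(p$exclusion)) p$exclusion <- fn(p$exclusion)
    p
  }
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    for (tr in augment) {
      if (tr$name == "random_flip") {
        for (a in seq_len(d)) {
          if (with_rng(rng, stats::runif(1)) < 0.5)
            p <- apply_geom(p, function(x) .flip_axis(x, a))
        }
      } else if (tr$name == "random_rot90") {
        sp <- dim(p$source)[c(d - 1L, d)]
        k <- with_rng(rng, sample(0:3, 1))
        if (sp[1] == sp[2] && k > 0) {
          for (q in seq_len(k))
            p <- apply_geom(p, function(x) .rot90_once(x, d - 1L, d))
        }
      } else if (tr$name == "intensity_jitter") {
        g <- 1 + with_rng(rng, stats::rnorm(1, 0, tr$gain_sd %||% 0.1))
        b <- with_rng(rng, stats::rnorm(1, 0, tr$bias_sd %||% 0.05))
        p$source <- p$source * g + b
      } else {
        stop("unknown augmentation: ", tr$name)
      }
    }
    patches[[i]] <- p
  }
  patches
}
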