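# Seeded generator of desk-scale fixtures with the statistical structure
# each framework assumes: blob-shaped "nuclei" on a noisy background,
# semantic masks, instance-label maps, low/high-SNR pairs and H&E-like RGB
# tiles.  The forward model is deliberately minimal (ellipsoids, Gaussian
# PSF, Gaussian + optional Poisson noise): enough nonlinearity that
# identity models fail and learning is measurable, with exactly-known
# ground truth for metric ceilings.

#' Fixture specification
#'
#' @param task one of `labelfree`, `semantic`, `instance`, `denoise`,
#'   `stain`, `modality`.
#' @param dim 2 or 3.
#' @param shape spatial extents (YX or ZYX), each >= 16 (>= 8 in Z).
#' @param n_objects range `c(lo, hi)` of objects per image.
#' @param noise_sd Gaussian noise sd (intensity units of a [0,1] image).
#' @param poisson_scale 0 disables Poisson noise; otherwise photon count at
#'   intensity 1.
#' @param psf_sigma Gaussian PSF width (pixels).
#' @param seed generator seed.
#' @param n_images images per fixture set.
#' @return validated spec list.
#' @export
fixture_spec <- function(task = "labelfree", dim = 2L,
                         shape = if (dim == 2) c(64L, 64L) else c(8L, 32L, 32L),
                         n_objects = c(2L, 5L), noise_sd = 0.05,
                         poisson_scale = 0, psf_sigma = 1,
                         seed = 42L, n_images = 6L) {
  task <- match.arg(task, c("labelfree", "semantic", "instance",
                            "denoise", "stain", "modality"))
  stopifnot(dim %in% c(2L, 3L), length(shape) == dim,
            all(shape >= c(if (dim == 3) 8L, 16L, 16L)),
            all(n_objects >= 0))
  list(task = task, dim = as.integer(dim), shape = as.integer(shape),
       n_objects = as.integer(n_objects), noise_sd = noise_sd,
       poisson_scale = poisson_scale, psf_sigma = psf_sigma,
       seed = as.integer(seed), n_images = as.integer(n_images))
}

# separable Gaussian blur with symmetric (edge-included) padding
.gauss_blur <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  d <- dim(arr)
  for (a in seq_along(d)) {
    perm <- c(a, setdiff(seq_along(d), a))
    x <- aperm(arr, perm)
    n <- d[a]
    dim(x) <- c(n, length(x) / n)
    xp <- rbind(x[r:1, , drop = FALSE], x, x[n:(n - r + 1), , drop = FALSE])
    f <- stats::filter(xp, k, sides = 2)
    x <- f[r + seq_len(n), , drop = FALSE]
    dim(x) <- d[perm]
    arr <- aperm(x, order(perm))
  }
  arr
}

# coordinate grids (one array per axis, in voxel units)
.coord_grids <- function(S) {
  lapply(seq_along(S), function(a) {
    rep_each <- prod(S[seq_len(a - 1L)])
    rep_times <- prod(S[-seq_len(a)])
    array(rep(rep(seq_len(S[a]), each = rep_each), times = rep_times), S)
  })
}

#' Generate one blob world: instance labels plus clean intensity image
#'
#' Places up to `n_objects` random non-overlapping ellipses/ellipsoids
#' (rejection sampling, <= 100 attempts each); the clean intensity is a
#' per-object random amplitude times a smooth interior texture, blurred by
#' the PSF, on a constant background.  If fewer objects fit, the actual
#' count is recorded.
#'
#' @param spec a [fixture_spec()].
#' @param rng an [rng_stream()] (defaults to one derived from `spec$seed`).
#' @return list: `labels` (integer instance map), `clean` (intensity in
#'   `[0, ~1]`, no noise), `n_placed`.
#' @export
make_blob_world <- function(spec, rng = NULL) {
  if (is.null(rng)) rng <- rng_stream(child_seed(spec$seed, "world"))
  S <- spec$shape
  d <- spec$dim
  grids <- .coord_grids(S)
  labels <- array(0L, S)
  interior <- array(0, S)
  n_want <- if (length(spec$n_objects) > 1)
    with_rng(rng, sample(spec$n_objects[1]:spec$n_objects[2], 1))
  else spec$n_objects[1]
  n_placed <- 0L
  yx <- if (d == 3) 2:3 else 1:2
  for (obj in seq_len(n_want)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      amin <- 3; amax <- max(4, min(S[yx]) / 5)
      ax <- with_rng(rng, stats::runif(d, amin, amax))
      if (d == 3) ax[1] <- with_rng(rng, stats::runif(1, 1.5, max(2, S[1] / 3)))
      ctr <- vapply(seq_len(d), function(a)
        with_rng(rng, stats::runif(1, 1 + ax[a], S[a] - ax[a])), 0)
      theta <- with_rng(rng, stats::runif(1, 0, pi))
      u <- grids[[yx[1]]] - ctr[yx[1]]
      v <- grids[[yx[2]]] - ctr[yx[2]]
      ur <- cos(theta) * u + sin(theta) * v
      vr <- -sin(theta) * u + cos(theta) * v
      r2 <- (ur / ax[yx[1]])^2 + (vr / ax[yx[2]])^2
      if (d == 3) r2 <- r2 + ((grids[[1]] - ctr[1]) / ax[1])^2
      inside <- r2 <= 1
      if (!any(inside)) next
      if (any(labels[inside] > 0)) next
      n_placed <- n_placed + 1L
      labels[inside] <- n_placed
      amp <- with_rng(rng, stats::runif(1, 0.5, 1))
      tex <- amp * (1 - 0.35 * r2[inside]) *
        (1 + 0.15 * sin(0.9 * ur[inside]) * cos(0.9 * vr[inside]))
      interior[inside] <- tex
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  clean <- 0.1 + .gauss_blur(interior, spec$psf_sigma)
  list(labels = labels, clean = clean, n_placed = n_placed)
}

.add_noise <- function(img, spec, rng, sd_scale = 1) {
  out <- img
  if (spec$poisson_scale > 0) {
    lam <- pmax(out, 0) * spec$poisson_scale
    out <- with_rng(rng, stats::rpois(length(lam), lam)) / spec$poisson_scale
    dim(out) <- dim(img)
  }
  if (spec$noise_sd > 0)
    out <- out + with_rng(rng,
      array(stats::rnorm(length(img), 0, spec$noise_sd * sd_scale), dim(img)))
  out
}

# magnitude of the spatial gradient (central differences)
.grad_mag <- function(arr) {
  d <- dim(arr)
  g2 <- array(0, d)
  for (a in seq_along(d)) {
    idx_hi <- rep(list(quote(expr = )), length(d))
    idx_lo <- idx_hi
    n <- d[a]
    idx_hi[[a]] <- c(2:n, n)
    idx_lo[[a]] <- c(1, 1:(n - 1))
    hi <- do.call(`[`, c(list(arr), idx_hi, list(drop = FALSE)))
    lo <- do.call(`[`, c(list(arr), idx_lo, list(drop = FALSE)))
    g2 <- g2 + (hi - lo)^2 / 4
  }
  sqrt(g2)
}

# instances touching any image border (the typical uncurated-cell case)
.border_instances <- function(labels) {
  d <- dim(labels)
  touch <- integer(0)
  for (a in seq_along(d)) {
    idx <- rep(list(quote(expr = )), length(d))
    for (side in c(1L, d[a])) {
      idx[[a]] <- side
      sl <- do.call(`[`, c(list(labels), idx, list(drop = FALSE)))
      touch <- union(touch, sl[sl > 0])
    }
  }
  mask <- array(0L, d)
  if (length(touch)) mask[labels %in% touch] <- 1L
  mask
}

#' Render one source/target pair (plus optional exclusion) for a task
#'
#' @param spec a [fixture_spec()].
#' @param world a [make_blob_world()] result.
#' @param rng an [rng_stream()].
#' @return list of [nd_image()]s: `source`, `target`, optionally
#'   `exclusion`.
#' @export
render_task_pair <- function(spec, world, rng) {
  S <- spec$shape
  axes <- if (spec$dim == 2) c("Y", "X") else c("Z", "Y", "X")
  mk <- function(a, kind = "float") nd_image(a, axes, dtype_kind = kind)
  clean <- world$clean
  switch(spec$task,
    labelfree = {
      # brightfield-like: inverted, edge-enhanced, heavily blurred
      bf <- 1 - .gauss_blur(clean, 3 * spec$psf_sigma + 1) +
        0.8 * .gauss_blur(.grad_mag(clean), spec$psf_sigma)
      list(source = mk(.add_noise(bf, spec, rng)), target = mk(clean))
    },
    semantic = list(source = mk(.add_noise(clean, spec, rng)),
                    target = mk((world$labels > 0) * 1L, "uint")),
    instance = list(source = mk(.add_noise(clean, spec, rng)),
                    target = mk(world$labels, "uint"),
                    exclusion = mk(.border_instances(world$labels), "uint")),
    denoise = list(source = mk(.add_noise(clean, spec, rng, sd_scale = 6)),
                   target = mk(.add_noise(clean, spec, rng, sd_scale = 0.5))),
    modality = list(source = mk(.add_noise(.gauss_blur(clean,
                                                       3 * spec$psf_sigma + 1),
                                           spec, rng)),
                    target = mk(.add_noise(.gauss_blur(clean,
                                                       0.5 * spec$psf_sigma),
                                           spec, rng, sd_scale = 0.5))),
    stain = {
      # two-stain optical-density rendering with per-image colour jitter
      stopifnot(spec$dim == 2)
      hematoxylin <- c(0.65, 0.70, 0.29)
      eosin <- c(0.07, 0.99, 0.11)
      jit <- function(v) {
        vj <- v + with_rng(rng, stats::rnorm(3, 0, 0.05))
        vj / sqrt(sum(vj^2))
      }
      c_h <- (world$labels > 0) * clean * 1.2
      c_e <- 0.4 + 0.2 * .gauss_blur((world$labels == 0) * 1, 2)
      od <- outer(as.vector(c_h), jit(hematoxylin)) +
        outer(as.vector(c_e), jit(eosin))
      rgb <- exp(-od)
      arr <- array(t(rgb), c(3L, S))
      arr <- pmin(pmax(arr + with_rng(rng,
        array(stats::rnorm(length(arr), 0, spec$noise_sd), dim(arr))), 0), 1)
      list(source = nd_image(arr, c("C", axes)),
           target = mk((world$labels > 0) * 1L, "uint"))
    })
}

#' Materialize a fixture dataset on disk
#'
#' Writes `n_images` pairs under `out_dir` in both the paired-folders
#' layout (`image/`, `ground_truth/`, optionally `exclusion/`) and as a
#' `manifest.csv` (csv-manifest mode), plus the generating spec as
#' `fixture.yaml`.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created).
#' @return the directory, invisibly.
#' @export
make_task_pairs <- function(spec, out_dir) {
  dir.create(file.path(out_dir, "image"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "ground_truth"), showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(spec$n_images)) {
    rng <- rng_stream(child_seed(spec$seed, paste0("img", i)))
    world <- make_blob_world(spec, rng)
    pair <- render_task_pair(spec, world, rng)
    fn <- sprintf("img_%03d.tif", i)
    write_image(pair$source, file.path(out_dir, "image", fn))
    write_image(pair$target, file.path(out_dir, "ground_truth", fn))
    row <- list(source_path = file.path("image", fn),
                target_path = file.path("ground_truth", fn))
    if (!is.null(pair$exclusion)) {
      dir.create(file.path(out_dir, "exclusion"), showWarnings = FALSE)
      write_image(pair$exclusion, file.path(out_dir, "exclusion", fn))
      row$exclusion_path <- file.path("exclusion", fn)
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(tab, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(spec, file.path(out_dir, "fixture.yaml"))
  invisible(out_dir)
}
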