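# Image reading and writing.  Pixel data is stored as multi-page TIFF
# (pages ordered T-slowest, C, Z-fastest); axes, voxel size and dtype are
# recorded in a JSON sidecar `<file>.json` so integer images round-trip
# losslessly and float images round-trip to float32 precision (the float
# samples are affinely encoded into [0,1], with the affine recorded in the
# sidecar).  Files without a sidecar are interpreted by rank:
# 2 -> YX, 3 -> ZYX, 4 -> CZYX, 5 -> TCZYX.

.sidecar_path <- function(ref) paste0(ref, ".json")

#' Write an image to disk
#'
#' @param img an [nd_image()].
#' @param ref destination path (`.tif`); a `<ref>.json` sidecar records
#'   axes, voxel size and dtype.
#' @return `ref`, invisibly.
#' @export
write_image <- function(img, ref) {
  if (!dir.exists(dirname(ref)))
    stop("I/O error: parent directory does not exist: ", dirname(ref))
  img <- nd_canonicalize(img)
  arr <- img$data
  enc <- list(kind = img$dtype_kind)
  if (img$dtype_kind %in% c("uint", "int")) {
    if (any(arr != round(arr)))
      stop("integer dtype declared but data has fractional values")
    if (min(arr) < 0 || max(arr) > 65535)
      stop("integer data outside the uint16 range [0, 65535]")
    pages_data <- arr / 65535
    bits <- 16L
    enc$scale <- 65535
    enc$offset <- 0
  } else {
    lo <- min(arr); hi <- max(arr)
    if (hi == lo) hi <- lo + 1
    pages_data <- (arr - lo) / (hi - lo)
    bits <- 32L
    enc$scale <- hi - lo
    enc$offset <- lo
  }
  d <- dim(arr)
  axes <- img$axes
  yi <- match("Y", axes); xi <- match("X", axes)
  lead <- setdiff(seq_along(axes), c(yi, xi))
  n_pages <- if (length(lead)) prod(d[lead]) else 1L
  pages <- vector("list", n_pages)
  if (length(lead)) {
    # canonical order TCZ: Z varies fastest across pages
    grid <- as.matrix(do.call(expand.grid,
                              rev(lapply(lead, function(a) seq_len(d[a])))))
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # columns = lead
    for (p in seq_len(n_pages)) {
      idx <- rep(list(quote(expr = )), length(axes))
      for (j in seq_along(lead)) idx[[lead[j]]] <- grid[p, j]
      pg <- do.call(`[`, c(list(pages_data), idx, list(drop = FALSE)))
      pages[[p]] <- matrix(pg, d[yi], d[xi])
    }
  } else {
    pages[[1]] <- matrix(pages_data, d[yi], d[xi])
  }
  ok <- tryCatch(tiff::writeTIFF(pages, ref, bits.per.sample = bits,
                                 compression = "none", reduce = FALSE),
                 error = function(e) stop("I/O error writing ", ref, ": ",
                                          conditionMessage(e), call. = FALSE))
  meta <- list(axes = paste(axes, collapse = ""),
               shape = as.integer(d),
               dtype_kind = img$dtype_kind,
               encoding = enc,
               voxel_size_um = if (!is.null(img$voxel_size))
                 as.numeric(img$voxel_size))
  jsonlite::write_json(meta, .sidecar_path(ref), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(ref)
}

#' Read an image from disk
#'
#' Axes are taken from the JSON sidecar when present, else inferred from
#' rank (2 -> YX, 3 -> ZYX, 4 -> CZYX, 5 -> TCZYX) or forced with
#' `as_axes`.
#'
#' @param ref TIFF path.
#' @param as_axes optional axis labels overriding the inferred ones.
#' @return an [nd_image()].
#' @export
read_image <- function(ref, as_axes = NULL) {
  if (!file.exists(ref)) stop("I/O error: no such file: ", ref)
  sc <- .sidecar_path(ref)
  pages <- tryCatch(tiff::readTIFF(ref, all = TRUE, info = FALSE,
                                   as.is = !file.exists(sc)),
                    error = function(e) stop("I/O error reading ", ref, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    axes <- strsplit(meta$axes, "")[[1]]
    d <- as.integer(meta$shape)
    yi <- match("Y", axes); xi <- match("X", axes)
    lead <- setdiff(seq_along(axes), c(yi, xi))
    arr <- array(0, d)
    if (length(lead)) {
      grid <- as.matrix(do.call(expand.grid,
                                rev(lapply(lead, function(a) seq_len(d[a])))))
      grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
      for (p in seq_along(pages)) {
        idx <- rep(list(quote(expr = )), length(axes))
        for (j in seq_along(lead)) idx[[lead[j]]] <- grid[p, j]
        arr <- do.call(`[<-`, c(list(arr), idx, list(as.vector(pages[[p]]))))
      }
    } else {
      arr <- array(pages[[1]], d)
    }
    arr <- arr * meta$encoding$scale + (meta$encoding$offset %||% 0)
    if (meta$dtype_kind %in% c("uint", "int")) arr <- round(arr)
    vs <- meta$voxel_size_um
    if (is.null(vs) || !length(vs)) vs <- NULL
    return(nd_image(arr, axes, voxel_size = vs,
                    dtype_kind = meta$dtype_kind))
  }
  # no sidecar: rank dialect table
  p1 <- pages[[1]]
  spp <- if (length(dim(p1)) == 3) dim(p1)[3] else 1L   # samples per pixel
  n <- length(pages)
  if (n == 1 && spp == 1) {
    arr <- p1; axes <- c("Y", "X")
  } else if (n == 1 && spp > 1) {
    arr <- aperm(p1, c(3, 1, 2)); axes <- c("C", "Y", "X")
  } else if (spp == 1) {
    arr <- array(unlist(pages), c(dim(p1), n))
    arr <- aperm(arr, c(3, 1, 2)); axes <- c("Z", "Y", "X")
  } else {
    arr <- array(unlist(pages), c(dim(p1), n))     # (Y, X, S, Z)
    arr <- aperm(arr, c(3, 4, 1, 2)); axes <- c("C", "Z", "Y", "X")
  }
  if (!is.null(as_axes)) {
    as_axes <- axis_spec(as_axes)
    if (length(as_axes) != length(dim(arr)))
      stop("as_axes rank (", length(as_axes),
           ") does not match image rank (", length(dim(arr)), ")")
    axes <- as_axes
  }
  if (length(dim(arr)) > 5)
    stop("unsupported dimensionality: rank ", length(dim(arr)))
  kind <- if (all(arr == round(arr)) && min(arr) >= 0) "uint" else "float"
  nd_image(arr, axes, dtype_kind = kind)
}
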