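# Axis-labelled image arrays: the universal currency of the framework.
# Canonical storage order is TCZYX (the OME convention); any subsequence of
# it is a valid axis set as long as Y and X are present.

.AXIS_ORDER <- c("T", "C", "Z", "Y", "X")
.SPATIAL_AXES <- c("Z", "Y", "X")

#' Validate an axis label sequence
#'
#' Axis labels must be unique, drawn from \{T, C, Z, Y, X\}, contain Y and X,
#' and appear as a subsequence of the canonical order T, C, Z, Y, X.
#'
#' @param labels character vector of axis labels.
#' @return the labels, invisibly, after validation.
#' @export
axis_spec <- function(labels) {
  labels <- toupper(as.character(labels))
  if (anyDuplicated(labels))
    stop("axis labels must be unique, got: ", paste(labels, collapse = ""))
  bad <- setdiff(labels, .AXIS_ORDER)
  if (length(bad))
    stop("unknown axis label(s): ", paste(bad, collapse = ", "))
  if (!all(c("Y", "X") %in% labels))
    stop("axes must include Y and X, got: ", paste(labels, collapse = ""))
  if (!identical(labels, intersect(.AXIS_ORDER, labels)))
    stop("axis order must be a subsequence of TCZYX, got: ",
         paste(labels, collapse = ""))
  invisible(labels)
}

#' Construct an axis-labelled image
#'
#' An `nd_image` wraps a numeric array with axis labels (a subsequence of
#' TCZYX), optional physical voxel sizes in microns for the spatial axes,
#' and a declared dtype kind used when the image is written to disk.
#'
#' @param data numeric array; its rank must equal the number of axis labels.
#' @param axes character vector of axis labels, e.g. `c("Z","Y","X")`.
#' @param voxel_size optional numeric vector, microns per spatial axis
#'   present in `axes` (same order as the axes).
#' @param dtype_kind one of `"uint"`, `"int"`, `"float"`.
#' @return an object of class `nd_image`.
#' @export
nd_image <- function(data, axes, voxel_size = NULL,
                     dtype_kind = c("float", "uint", "int")) {
  dtype_kind <- match.arg(dtype_kind)
  axes <- axis_spec(axes)
  if (is.null(dim(data))) {
    if (length(axes) != 1L) dim(data) <- if (length(axes) == 2L)
      c(length(data), 1L) else stop("rank mismatch")
  }
  if (length(dim(data)) != length(axes))
    stop("array rank (", length(dim(data)), ") != number of axes (",
         length(axes), ")")
  sp <- intersect(axes, .SPATIAL_AXES)
  if (any(dim(data)[match(sp, axes)] < 1L))
    stop("spatial extents must be >= 1")
  if (!is.null(voxel_size)) {
    if (length(voxel_size) != length(sp))
      stop("voxel_size needs one entry per spatial axis (", length(sp), ")")
    if (any(voxel_size <= 0)) stop("voxel_size entries must be > 0")
    voxel_size <- as.numeric(voxel_size)
    names(voxel_size) <- sp
  }
  structure(list(data = data, axes = axes, voxel_size = voxel_size,
                 dtype_kind = dtype_kind),
            class = "nd_image")
}

#' @export
print.nd_image <- function(x, ...) {
  cat("<nd_image> ", paste(x$axes, collapse = ""), " ",
      paste(dim(x$data), collapse = "x"),
      " dtype=", x$dtype_kind, sep = "")
  if (!is.null(x$voxel_size))
    cat("  voxel(um)=", paste(signif(x$voxel_size, 4), collapse = "x"),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.nd_image <- function(x) dim(x$data)

nd_axes <- function(img) img$axes

#' Spatial shape of an image
#' @param img an `nd_image`.
#' @return named integer vector of extents for the spatial axes present.
#' @export
nd_spatial_shape <- function(img) {
  sp <- intersect(img$axes, .SPATIAL_AXES)
  stats::setNames(dim(img$data)[match(sp, img$axes)], sp)
}

nd_axis_extent <- function(img, ax) {
  i <- match(ax, img$axes)
  if (is.na(i)) 1L else dim(img$data)[i]
}

#' Reorder axes to the canonical TCZYX subsequence
#'
#' Idempotent: images already in canonical order are returned unchanged.
#'
#' @param img an `nd_image` or a plain array plus `axes`.
#' @return an `nd_image` whose axes follow canonical order.
#' @export
nd_canonicalize <- function(img) {
  want <- intersect(.AXIS_ORDER, img$axes)
  if (identical(want, img$axes)) return(img)
  perm <- match(want, img$axes)
  nd_image(aperm(img$data, perm), want, voxel_size = img$voxel_size,
           dtype_kind = img$dtype_kind)
}

# Extract one timepoint (and keep remaining axes); ax extent 1 is dropped.
nd_drop_axis <- function(img, ax, index = 1L) {
  i <- match(ax, img$axes)
  if (is.na(i)) return(img)
  idx <- rep(list(quote(expr = )), length(img$axes))
  idx[[i]] <- index
  d <- do.call(`[`, c(list(img$data), idx, list(drop = FALSE)))
  newdim <- dim(d)[-i]
  d <- array(d, newdim)
  nd_image(d, img$axes[-i], voxel_size = img$voxel_size,
           dtype_kind = img$dtype_kind)
}

# Insert a length-1 axis in canonical position.
nd_add_axis <- function(img, ax) {
  if (ax %in% img$axes) return(img)
  newaxes <- intersect(.AXIS_ORDER, c(img$axes, ax))
  pos <- match(ax, newaxes)
  nd <- append(as.list(dim(img$data)), 1L, after = pos - 1L)
  d <- array(img$data, unlist(nd))
  nd_image(d, newaxes, voxel_size = img$voxel_size,
           dtype_kind = img$dtype_kind)
}
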