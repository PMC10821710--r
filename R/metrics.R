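# Evaluation metrics: Pearson correlation, SSIM, PSNR, pixel F1 and
# instance-level average precision at an IoU threshold, with mean +/- sd
# aggregation into a metric report.

#' Pearson correlation over all voxels
#' @param pred,gt numeric arrays of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(pred, gt) {
  p <- as.vector(pred); g <- as.vector(gt)
  if (stats::sd(p) == 0 || stats::sd(g) == 0)
    stop("undefined-correlation error: constant input")
  stats::cor(p, g)
}

# uniform box filter over valid positions (2D), via an integral image
.box_mean_2d <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  cs <- matrix(0, H + 1L, W + 1L)
  cs[-1L, -1L] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  i2 <- (w + 1L):(H + 1L); j2 <- (w + 1L):(W + 1L)
  (cs[i2, j2] - cs[i2 - w, j2] - cs[i2, j2 - w] + cs[i2 - w, j2 - w]) / w^2
}

.ssim_2d <- function(x, y, data_range, win = 7L) {
  if (any(dim(x) < win))
    stop("image smaller than the SSIM window (", win, ")")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mx <- .box_mean_2d(x, win)
  my <- .box_mean_2d(y, win)
  mxx <- .box_mean_2d(x * x, win)
  myy <- .box_mean_2d(y * y, win)
  mxy <- .box_mean_2d(x * y, win)
  # unbiased (n/(n-1)) covariance estimates, matching the reference
  # implementation of the SSIM paper
  nf <- win^2 / (win^2 - 1)
  vx <- nf * (mxx - mx^2)
  vy <- nf * (myy - my^2)
  cxy <- nf * (mxy - mx * my)
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Structural similarity index
#'
#' Mean local SSIM with a 7x7 uniform window and the standard stabilizing
#' constants (k1 = 0.01, k2 = 0.03).  3D volumes are scored as the average
#' of plane-wise 2D SSIM over Z.
#'
#' @param pred,gt numeric arrays (2D matrices or 3D `(Z, Y, X)` arrays).
#' @param data_range dynamic range of the data (max - min), > 0.
#' @param win window width, default 7.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(pred, gt, data_range, win = 7L) {
  stopifnot(data_range > 0, identical(dim(pred), dim(gt)))
  d <- length(dim(pred))
  if (d == 2) return(.ssim_2d(pred, gt, data_range, win))
  if (d == 3) {
    vals <- vapply(seq_len(dim(pred)[1]), function(z)
      .ssim_2d(pred[z, , ], gt[z, , ], data_range, win), 0)
    return(mean(vals))
  }
  stop("ssim expects 2D or 3D input")
}

#' Peak signal-to-noise ratio in dB
#' @param pred,gt numeric arrays.
#' @param data_range dynamic range, > 0.
#' @return `10 * log10(data_range^2 / MSE)`; `Inf` when MSE is 0.
#' @export
psnr <- function(pred, gt, data_range) {
  stopifnot(data_range > 0)
  mse <- mean((as.vector(pred) - as.vector(gt))^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Pixel-level F1 score of binary masks
#' @param pred_mask,gt_mask binary arrays.
#' @return `2 TP / (2 TP + FP + FN)`; two empty masks score 1.
#' @export
f1_pixel <- function(pred_mask, gt_mask) {
  p <- as.vector(pred_mask) > 0
  g <- as.vector(gt_mask) > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# IoU matrix between all (gt, pred) instance pairs, computed sparsely
.iou_matrix <- function(pred, gt) {
  pv <- as.vector(pred); gv <- as.vector(gt)
  pl <- sort(unique(pv[pv > 0])); gl <- sort(unique(gv[gv > 0]))
  if (!length(pl) || !length(gl))
    return(matrix(0, length(gl), length(pl),
                  dimnames = list(gl, pl)))
  sel <- pv > 0 & gv > 0
  key <- paste(gv[sel], pv[sel])
  inter <- table(key)
  psz <- table(factor(pv[pv > 0], levels = pl))
  gsz <- table(factor(gv[gv > 0], levels = gl))
  iou <- matrix(0, length(gl), length(pl), dimnames = list(gl, pl))
  if (length(inter)) {
    parts <- do.call(rbind, strsplit(names(inter), " "))
    gi <- match(as.integer(parts[, 1]), gl)
    pi <- match(as.integer(parts[, 2]), pl)
    for (r in seq_along(gi)) {
      i <- as.numeric(inter[r])
      iou[gi[r], pi[r]] <- i / (gsz[gi[r]] + psz[pi[r]] - i)
    }
  }
  iou
}

#' Instance-level average precision at an IoU threshold
#'
#' Greedy one-to-one matching of prediction/ground-truth instance pairs by
#' descending IoU; pairs with IoU >= `iou_thresh` are true positives and
#' `AP = TP / (TP + FP + FN)` with FP = unmatched predictions and FN =
#' unmatched ground-truth instances.  Two empty maps score 1 by
#' convention.
#'
#' @param pred,gt integer instance maps (0 = background).
#' @param iou_thresh IoU threshold, default 0.5.
#' @return AP value in `[0, 1]`.
#' @export
average_precision <- function(pred, gt, iou_thresh = 0.5) {
  iou <- .iou_matrix(pred, gt)
  ng <- nrow(iou); np <- ncol(iou)
  if (ng == 0 && np == 0) return(1)
  if (ng == 0 || np == 0) return(0)
  tp <- 0L
  used_g <- rep(FALSE, ng); used_p <- rep(FALSE, np)
  repeat {
    iou_f <- iou
    iou_f[used_g, ] <- -1
    iou_f[, used_p] <- -1
    m <- which.max(iou_f)
    if (iou_f[m] < iou_thresh) break
    gi <- (m - 1) %% ng + 1
    pi <- (m - 1) %/% ng + 1
    used_g[gi] <- TRUE; used_p[pi] <- TRUE
    tp <- tp + 1L
    if (all(used_g) || all(used_p)) break
  }
  fp <- np - tp; fn <- ng - tp
  tp / (tp + fp + fn)
}

#' Build a metric report with mean +/- population-sd summaries
#'
#' @param per_image data frame with columns `id`, `metric`, `value`.
#' @return list of class `metric_report`: `per_image` and `summary` (one
#'   row per metric: mean, sd, n).
#' @export
metric_report <- function(per_image) {
  stopifnot(all(c("id", "metric", "value") %in% names(per_image)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  metrics <- unique(per_image$metric)
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m)
      mean(per_image$value[per_image$metric == m]), 0),
    sd = vapply(metrics, function(m)
      pop_sd(per_image$value[per_image$metric == m]), 0),
    n = vapply(metrics, function(m)
      sum(per_image$metric == m), 0L),
    row.names = NULL)
  structure(list(per_image = per_image, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("%-10s %.4f +/- %.4f (n=%d)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i], x$summary$n[i]))
  invisible(x)
}

#' Write a metric report to CSV (per image) and JSON (summary)
#' @param report a [metric_report()].
#' @param prefix file path prefix; writes `<prefix>_per_image.csv` and
#'   `<prefix>_summary.json`.
#' @export
write_metric_report <- function(report, prefix) {
  utils::write.csv(report$per_image,
                   paste0(prefix, "_per_image.csv"), row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(report$summary$mean), report$summary$metric),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
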