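# Segmentation-quality and clinical volumetry metrics.

#' Per-class overlap metrics
#'
#' Dice, IoU, precision, recall and F1 from per-class TP/FP/FN counts.
#' Empty-class convention: both masks empty gives 1 for all metrics, one
#' empty gives 0.
#'
#' @param pred,truth \code{\link{label_volume}} objects or integer
#'   arrays of matching shape.
#' @param cls class label to evaluate.
#' @return named numeric: dice, iou, precision, recall, f1.
#' @export
confusion_metrics <- function(pred, truth, cls) {
  p <- if (inherits(pred, "label_volume")) pred$labels else pred
  t <- if (inherits(truth, "label_volume")) truth$labels else truth
  if (!identical(dim(p), dim(t)))
    stop("confusion_metrics: shape mismatch")
  a <- p == cls
  b <- t == cls
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  if (tp + fp + fn == 0)
    return(c(dice = 1, iou = 1, precision = 1, recall = 1, f1 = 1))
  if (sum(a) == 0 || sum(b) == 0)
    return(c(dice = 0, iou = 0, precision = 0, recall = 0, f1 = 0))
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(dice = 2 * tp / (2 * sum(a & b) + fp + fn), iou = tp / (tp + fp + fn),
    precision = precision, recall = recall, f1 = f1)
}

# Surface voxels by 6-connectivity erosion difference.
surface_voxels <- function(mask) boundary_shell(mask)

# Directed surface distances (mm) from every surface voxel of `a` to the
# surface of `b`.
directed_surface_distances <- function(a, b, spacing) {
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  if (!any(sa) || !any(sb)) return(NULL)
  d <- sqrt(.edt_sq(as.vector(sb), as.integer(dim(a)),
                    as.numeric(spacing)))
  d[as.vector(sa)]
}

#' Hausdorff distance between two masks
#'
#' Maximum (or given percentile) of the directed surface distances,
#' symmetrized by the maximum, in mm.  Undefined for an empty mask:
#' returns \code{NA} with a warning rather than 0.
#'
#' @param a,b binary 3D arrays.
#' @param spacing mm per axis.
#' @param percentile percentile of directed distances (100 = classic
#'   Hausdorff).
#' @export
hausdorff_distance <- function(a, b, spacing, percentile = 100) {
  dab <- directed_surface_distances(a != 0, b != 0, spacing)
  dba <- directed_surface_distances(b != 0, a != 0, spacing)
  if (is.null(dab) || is.null(dba)) {
    warning("hausdorff_distance: empty mask, metric undefined")
    return(NA_real_)
  }
  q <- percentile / 100
  max(stats::quantile(dab, q, names = FALSE),
      stats::quantile(dba, q, names = FALSE))
}

#' Average symmetric surface distance
#'
#' Mean of the two directed mean surface distances, in mm; bounded above
#' by the Hausdorff distance.
#'
#' @inheritParams hausdorff_distance
#' @export
assd <- function(a, b, spacing) {
  dab <- directed_surface_distances(a != 0, b != 0, spacing)
  dba <- directed_surface_distances(b != 0, a != 0, spacing)
  if (is.null(dab) || is.null(dba)) {
    warning("assd: empty mask, metric undefined")
    return(NA_real_)
  }
  (mean(dab) + mean(dba)) / 2
}

#' Mask volume in millilitres
#'
#' Voxel count times voxel volume (mm^3) divided by 1000.
#'
#' @param mask binary 3D array (or \code{\link{label_volume}} with a
#'   class via \code{cls}).
#' @param spacing mm per axis.
#' @param cls optional class label when \code{mask} is a label volume.
#' @export
volume_ml <- function(mask, spacing = NULL, cls = NULL) {
  if (inherits(mask, "label_volume")) {
    spacing <- mask$spacing
    mask <- if (is.null(cls)) mask$labels != 0 else mask$labels == cls
  }
  sum(mask != 0) * prod(spacing) / 1000
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean of estimate minus reference) and 95% limits of agreement
#' (bias plus/minus 1.96 times the SD of the differences).
#'
#' @param reference,estimate paired numeric vectors (>= 2 pairs).
#' @return named numeric: bias, loa_low, loa_high.
#' @export
bland_altman <- function(reference, estimate) {
  if (length(reference) != length(estimate) || length(reference) < 2)
    stop("bland_altman: need >= 2 pairs")
  d <- estimate - reference
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Pearson correlation of paired measurements
#'
#' @param reference,estimate paired numeric vectors with nonzero
#'   variance.
#' @export
pearson_r <- function(reference, estimate) {
  if (length(reference) != length(estimate) || length(reference) < 2)
    stop("pearson_r: need >= 2 pairs")
  if (stats::sd(reference) == 0 || stats::sd(estimate) == 0) {
    warning("pearson_r: zero variance, undefined")
    return(NA_real_)
  }
  stats::cor(reference, estimate)
}

#' Full metric report for a prediction
#'
#' Per-class (LA, EAT) and mean Dice/IoU/precision/recall/F1, surface
#' distances (mm) and volumes (mL); the mean excludes background.
#'
#' @param pred,truth \code{\link{label_volume}} objects.
#' @param hd_percentile percentile for the Hausdorff distance.
#' @return a data.frame with one row per class plus a \code{"mean"} row.
#' @export
metric_report <- function(pred, truth, hd_percentile = 100) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"))
  sp <- truth$spacing
  rows <- lapply(c(LA = 1L, EAT = 2L), function(cl) {
    cm <- confusion_metrics(pred, truth, cl)
    a <- pred$labels == cl
    b <- truth$labels == cl
    hd <- suppressWarnings(hausdorff_distance(a, b, sp, hd_percentile))
    as_ <- suppressWarnings(assd(a, b, sp))
    data.frame(t(cm), hd = hd, assd = as_,
               volume_ml_pred = volume_ml(a, sp),
               volume_ml_truth = volume_ml(b, sp))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, mean = colMeans(out))
  cbind(class = c("LA", "EAT", "mean"), out)
}
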