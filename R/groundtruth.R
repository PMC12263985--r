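# Semi-automatic EAT reference labels: normalize the fat-fraction map,
# keep voxels whose fat fraction exceeds a threshold (default 0.4), and
# intersect with a manually drawn fat ROI.

#' Normalize a fat-fraction map
#'
#' Divides by the grid maximum so values lie in \code{[0, 1]}; an
#' all-zero grid is returned unchanged.
#'
#' @param raw non-negative 3D numeric array.
#' @param spacing mm per axis (kept with the map).
#' @return object of class \code{"fat_fraction_map"}.
#' @export
normalize_fat_fraction <- function(raw, spacing = c(1, 1, 1)) {
  if (any(!is.finite(raw))) stop("normalize_fat_fraction: non-finite input")
  if (min(raw) < 0) stop("normalize_fat_fraction: negative values")
  mx <- max(raw)
  vals <- if (mx > 0) raw / mx else raw
  structure(list(values = vals, spacing = as.numeric(spacing)),
            class = "fat_fraction_map")
}

#' Threshold the fat-fraction map
#'
#' Voxels with fat fraction strictly exceeding \code{thr} are retained
#' (a voxel exactly at the threshold is excluded).
#'
#' @param ff a \code{\link{normalize_fat_fraction}} map or a plain array
#'   already in \code{[0, 1]}.
#' @param thr threshold in \code{[0, 1]}, default 0.4.
#' @param strict use strict \code{>} (default); \code{FALSE} uses
#'   \code{>=}.
#' @return binary integer array.
#' @export
threshold_eat <- function(ff, thr = 0.4, strict = TRUE) {
  if (!is.numeric(thr) || thr < 0 || thr > 1)
    stop("threshold_eat: threshold must be in [0, 1]")
  vals <- if (inherits(ff, "fat_fraction_map")) ff$values else ff
  keep <- if (strict) vals > thr else vals >= thr
  array(as.integer(keep), dim(vals))
}

#' Intersect the thresholded mask with a fat ROI
#'
#' Voxel-wise AND (product) of the threshold mask and the manual /
#' supplied region of interest.
#'
#' @param eat_mask binary array from \code{\link{threshold_eat}}.
#' @param roi binary array of the same shape.
#' @return binary integer array.
#' @export
combine_with_roi <- function(eat_mask, roi) {
  if (!identical(dim(eat_mask), dim(roi)))
    stop("combine_with_roi: shape mismatch")
  array(as.integer((eat_mask != 0) & (roi != 0)), dim(eat_mask))
}

#' Full semi-automatic EAT ground-truth pipeline
#'
#' Normalization, thresholding at \code{thr}, and ROI intersection in
#' one call.
#'
#' @param raw_ff raw fat-fraction array (any non-negative scale).
#' @param roi binary ROI array.
#' @param thr fat-fraction threshold, default 0.4.
#' @export
make_eat_groundtruth <- function(raw_ff, roi, thr = 0.4) {
  ff <- normalize_fat_fraction(raw_ff)
  combine_with_roi(threshold_eat(ff, thr), roi)
}
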