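#' Spacing-aware multi-channel 3D image
#'
#' Bundles co-registered \code{water}, \code{fat} and \code{fat_fraction}
#' 3D arrays with their voxel spacing in mm.  All channels must share one
#' shape; the fat fraction is expected in \code{[0, 1]}.
#'
#' @param water,fat,fat_fraction 3D numeric arrays of identical shape.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @return an object of class \code{"seg_volume"}.
#' @export
seg_volume <- function(water, fat, fat_fraction, spacing) {
  dm <- dim(water)
  if (length(dm) != 3) stop("seg_volume: channels must be 3D arrays")
  if (!identical(dm, dim(fat)) || !identical(dm, dim(fat_fraction)))
    stop("seg_volume: channel shape mismatch")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("seg_volume: spacing must be 3 positive numbers")
  if (min(fat_fraction) < -1e-9 || max(fat_fraction) > 1 + 1e-9)
    stop("seg_volume: fat_fraction outside [0, 1]")
  structure(list(channels = list(water = water, fat = fat,
                                 fat_fraction = fat_fraction),
                 spacing = spacing),
            class = "seg_volume")
}

#' Three-class label grid
#'
#' Integer 3D grid over \{0 = background, 1 = LA, 2 = EAT\} with voxel
#' spacing in mm.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @param spacing numeric length-3, mm per axis.
#' @export
label_volume <- function(labels, spacing) {
  if (length(dim(labels)) != 3) stop("label_volume: labels must be 3D")
  if (!all(labels %in% 0:2))
    stop("label_volume: labels must be in {0, 1, 2}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("label_volume: spacing must be 3 positive numbers")
  structure(list(labels = labels, spacing = spacing),
            class = "label_volume")
}

#' Channel-vector field over a 3D lattice
#'
#' Internal currency of the networks: an (nvox x channels) matrix in
#' voxel-major order (x fastest) plus the lattice dims.  Hyperbolic
#' fields carry the curvature under which their channel vectors satisfy
#' the ball invariant \eqn{k\|v\|^2 < 1}.
#'
#' @param data (nvox x channels) numeric matrix.
#' @param dims integer length-3 lattice dims (nx, ny, nz).
#' @param space \code{"euclidean"} or \code{"hyperbolic"}.
#' @param curvature positive curvature, required iff hyperbolic.
#' @export
feature_field <- function(data, dims,
                          space = c("euclidean", "hyperbolic"),
                          curvature = NULL) {
  space <- match.arg(space)
  dims <- as.integer(dims)
  if (length(dims) != 3 || nrow(data) != prod(dims))
    stop("feature_field: data rows do not match dims")
  if (space == "hyperbolic") {
    if (is.null(curvature)) stop("feature_field: hyperbolic needs curvature")
    if (any(curvature * rowSums(data^2) >= 1))
      stop("feature_field: ball invariant violated")
  }
  structure(list(data = data, dims = dims, space = space,
                 curvature = curvature),
            class = "feature_field")
}

# seg_volume -> (nvox x 3) matrix in documented channel order.
volume_to_matrix <- function(v) {
  cbind(water = as.vector(v$channels$water),
        fat = as.vector(v$channels$fat),
        fat_fraction = as.vector(v$channels$fat_fraction))
}

matrix_to_array <- function(m, dims) array(m, dim = dims)
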