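# Synthetic Dixon phantom: an ellipsoidal LA blood pool with a thin
# wall, a patchy high-fat EAT rind on the wall, distractor fat blobs far
# from the LA, and a water-dominant background.  Water/fat signal pairs
# per tissue are chosen so that fat-fraction thresholding semantics hold
# (EAT well above the 0.4 threshold, blood/background well below).

.TISSUE_SIGNALS <- list(blood = c(water = 1.0, fat = 0.05),
                        wall = c(water = 0.8, fat = 0.1),
                        eat = c(water = 0.15, fat = 0.9),
                        distractor = c(water = 0.1, fat = 0.95),
                        background = c(water = 0.4, fat = 0.2))

#' Phantom configuration
#'
#' Defaults emulate the acquisition geometry of a 1.5T LGE Dixon scan:
#' voxel spacing 1.25 x 1.25 x 2.5 mm, an LA blood pool of roughly
#' 16 x 14 x 12 mm semi-axes with a 2.5 mm wall, an EAT rind covering
#' ~40% of the wall surface at 3.75 mm thickness, a few distractor fat
#' blobs at >= 10 mm from the LA surface, and mild Gaussian noise.
#'
#' @param shape grid dims, default \code{c(64, 64, 64)}.
#' @param spacing mm per axis, default \code{c(1.25, 1.25, 2.5)}.
#' @param la_radii ellipsoid semi-axes of the blood pool in mm.
#' @param wall_thickness LA wall thickness in mm.
#' @param eat_fraction_of_wall fraction of the wall surface covered by
#'   EAT patches, in \code{[0, 1]}.
#' @param eat_thickness EAT rind thickness in mm.
#' @param distractor_count number of far-from-LA fat blobs.
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the
#'   unit signal scale.
#' @param seed integer RNG seed.
#' @export
phantom_config <- function(shape = c(64, 64, 64),
                           spacing = c(1.25, 1.25, 2.5),
                           la_radii = c(16, 14, 12),
                           wall_thickness = 2.5,
                           eat_fraction_of_wall = 0.4,
                           eat_thickness = 3.75,
                           distractor_count = 3,
                           noise_sigma = 0.03,
                           seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("phantom_config: spacing must be positive")
  if (any(shape < 8)) stop("phantom_config: grid too small")
  if (eat_fraction_of_wall < 0 || eat_fraction_of_wall > 1)
    stop("phantom_config: eat_fraction_of_wall must be in [0, 1]")
  if (noise_sigma < 0) stop("phantom_config: negative noise")
  half_extent <- shape * spacing / 2
  outer <- la_radii + wall_thickness + eat_thickness
  if (any(outer >= 0.95 * half_extent))
    stop("phantom_config: LA geometry does not fit the grid")
  structure(list(shape = shape, spacing = spacing, la_radii = la_radii,
                 wall_thickness = wall_thickness,
                 eat_fraction_of_wall = eat_fraction_of_wall,
                 eat_thickness = eat_thickness,
                 distractor_count = as.integer(distractor_count),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

# World mm coordinates of voxel centers, centered on the grid.
phantom_coords <- function(shape, spacing) {
  lapply(1:3, function(ax)
    (seq_len(shape[ax]) - (shape[ax] + 1) / 2) * spacing[ax])
}

# Normalized ellipsoid radius field for semi-axes r (mm).
ellipsoid_rho <- function(coords, r) {
  nx <- length(coords[[1]]); ny <- length(coords[[2]])
  nz <- length(coords[[3]])
  x2 <- (coords[[1]] / r[1])^2
  y2 <- (coords[[2]] / r[2])^2
  z2 <- (coords[[3]] / r[3])^2
  sqrt(outer(outer(x2, y2, `+`), z2, `+`))
}

#' Generate one synthetic Dixon phantom
#'
#' Deterministic given \code{cfg$seed}.  Returns co-registered water,
#' fat and fat-fraction channels plus the 3-class label grid
#' (0 background, 1 LA = blood pool and wall, 2 EAT).  Pre-noise, every
#' EAT voxel has fat fraction above the 0.4 threshold; the fat fraction
#' is recomputed as \code{fat/(fat+water+1e-8)} from the noisy channels
#' and clipped to \code{[0, 1]}.
#'
#' @param cfg a \code{\link{phantom_config}}.
#' @return list of class \code{"phantom_sample"} with \code{volume}
#'   (\code{\link{seg_volume}}), \code{labels}
#'   (\code{\link{label_volume}}) and \code{config}.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  set.seed(cfg$seed)
  dm <- cfg$shape
  co <- phantom_coords(dm, cfg$spacing)
  rho_in <- ellipsoid_rho(co, cfg$la_radii)
  rho_wall <- ellipsoid_rho(co, cfg$la_radii + cfg$wall_thickness)
  rho_eat <- ellipsoid_rho(co, cfg$la_radii + cfg$wall_thickness +
                             cfg$eat_thickness)
  blood <- rho_in <= 1
  wall <- !blood & rho_wall <= 1
  shell <- !blood & !wall & rho_eat <= 1

  # patchy EAT: keep the fraction of shell voxels with the highest
  # low-frequency angular score
  eat <- array(FALSE, dm)
  if (cfg$eat_fraction_of_wall > 0 && any(shell)) {
    idx <- which(shell)
    pos <- arrayInd(idx, dm)
    dir <- cbind(co[[1]][pos[, 1]], co[[2]][pos[, 2]], co[[3]][pos[, 3]])
    dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
    score <- numeric(length(idx))
    for (j in 1:4) {
      e <- stats::rnorm(3); e <- e / sqrt(sum(e^2))
      om <- stats::runif(1, 2, 5)
      ph <- stats::runif(1, 0, 2 * pi)
      score <- score + cos(om * (dir %*% e) + ph)
    }
    keep <- score >= stats::quantile(score, 1 - cfg$eat_fraction_of_wall)
    eat[idx[keep]] <- TRUE
  }

  labels <- array(0L, dm)
  labels[blood | wall] <- 1L
  labels[eat] <- 2L

  water <- array(.TISSUE_SIGNALS$background["water"], dm)
  fat <- array(.TISSUE_SIGNALS$background["fat"], dm)
  # smooth background modulation (+-10%)
  modx <- 1 + 0.1 * sin(2 * pi * seq_len(dm[1]) / dm[1])
  modz <- 1 + 0.1 * cos(2 * pi * seq_len(dm[3]) / dm[3])
  mod <- outer(outer(modx, rep(1, dm[2])), modz)
  water <- water * mod
  fat <- fat * mod
  assign_tissue <- function(mask, sig) {
    water[mask] <<- sig["water"]
    fat[mask] <<- sig["fat"]
  }
  assign_tissue(blood, .TISSUE_SIGNALS$blood)
  assign_tissue(wall, .TISSUE_SIGNALS$wall)
  assign_tissue(eat, .TISSUE_SIGNALS$eat)

  # distractor fat blobs, >= 10 mm from the LA surface, labeled background
  if (cfg$distractor_count > 0) {
    la_d <- sqrt(.edt_sq(as.vector(labels > 0), as.integer(dm),
                         cfg$spacing))
    placed <- 0
    tries <- 0
    while (placed < cfg$distractor_count && tries < 200) {
      tries <- tries + 1
      ctr <- sapply(dm, function(n) sample.int(n, 1))
      r_blob <- stats::runif(1, 3, 6)
      i <- ctr[1] + dm[1] * ((ctr[2] - 1) + dm[2] * (ctr[3] - 1))
      if (la_d[i] < 10 + r_blob) next
      dx2 <- ((co[[1]] - co[[1]][ctr[1]]) / r_blob)^2
      dy2 <- ((co[[2]] - co[[2]][ctr[2]]) / r_blob)^2
      dz2 <- ((co[[3]] - co[[3]][ctr[3]]) / r_blob)^2
      blob <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
      blob <- blob & labels == 0L
      assign_tissue(blob, .TISSUE_SIGNALS$distractor)
      placed <- placed + 1
    }
  }

  if (cfg$noise_sigma > 0) {
    water <- water + array(stats::rnorm(prod(dm), sd = cfg$noise_sigma), dm)
    fat <- fat + array(stats::rnorm(prod(dm), sd = cfg$noise_sigma), dm)
    water <- pmax(water, 0)
    fat <- pmax(fat, 0)
  }
  ff <- fat / (fat + water + 1e-8)
  ff <- pmin(pmax(ff, 0), 1)
  structure(list(volume = seg_volume(water, fat, ff, cfg$spacing),
                 labels = label_volume(labels, cfg$spacing),
                 config = cfg),
            class = "phantom_sample")
}

#' Generate a dataset of phantoms
#'
#' \code{n} samples with per-sample derived seeds and geometry
#' parameters jittered by +-20% around the base configuration.
#'
#' @param n number of samples.
#' @param cfg base \code{\link{phantom_config}}.
#' @param seed master seed; the same master seed reproduces the same
#'   dataset.
#' @return list of \code{"phantom_sample"} objects.
#' @export
generate_dataset <- function(n, cfg = phantom_config(), seed = 1L) {
  if (n < 1) stop("generate_dataset: n must be >= 1")
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  jit <- matrix(stats::runif(n * 4, 0.8, 1.2), n, 4)
  lapply(seq_len(n), function(i) {
    ci <- cfg
    ci$la_radii <- cfg$la_radii * jit[i, 1]
    ci$wall_thickness <- cfg$wall_thickness * jit[i, 2]
    ci$eat_thickness <- cfg$eat_thickness * jit[i, 3]
    ci$eat_fraction_of_wall <-
      min(1, cfg$eat_fraction_of_wall * jit[i, 4])
    ci$seed <- sample_seeds[i]
    generate_phantom(ci)
  })
}

#' Balanced patch sampling
#'
#' Alternates patch centers between EAT, LA and background voxels so
#' minority classes appear in every mini-batch; patches are clipped to
#' the grid.  Deterministic given \code{seed}.
#'
#' @param s a \code{"phantom_sample"} (or any list with \code{volume}
#'   and \code{labels}).
#' @param patch cube edge in voxels.
#' @param n number of patches.
#' @param seed RNG seed.
#' @return list of lists with \code{volume} and \code{labels} patches.
#' @export
sample_balanced_patches <- function(s, patch, n, seed = 1L) {
  dm <- dim(s$labels$labels)
  patch <- as.integer(patch)
  if (any(patch > dm)) stop("sample_balanced_patches: patch exceeds grid")
  set.seed(seed)
  class_cycle <- c(2L, 1L, 0L)
  vox_by_class <- lapply(0:2, function(cl) which(s$labels$labels == cl))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- class_cycle[((i - 1L) %% 3L) + 1L]
    pool <- vox_by_class[[cl + 1L]]
    if (length(pool) == 0) pool <- seq_len(prod(dm))
    ctr <- arrayInd(pool[sample.int(length(pool), 1)], dm)
    lo <- pmin(pmax(as.integer(ctr) - patch %/% 2L, 1L), dm - patch + 1L)
    hi <- lo + patch - 1L
    sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                         drop = FALSE]
    v <- s$volume
    out[[i]] <- list(
      volume = seg_volume(sub(v$channels$water), sub(v$channels$fat),
                          sub(v$channels$fat_fraction), v$spacing),
      labels = label_volume(sub(s$labels$labels), s$labels$spacing))
  }
  out
}

#' Random flip / rotation / scaling augmentation
#'
#' Axis flips, in-plane 90-degree rotations and isotropic scaling in
#' \code{[0.9, 1.1]} with nearest-neighbor label resampling; labels stay
#' in \{0, 1, 2\}.  When \code{seed} is given the transform is drawn
#' from it; explicit arguments override the draw (all-identity
#' arguments give the identity transform).
#'
#' @param volume a \code{\link{seg_volume}} patch.
#' @param labels matching \code{\link{label_volume}}.
#' @param seed RNG seed, or \code{NULL} with explicit arguments.
#' @param flips logical length-3: flip each axis.
#' @param rot in-plane rotation count (0-3 quarter turns in the xy
#'   plane; applied only when nx == ny).
#' @param scale isotropic scale factor about the patch center.
#' @return list with transformed \code{volume} and \code{labels}.
#' @export
augment_patch <- function(volume, labels, seed = NULL, flips = NULL,
                          rot = NULL, scale = NULL) {
  dm <- dim(labels$labels)
  if (!is.null(seed)) {
    set.seed(seed)
    if (is.null(flips)) flips <- stats::runif(3) < 0.5
    if (is.null(rot)) rot <- sample(0:3, 1)
    if (is.null(scale)) scale <- stats::runif(1, 0.9, 1.1)
  }
  if (is.null(flips)) flips <- c(FALSE, FALSE, FALSE)
  if (is.null(rot)) rot <- 0L
  if (is.null(scale)) scale <- 1
  # build the source index per axis (nearest-neighbor scaling)
  src_index <- function(n, s) {
    ctr <- (n + 1) / 2
    i <- round((seq_len(n) - ctr) / s + ctr)
    pmin(pmax(i, 1L), n)
  }
  ix <- src_index(dm[1], scale)
  iy <- src_index(dm[2], scale)
  iz <- src_index(dm[3], scale)
  tf <- function(a) {
    a <- a[ix, iy, iz, drop = FALSE]
    if (flips[1]) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
    if (flips[2]) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
    if (flips[3]) a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
    if (rot %% 4L != 0L && dim(a)[1] == dim(a)[2]) {
      for (r in seq_len(rot %% 4L)) {
        a <- aperm(a, c(2, 1, 3))
        a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
      }
    }
    a
  }
  v <- volume
  list(volume = seg_volume(tf(v$channels$water), tf(v$channels$fat),
                           tf(v$channels$fat_fraction), v$spacing),
       labels = label_volume(tf(labels$labels), labels$spacing))
}
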