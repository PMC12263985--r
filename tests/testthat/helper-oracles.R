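# Shared fixtures and independent oracles, all built in code.

# central-difference numeric gradient
numgrad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# brute-force direct 3D convolution (kernel 3, pad 1) on small arrays
naive_conv3d <- function(xarr, warr, bias) {
  dm <- dim(xarr)[1:3]; cin <- dim(xarr)[4]; cout <- dim(warr)[5]
  out <- array(0, c(dm, cout))
  for (co in 1:cout) for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    s <- bias[co]
    for (ci in 1:cin) for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      xi <- x + dx; yi <- y + dy; zi <- z + dz
      if (xi >= 1 && xi <= dm[1] && yi >= 1 && yi <= dm[2] &&
          zi >= 1 && zi <= dm[3])
        s <- s + xarr[xi, yi, zi, ci] * warr[dx + 2, dy + 2, dz + 2, ci, co]
    }
    out[x, y, z, co] <- s
  }
  out
}

# all-pairs minimum distance from each voxel to a set of voxels (mm)
brute_min_dist <- function(from_idx, to_idx, spacing) {
  vapply(seq_len(nrow(from_idx)), function(i) {
    diff <- sweep(to_idx, 2, as.numeric(from_idx[i, ]))
    min(sqrt(rowSums(sweep(diff, 2, spacing, `*`)^2)))
  }, numeric(1))
}

# 6-connectivity surface voxels, independent implementation
brute_surface <- function(mask) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  idx <- which(mask != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    on_edge <- any(v == 1) || any(v == dm)
    if (!on_edge) {
      nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                  v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
      on_edge <- any(mask[nb] == 0)
    }
    if (on_edge) out[v[1], v[2], v[3]] <- TRUE
  }
  out
}

brute_hausdorff <- function(a, b, spacing) {
  sa <- which(brute_surface(a), arr.ind = TRUE)
  sb <- which(brute_surface(b), arr.ind = TRUE)
  max(max(brute_min_dist(sa, sb, spacing)),
      max(brute_min_dist(sb, sa, spacing)))
}

brute_assd <- function(a, b, spacing) {
  sa <- which(brute_surface(a), arr.ind = TRUE)
  sb <- which(brute_surface(b), arr.ind = TRUE)
  (mean(brute_min_dist(sa, sb, spacing)) +
     mean(brute_min_dist(sb, sa, spacing))) / 2
}

# random point strictly inside the ball of curvature k
rand_ball_point <- function(n, k, max_frac = 0.9) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2)) * stats::runif(1, 0, max_frac) / sqrt(k)
}

# tiny phantom configuration that fits a 24^3 grid
tiny_phantom_config <- function(seed = 1L, shape = c(24, 24, 24),
                                noise_sigma = 0.03) {
  phantom_config(shape = shape, la_radii = c(8, 7, 6),
                 wall_thickness = 2, eat_thickness = 3,
                 distractor_count = 1, noise_sigma = noise_sigma,
                 seed = seed)
}

# tiny network configs for gradient checks; biases are jittered away from
# zero so that no pre-activation sits exactly on the ReLU kink (the
# analytic subgradient and a central difference disagree there)
tiny_poinunet <- function(seed = 3, ...) {
  cfg <- model_config(base_channels = 2, depth = 2, patch_size = 4, ...)
  model <- build_poinunet(cfg, seed = seed)
  set.seed(seed + 100)
  for (nm in names(model$params))
    if (grepl("\\.b", nm))
      model$params[[nm]] <- model$params[[nm]] +
        stats::rnorm(length(model$params[[nm]]), sd = 0.05)
  model
}

tiny_stage1 <- function(seed = 4) {
  cfg <- model_config(base_channels = 2, depth = 2, num_classes = 2,
                      patch_size = 4)
  model <- build_stage1_unet(cfg, seed = seed)
  set.seed(seed + 100)
  for (nm in names(model$params))
    if (grepl("\\.b", nm))
      model$params[[nm]] <- model$params[[nm]] +
        stats::rnorm(length(model$params[[nm]]), sd = 0.05)
  model
}

# internal helpers used across tests
hs <- asNamespace("hyperseg")
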