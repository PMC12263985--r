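#' Network configuration
#'
#' @param base_channels width of the first encoder stage (default 8).
#' @param depth number of resolution levels (default 3: two pooling
#'   stages plus a bottleneck).
#' @param num_classes number of output classes (3: background/LA/EAT).
#' @param patch_size training patch edge in voxels; must be divisible by
#'   \code{2^(depth-1)}.
#' @param use_hyperbolic_attention gate the hyperbolic branch with
#'   neighborhood attention weights (experimental, default off).
#' @param manifold a \code{\link{manifold_params}} object.
#' @export
model_config <- function(base_channels = 8, depth = 3, num_classes = 3,
                         patch_size = 96,
                         use_hyperbolic_attention = FALSE,
                         manifold = manifold_params()) {
  if (base_channels < 1 || depth < 2) stop("model_config: invalid size")
  if (patch_size %% 2^(depth - 1) != 0)
    stop("model_config: patch_size must be divisible by 2^(depth-1)")
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 num_classes = as.integer(num_classes),
                 patch_size = as.integer(patch_size),
                 use_hyperbolic_attention = isTRUE(use_hyperbolic_attention),
                 manifold = manifold),
            class = "model_config")
}

# He-style initialization for a (27*Cin x Cout) conv weight.
init_conv_w <- function(cin, cout) {
  matrix(stats::rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
         27 * cin, cout)
}

enc_widths <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth - 1) - 1)

#' Build the Stage-1 ROI 3D U-Net
#'
#' A plain 3D U-Net (conv blocks + MaxPool encoder, nearest-neighbor
#' upsampling + skip concatenation decoder, 1x1x1 output head) that maps
#' the fat channel to a 2-class foreground/background voxel map used for
#' region-of-interest localization.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param seed RNG seed for weight initialization.
#' @return a model object (list with \code{params}, \code{kind},
#'   \code{config}, \code{stage}).
#' @export
build_stage1_unet <- function(cfg = model_config(num_classes = 2),
                              seed = 1L) {
  set.seed(seed)
  w <- enc_widths(cfg)
  L <- cfg$depth - 1
  params <- list()
  kind <- character()
  cin <- 1L
  for (l in seq_len(L)) {
    params[[paste0("enc", l, ".W")]] <- init_conv_w(cin, w[l])
    params[[paste0("enc", l, ".b")]] <- numeric(w[l])
    cin <- w[l]
  }
  wb <- 2L * w[L]
  params[["bott.W"]] <- init_conv_w(w[L], wb)
  params[["bott.b"]] <- numeric(wb)
  deep <- wb
  for (l in rev(seq_len(L))) {
    params[[paste0("dec", l, ".Wup")]] <- init_conv_w(deep, w[l])
    params[[paste0("dec", l, ".bup")]] <- numeric(w[l])
    params[[paste0("dec", l, ".Wm")]] <- init_conv_w(2L * w[l], w[l])
    params[[paste0("dec", l, ".bm")]] <- numeric(w[l])
    deep <- w[l]
  }
  params[["head.W"]] <- matrix(stats::rnorm(w[1] * 2, sd = sqrt(1 / w[1])),
                               w[1], 2)
  params[["head.b"]] <- numeric(2)
  kind <- setNames(rep("euclid", length(params)), names(params))
  structure(list(stage = 1L, config = cfg, params = params, kind = kind,
                 version = "hyperseg-ckpt-1"),
            class = "hyperseg_model")
}

#' Build the Stage-2 hyperbolic segmentation network
#'
#' Encoder of dual Euclidean/hyperbolic blocks (shared conv stem,
#' parallel Moebius-convolution branch, channel concatenation, 2x
#' MaxPool), a Euclidean bottleneck and decoder with skip connections,
#' and a final Poincare embedding + hyperbolic multinomial logistic
#' regression head over the three classes.  Inputs are the water, fat
#' and fat-fraction channels.
#'
#' @param cfg a \code{\link{model_config}}.
#' @param seed RNG seed for weight initialization.
#' @export
build_poinunet <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  w <- enc_widths(cfg)
  L <- cfg$depth - 1
  params <- list()
  kind <- character()
  cin <- 3L
  for (l in seq_len(L)) {
    params[[paste0("enc", l, ".We")]] <- init_conv_w(cin, w[l])
    params[[paste0("enc", l, ".be")]] <- numeric(w[l])
    params[[paste0("enc", l, ".Wh")]] <- init_conv_w(w[l], w[l])
    params[[paste0("enc", l, ".bh")]] <- numeric(w[l])
    kind[paste0("enc", l, c(".We", ".be", ".Wh"))] <- "euclid"
    kind[paste0("enc", l, ".bh")] <- "ball"
    cin <- 2L * w[l]
  }
  wb <- 2L * w[L]
  params[["bott.W"]] <- init_conv_w(wb, wb)
  params[["bott.b"]] <- numeric(wb)
  kind[c("bott.W", "bott.b")] <- "euclid"
  deep <- wb
  for (l in rev(seq_len(L))) {
    params[[paste0("dec", l, ".Wup")]] <- init_conv_w(deep, w[l])
    params[[paste0("dec", l, ".bup")]] <- numeric(w[l])
    params[[paste0("dec", l, ".Wm")]] <- init_conv_w(3L * w[l], w[l])
    params[[paste0("dec", l, ".bm")]] <- numeric(w[l])
    kind[paste0("dec", l, c(".Wup", ".bup", ".Wm", ".bm"))] <- "euclid"
    deep <- w[l]
  }
  nfeat <- w[1]
  for (ci in seq_len(cfg$num_classes)) {
    params[[paste0("head.p", ci)]] <- numeric(nfeat)
    params[[paste0("head.a", ci)]] <-
      stats::rnorm(nfeat, sd = sqrt(1 / nfeat))
    params[[paste0("head.zeta", ci)]] <- 1
    kind[paste0("head.p", ci)] <- "ball"
    kind[c(paste0("head.a", ci), paste0("head.zeta", ci))] <- "euclid"
  }
  params[["sigma"]] <- cfg$manifold$sigma
  kind["sigma"] <- "sigma"
  structure(list(stage = 2L, config = cfg, params = params, kind = kind,
                 version = "hyperseg-ckpt-1"),
            class = "hyperseg_model")
}

current_manifold <- function(model) {
  m <- model$config$manifold
  m$sigma <- model$params$sigma
  m
}

## ---------------------------------------------------------------------
## Stage-1 forward/backward

stage1_fw <- function(model, x, dims) {
  p <- model$params
  L <- model$config$depth - 1
  caches <- list()
  skips <- list()
  cur <- x; cdims <- dims
  for (l in seq_len(L)) {
    cb <- conv_block_fw(cur, cdims, p[[paste0("enc", l, ".W")]],
                        p[[paste0("enc", l, ".b")]])
    mp <- .maxpool2_fw(cb$y, cdims)
    caches[[paste0("enc", l)]] <-
      list(cb = cb, argmax = mp$argmax, nvox = nrow(cb$y), dims = cdims)
    skips[[l]] <- cb$y
    cur <- mp$y; cdims <- cdims %/% 2L
  }
  bott <- conv_block_fw(cur, cdims, p[["bott.W"]], p[["bott.b"]])
  caches[["bott"]] <- bott
  cur <- bott$y
  for (l in rev(seq_len(L))) {
    up <- .upsample2_fw(cur, cdims)
    cdims <- cdims * 2L
    cu <- conv_block_fw(up, cdims, p[[paste0("dec", l, ".Wup")]],
                        p[[paste0("dec", l, ".bup")]])
    cat_in <- cbind(cu$y, skips[[l]])
    cm <- conv_block_fw(cat_in, cdims, p[[paste0("dec", l, ".Wm")]],
                        p[[paste0("dec", l, ".bm")]])
    caches[[paste0("dec", l)]] <-
      list(cu = cu, cm = cm, dims_small = cdims %/% 2L,
           wch = ncol(cu$y))
    cur <- cm$y
  }
  logits <- cur %*% p[["head.W"]] +
    matrix(p[["head.b"]], nrow(cur), 2, byrow = TRUE)
  caches[["head"]] <- list(feat = cur)
  list(logits = logits, caches = caches)
}

stage1_bw <- function(model, fwd, glogits) {
  p <- model$params
  L <- model$config$depth - 1
  g <- list()
  feat <- fwd$caches[["head"]]$feat
  g[["head.W"]] <- crossprod(feat, glogits)
  g[["head.b"]] <- colSums(glogits)
  cur <- glogits %*% t(p[["head.W"]])
  gskips <- vector("list", L)
  for (l in seq_len(L)) {
    dc <- fwd$caches[[paste0("dec", l)]]
    cmb <- conv_block_bw(dc$cm$cache, cur)
    g[[paste0("dec", l, ".Wm")]] <- cmb$gw
    g[[paste0("dec", l, ".bm")]] <- cmb$gb
    gcu <- cmb$gx[, seq_len(dc$wch), drop = FALSE]
    gskips[[l]] <- cmb$gx[, dc$wch + seq_len(ncol(cmb$gx) - dc$wch),
                          drop = FALSE]
    cub <- conv_block_bw(dc$cu$cache, gcu)
    g[[paste0("dec", l, ".Wup")]] <- cub$gw
    g[[paste0("dec", l, ".bup")]] <- cub$gb
    cur <- .upsample2_bw(cub$gx, dc$dims_small)
  }
  bb <- conv_block_bw(fwd$caches[["bott"]]$cache, cur)
  g[["bott.W"]] <- bb$gw
  g[["bott.b"]] <- bb$gb
  cur <- bb$gx
  for (l in rev(seq_len(L))) {
    ec <- fwd$caches[[paste0("enc", l)]]
    gpre <- .maxpool2_bw(cur, ec$argmax, ec$nvox) + gskips[[l]]
    cb <- conv_block_bw(ec$cb$cache, gpre)
    g[[paste0("enc", l, ".W")]] <- cb$gw
    g[[paste0("enc", l, ".b")]] <- cb$gb
    cur <- cb$gx
  }
  g
}

## ---------------------------------------------------------------------
## Stage-2 forward/backward

# Box-mean convolution weights for C channels (fixed, not learned).
box_mean_w <- function(c) {
  w <- matrix(0, 27 * c, c)
  for (ci in seq_len(c)) w[(ci - 1) * 27 + (1:27), ci] <- 1 / 27
  w
}

# Neighborhood attention on tangent features: per-voxel gate
# sigmoid(-msd) where msd is the mean squared tangent distance to the
# 3^3 neighborhood.
attn_fw <- function(tfeat, dims) {
  c <- ncol(tfeat)
  wb <- box_mean_w(c)
  w1 <- box_mean_w(1L)
  n2 <- matrix(rowSums(tfeat^2), ncol = 1)
  tb <- .conv3d_fw(tfeat, dims, wb, numeric(c))
  n2b <- .conv3d_fw(n2, dims, w1, 0)
  msd <- as.vector(n2) + as.vector(n2b) - 2 * rowSums(tfeat * tb)
  att <- 1 / (1 + exp(pmin(msd, 50)))
  list(y = tfeat * att,
       cache = list(tfeat = tfeat, tb = tb, att = att, dims = dims,
                    wb = wb, w1 = w1))
}

attn_bw <- function(cache, gout) {
  tf <- cache$tfeat; att <- cache$att; dims <- cache$dims
  gatt <- rowSums(gout * tf)
  gmsd <- -gatt * att * (1 - att)
  boxv <- function(v) as.vector(.conv3d_fw(matrix(v, ncol = 1), dims,
                                           cache$w1, 0))
  boxm <- function(m) .conv3d_fw(m, dims, cache$wb, numeric(ncol(m)))
  gtf <- gout * att +
    2 * tf * gmsd +
    2 * tf * boxv(gmsd) -
    2 * cache$tb * gmsd -
    2 * boxm(tf * gmsd)
  gtf
}

stage2_fw <- function(model, x, dims) {
  p <- model$params
  cfg <- model$config
  L <- cfg$depth - 1
  m <- current_manifold(model)
  k <- curvature_value(m)
  eps <- m$eps_ball
  caches <- list()
  skips <- list()
  cur <- x; cdims <- dims
  for (l in seq_len(L)) {
    if (cfg$use_hyperbolic_attention) {
      db <- dual_block_attn_fw(cur, cdims, p[[paste0("enc", l, ".We")]],
                               p[[paste0("enc", l, ".be")]],
                               p[[paste0("enc", l, ".Wh")]],
                               p[[paste0("enc", l, ".bh")]], k, eps)
    } else {
      db <- dual_block_fw(cur, cdims, p[[paste0("enc", l, ".We")]],
                          p[[paste0("enc", l, ".be")]],
                          p[[paste0("enc", l, ".Wh")]],
                          p[[paste0("enc", l, ".bh")]], k, eps)
    }
    caches[[paste0("enc", l)]] <- db
    skips[[l]] <- db$skip
    cur <- db$y; cdims <- db$dims_out
  }
  bott <- conv_block_fw(cur, cdims, p[["bott.W"]], p[["bott.b"]])
  caches[["bott"]] <- bott
  cur <- bott$y
  for (l in rev(seq_len(L))) {
    up <- .upsample2_fw(cur, cdims)
    cdims <- cdims * 2L
    cu <- conv_block_fw(up, cdims, p[[paste0("dec", l, ".Wup")]],
                        p[[paste0("dec", l, ".bup")]])
    cat_in <- cbind(cu$y, skips[[l]])
    cm <- conv_block_fw(cat_in, cdims, p[[paste0("dec", l, ".Wm")]],
                        p[[paste0("dec", l, ".bm")]])
    caches[[paste0("dec", l)]] <-
      list(cu = cu, cm = cm, dims_small = cdims %/% 2L, wch = ncol(cu$y))
    cur <- cm$y
  }
  emb <- exp0_fw(cur, k, eps)
  planes <- lapply(seq_len(cfg$num_classes), function(ci)
    list(offset = project_to_ball(p[[paste0("head.p", ci)]], k, eps),
         normal = p[[paste0("head.a", ci)]],
         zeta = max(p[[paste0("head.zeta", ci)]], 1e-3)))
  hm <- hmlr_fw(emb$y, planes, k)
  caches[["emb"]] <- emb
  caches[["hmlr"]] <- hm
  list(logits = hm$logits, caches = caches, k = k)
}

stage2_bw <- function(model, fwd, glogits) {
  p <- model$params
  cfg <- model$config
  L <- cfg$depth - 1
  g <- list()
  gk <- 0
  hb <- hmlr_bw(fwd$caches[["hmlr"]], glogits)
  gk <- gk + hb$gk
  for (ci in seq_len(cfg$num_classes)) {
    g[[paste0("head.p", ci)]] <- hb$gplanes[[ci]]$offset
    g[[paste0("head.a", ci)]] <- hb$gplanes[[ci]]$normal
    g[[paste0("head.zeta", ci)]] <- hb$gplanes[[ci]]$zeta
  }
  eb <- exp0_bw(fwd$caches[["emb"]]$cache, hb$gz)
  gk <- gk + eb$gk
  cur <- eb$gx
  gskips <- vector("list", L)
  for (l in seq_len(L)) {
    dc <- fwd$caches[[paste0("dec", l)]]
    cmb <- conv_block_bw(dc$cm$cache, cur)
    g[[paste0("dec", l, ".Wm")]] <- cmb$gw
    g[[paste0("dec", l, ".bm")]] <- cmb$gb
    gcu <- cmb$gx[, seq_len(dc$wch), drop = FALSE]
    gskips[[l]] <- cmb$gx[, dc$wch + seq_len(ncol(cmb$gx) - dc$wch),
                          drop = FALSE]
    cub <- conv_block_bw(dc$cu$cache, gcu)
    g[[paste0("dec", l, ".Wup")]] <- cub$gw
    g[[paste0("dec", l, ".bup")]] <- cub$gb
    cur <- .upsample2_bw(cub$gx, dc$dims_small)
  }
  bb <- conv_block_bw(fwd$caches[["bott"]]$cache, cur)
  g[["bott.W"]] <- bb$gw
  g[["bott.b"]] <- bb$gb
  cur <- bb$gx
  for (l in rev(seq_len(L))) {
    db <- fwd$caches[[paste0("enc", l)]]
    bwfun <- if (cfg$use_hyperbolic_attention) dual_block_attn_bw
             else dual_block_bw
    dbb <- bwfun(db$cache, cur, gskips[[l]])
    g[[paste0("enc", l, ".We")]] <- dbb$gWe
    g[[paste0("enc", l, ".be")]] <- dbb$gbe
    g[[paste0("enc", l, ".Wh")]] <- dbb$gWh
    g[[paste0("enc", l, ".bh")]] <- dbb$gbh
    gk <- gk + dbb$gk
    cur <- dbb$gx
  }
  m <- current_manifold(model)
  g[["sigma"]] <- gk * curvature_grad_sigma(m)
  attr(g, "gk") <- gk
  g
}

# Dual encoder block with the attention gate on the tangent features of
# the hyperbolic branch (experimental path).
dual_block_attn_fw <- function(x, dims, We, be, Wh, bh, k, eps = 1e-5) {
  cb <- conv_block_fw(x, dims, We, be)
  em <- exp0_fw(cb$y, k, eps)
  mc <- mconv_fw(em$y, dims, Wh, bh, k, eps)
  lg <- log0_fw(mc$y, k)
  at <- attn_fw(lg$x, dims)
  skip <- cbind(cb$y, at$y)
  mp <- .maxpool2_fw(skip, dims)
  list(y = mp$y, skip = skip, dims_out = dims %/% 2L,
       cache = list(cb = cb, em = em, mc = mc, lg = lg, at = at,
                    argmax = mp$argmax, nvox = nrow(skip), dims = dims))
}

dual_block_attn_bw <- function(cache, gout, gskip = NULL) {
  gcat <- .maxpool2_bw(gout, cache$argmax, cache$nvox)
  if (!is.null(gskip)) gcat <- gcat + gskip
  w <- ncol(cache$cb$y)
  ge <- gcat[, seq_len(w), drop = FALSE]
  gh_att <- gcat[, w + seq_len(w), drop = FALSE]
  gh_tan <- attn_bw(cache$at$cache, gh_att)
  lb <- log0_bw(cache$lg$cache, gh_tan)
  mb <- mconv_bw(cache$mc$cache, lb$gy)
  eb <- exp0_bw(cache$em$cache, mb$gh)
  cb <- conv_block_bw(cache$cb$cache, ge + eb$gx)
  list(gx = cb$gx, gWe = cb$gw, gbe = cb$gb, gWh = mb$gw,
       gbh = mb$gbias, gk = lb$gk + mb$gk + eb$gk)
}

## ---------------------------------------------------------------------
## Inference helpers

# Model forward on a (nvox x C) matrix; returns logits.
model_forward <- function(model, x, dims) {
  if (model$stage == 1L) stage1_fw(model, x, dims)$logits
  else stage2_fw(model, x, dims)$logits
}

#' Crop a volume to the bounding box of a mask
#'
#' Axis-aligned bounding box of the mask's nonzero voxels, expanded by
#' \code{margin} voxels, clipped to the volume, then grown/padded so
#' every side is a multiple of \code{2^(depth-1)} (pooling validity).
#' An empty mask falls back to the full volume.  The returned
#' \code{crop_record} re-embeds predictions exactly into the original
#' grid via \code{\link{uncrop_labels}}.
#'
#' @param v a \code{\link{seg_volume}}.
#' @param mask binary 3D array (or \code{\link{label_volume}} whose
#'   nonzero voxels define the region).
#' @param margin expansion in voxels (default 8).
#' @param depth network depth used for the padding multiple.
#' @return list with the cropped \code{volume} and the \code{crop_record}.
#' @export
crop_to_roi <- function(v, mask, margin = 8L, depth = 3L) {
  if (inherits(mask, "label_volume")) mask <- mask$labels
  dm <- dim(v$channels$water)
  if (!identical(dim(mask), dm)) stop("crop_to_roi: mask shape mismatch")
  mult <- 2L^(depth - 1L)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    lo <- c(1L, 1L, 1L); hi <- dm
  } else {
    lo <- pmax(apply(idx, 2, min) - margin, 1L)
    hi <- pmin(apply(idx, 2, max) + margin, dm)
  }
  # grow each axis to the next multiple of `mult`, staying in bounds
  pad <- integer(3)
  for (ax in 1:3) {
    len <- hi[ax] - lo[ax] + 1L
    want <- as.integer(ceiling(len / mult) * mult)
    extra <- want - len
    lo_room <- lo[ax] - 1L
    hi_room <- dm[ax] - hi[ax]
    take_lo <- min(extra %/% 2L, lo_room)
    take_hi <- min(extra - take_lo, hi_room)
    # if still short, shift remaining onto the other side
    rem <- extra - take_lo - take_hi
    add_lo <- min(rem, lo_room - take_lo)
    take_lo <- take_lo + add_lo
    rem <- rem - add_lo
    lo[ax] <- lo[ax] - take_lo
    hi[ax] <- hi[ax] + take_hi
    pad[ax] <- rem  # zero-padding appended when the volume is too small
  }
  sub <- function(a) {
    s <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (any(pad > 0)) {
      out <- array(0, dim(s) + pad)
      out[seq_len(dim(s)[1]), seq_len(dim(s)[2]), seq_len(dim(s)[3])] <- s
      out
    } else s
  }
  vol <- seg_volume(sub(v$channels$water), sub(v$channels$fat),
                    sub(v$channels$fat_fraction), v$spacing)
  rec <- list(orig_dims = dm, lo = lo, hi = hi, pad = pad)
  list(volume = vol, crop_record = rec)
}

#' Re-embed cropped label predictions into the original grid
#'
#' @param labels 3D integer array predicted on the cropped grid.
#' @param crop_record record returned by \code{\link{crop_to_roi}}.
#' @return 3D integer array of the original shape, background outside
#'   the crop box.
#' @export
uncrop_labels <- function(labels, crop_record) {
  r <- crop_record
  core_dims <- r$hi - r$lo + 1L
  core <- labels[seq_len(core_dims[1]), seq_len(core_dims[2]),
                 seq_len(core_dims[3]), drop = FALSE]
  out <- array(0L, r$orig_dims)
  out[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3]] <- core
  out
}

#' Two-stage segmentation
#'
#' Stage 1 segments a foreground region on the fat channel; its mask is
#' used to crop the volume, and stage 2 segments background/LA/EAT on
#' the cropped water/fat/fat-fraction channels.  Predictions are
#' re-embedded into the full grid with background outside the crop box.
#'
#' @param v a \code{\link{seg_volume}}.
#' @param stage1 stage-1 model, or a binary 3D array used directly as
#'   the ROI mask (oracle mode), or \code{NULL} to skip cropping.
#' @param stage2 stage-2 model.
#' @param margin crop margin in voxels.
#' @return a \code{\link{label_volume}}.
#' @export
two_stage_predict <- function(v, stage1, stage2, margin = 8L) {
  dm <- dim(v$channels$water)
  depth <- stage2$config$depth
  if (is.null(stage1)) {
    mask <- array(1L, dm)
  } else if (is.array(stage1)) {
    mask <- stage1
  } else {
    fat <- matrix(as.vector(v$channels$fat), ncol = 1)
    lg <- model_forward(stage1, fat, dm)
    mask <- array(as.integer(lg[, 2] > lg[, 1]), dm)
  }
  cr <- crop_to_roi(v, mask, margin = margin, depth = depth)
  x <- volume_to_matrix(cr$volume)
  cdims <- dim(cr$volume$channels$water)
  logits <- model_forward(stage2, x, cdims)
  pred <- array(max.col(softmax_rows(logits), ties.method = "first") - 1L,
                cdims)
  label_volume(uncrop_labels(pred, cr$crop_record), v$spacing)
}

#' Save / load model checkpoints
#'
#' Single-file serialized weight archive with the embedded configuration
#' and manifold state; the format version is checked on load.
#'
#' @param model a model built by \code{\link{build_stage1_unet}} or
#'   \code{\link{build_poinunet}}.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "hyperseg-ckpt-1"))
    stop("load_checkpoint: unsupported checkpoint version: ",
         obj$version)
  structure(obj, class = "hyperseg_model")
}
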