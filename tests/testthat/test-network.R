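# Network layers, the two architectures, cropping and two-stage
# prediction.

test_that("conv_block contracts", {
  dims <- c(5L, 5L, 5L)
  set.seed(1)
  x <- feature_field(matrix(stats::rnorm(prod(dims) * 2), prod(dims), 2),
                     dims)
  # zero weights, non-negative bias: constant output everywhere
  y <- conv_block(x, matrix(0, 27 * 2, 3), c(0.5, 0, 1.2))
  expect_identical(dim(y$data), as.integer(c(prod(dims), 3)))
  expect_true(all(abs(sweep(y$data, 2, c(0.5, 0, 1.2))) < 1e-14))
  # against the direct-convolution oracle (random weights + impulse)
  warr <- array(stats::rnorm(27 * 2 * 2), c(3, 3, 3, 2, 2))
  b <- c(0.1, -0.2)
  xarr <- array(0, c(dims, 2))
  xarr[3, 3, 3, 1] <- 1  # impulse
  xarr[, , , 2] <- stats::rnorm(prod(dims))
  xm <- matrix(xarr, prod(dims), 2)
  ref <- naive_conv3d(xarr, warr, b)
  got <- conv_block(feature_field(xm, dims), warr, b)
  expect_equal(got$data, pmax(matrix(ref, prod(dims), 2), 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identity-like kernel preserves the impulse
  wid <- array(0, c(3, 3, 3, 1, 1)); wid[2, 2, 2, 1, 1] <- 1
  imp <- feature_field(matrix(xarr[, , , 1], prod(dims), 1), dims)
  expect_equal(conv_block(imp, wid, 0)$data, imp$data,
               ignore_attr = TRUE)
  expect_error(conv_block(x, matrix(0, 27, 1), 0), "weight shape")
})

test_that("poincare_embed maps into the ball and has a flat limit", {
  dims <- c(4L, 4L, 4L)
  set.seed(2)
  f <- feature_field(matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3),
                     dims)
  m <- manifold_params(sigma = 0)
  h <- poincare_embed(f, m)
  k <- curvature_value(m)
  expect_identical(h$space, "hyperbolic")
  expect_true(all(k * rowSums(h$data^2) < 1))
  # zero feature -> origin
  z0 <- feature_field(matrix(0, prod(dims), 3), dims)
  expect_true(all(poincare_embed(z0, m)$data == 0))
  # k -> 0: embedding approaches the identity
  mflat <- manifold_params(sigma = log(1e-6) / 1, l_0 = 1e-12)
  hf <- poincare_embed(f, mflat)
  expect_equal(hf$data, f$data, tolerance = 1e-4)
})

test_that("mobius_conv contracts and flat limit", {
  dims <- c(4L, 4L, 4L)
  set.seed(3)
  m <- manifold_params()
  k <- curvature_value(m)
  f <- poincare_embed(
    feature_field(matrix(stats::rnorm(prod(dims) * 2), prod(dims), 2),
                  dims), m)
  w <- matrix(stats::rnorm(27 * 2 * 2, sd = 0.1), 27 * 2, 2)
  out <- mobius_conv(f, w, c(0.01, -0.02), m)
  expect_true(all(curvature_value(m) * rowSums(out$data^2) < 1))
  # zero weights and zero bias -> all-origin output
  out0 <- mobius_conv(f, matrix(0, 27 * 2, 2), c(0, 0), m)
  expect_true(all(out0$data == 0))
  # flat limit: agrees with the plain Euclidean convolution
  mflat <- manifold_params(sigma = log(1e-6), l_0 = 1e-12)
  xeu <- matrix(stats::rnorm(prod(dims) * 2) * 0.5, prod(dims), 2)
  fflat <- poincare_embed(feature_field(xeu, dims), mflat)
  got <- mobius_conv(fflat, w, c(0, 0), mflat)
  ref <- hs$.conv3d_fw(xeu, dims, w, c(0, 0))
  expect_equal(got$data, ref, tolerance = 1e-4)
})

test_that("dual encoder block shape/width and Euclidean ablation", {
  dims <- c(6L, 6L, 6L)
  set.seed(4)
  m <- manifold_params()
  x <- feature_field(matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3),
                     dims)
  w <- 4L
  We <- matrix(stats::rnorm(27 * 3 * w, sd = 0.2), 27 * 3, w)
  be <- stats::rnorm(w, sd = 0.1)
  Wh <- matrix(stats::rnorm(27 * w * w, sd = 0.2), 27 * w, w)
  bh <- numeric(w)
  out <- dual_encoder_block(x, We, be, Wh, bh, m)
  expect_identical(out$dims, dims %/% 2L)
  expect_identical(ncol(out$data), 2L * w)
  # hyperbolic branch zeroed: first half equals plain conv+pool
  out0 <- dual_encoder_block(x, We, be, matrix(0, 27 * w, w), numeric(w), m)
  cb <- conv_block(x, We, be)
  mp <- hs$.maxpool2_fw(cb$data, dims)
  expect_equal(out0$data[, 1:w], mp$y, ignore_attr = TRUE)
  expect_true(all(out0$data[, w + 1:w] == 0))
  expect_error(dual_encoder_block(
    feature_field(matrix(0, 5 * 5 * 5, 1), c(5L, 5L, 5L)),
    We, be, Wh, bh, m), "even")
})

test_that("hmlr_logits: plane symmetry and Euclidean ranking limit", {
  set.seed(5)
  n <- 4
  k <- 1.001
  m <- manifold_params()
  Z <- hs$exp0_fw(matrix(stats::rnorm(60) * 0.5, 15, n), k)$y
  p <- rand_ball_point(n, k, 0.3)
  a <- stats::rnorm(n)
  # mirrored planes: posteriors 0.5/0.5 everywhere on the plane through p
  planes <- list(class_plane(p, a), class_plane(p, -a))
  lg <- hmlr_logits(rbind(p), planes, m)
  post <- hs$softmax_rows(lg)
  expect_equal(as.vector(post), c(0.5, 0.5), tolerance = 1e-9)
  # z on the plane of class y -> zero logit for y
  expect_equal(lg[1, 1], 0, tolerance = 1e-12)
  # flat limit ranks like the Euclidean linear classifier
  kf <- 1e-6
  planesf <- lapply(1:3, function(i)
    list(offset = stats::rnorm(n) * 0.2, normal = stats::rnorm(n),
         zeta = 1))
  Zf <- matrix(stats::rnorm(100 * n) * 0.3, 100, n)
  lgf <- hs$hmlr_fw(Zf, planesf, kf)$logits
  for (ci in 1:3) {
    eu <- 2 * as.vector(sweep(Zf, 2, planesf[[ci]]$offset) %*%
                          planesf[[ci]]$normal) /
      sqrt(sum(planesf[[ci]]$normal^2))
    expect_identical(order(lgf[, ci]), order(eu))
  }
  # posteriors sum to one
  expect_true(all(abs(rowSums(hs$softmax_rows(lgf)) - 1) < 1e-6))
  expect_error(hmlr_logits(Zf, list(), m), "missing")
})

test_that("stage-1 U-Net: shapes, constant input, parameter count", {
  cfg <- model_config(base_channels = 4, depth = 2, num_classes = 2,
                      patch_size = 8)
  model <- build_stage1_unet(cfg, seed = 1)
  dims <- c(8L, 8L, 8L)
  lg <- hs$stage1_fw(model, matrix(stats::rnorm(prod(dims)), prod(dims), 1),
                     dims)$logits
  expect_identical(dim(lg), as.integer(c(prod(dims), 2)))
  # spatially constant on all-zero input (translation invariance; the
  # freshly built net has zero biases, so every activation is zero)
  lg0 <- hs$stage1_fw(model, matrix(0, prod(dims), 1), dims)$logits
  expect_lt(max(apply(lg0, 2, function(v) diff(range(v)))), 1e-12)
  # analytic parameter count for depth 2, base 4
  w <- 4
  expected <- (27 * 1 * w + w) +            # encoder conv
    (27 * w * 2 * w + 2 * w) +              # bottleneck
    (27 * 2 * w * w + w) +                  # decoder up conv
    (27 * 2 * w * w + w) +                  # decoder merge conv
    (w * 2 + 2)                             # 1x1 head
  expect_identical(sum(vapply(model$params, length, integer(1))),
                   as.integer(expected))
})

test_that("stage-2 network: shapes and finite nonzero manifold gradients", {
  model <- tiny_poinunet()
  dims <- c(8L, 8L, 8L)
  set.seed(6)
  x <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  fwd <- hs$stage2_fw(model, x, dims)
  expect_identical(dim(fwd$logits), as.integer(c(prod(dims), 3)))
  expect_true(all(abs(rowSums(hs$softmax_rows(fwd$logits)) - 1) < 1e-6))
  G <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  g <- hs$stage2_bw(model, fwd, G)
  for (nm in names(model$params))
    expect_true(all(is.finite(g[[nm]])), info = nm)
  expect_gt(abs(g$sigma), 0)
  for (ci in 1:3) {
    expect_gt(max(abs(g[[paste0("head.a", ci)]])), 0)
    expect_gt(max(abs(g[[paste0("head.p", ci)]])), 0)
  }
})

test_that("full network gradients match finite differences", {
  model <- tiny_poinunet()
  dims <- c(4L, 4L, 4L)
  set.seed(7)
  x <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  G <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  fwd <- hs$stage2_fw(model, x, dims)
  g <- hs$stage2_bw(model, fwd, G)
  # spot-check a representative subset of parameters (full check is slow)
  for (nm in c("enc1.Wh", "enc1.bh", "bott.b", "dec1.Wup", "head.p2",
               "head.a1", "head.zeta3", "sigma")) {
    ng <- numgrad(function(v) {
      mod <- model; mod$params[[nm]][] <- v
      sum(G * hs$stage2_fw(mod, x, dims)$logits)
    }, as.vector(model$params[[nm]]))
    expect_equal(as.vector(g[[nm]]), ng, tolerance = 1e-4, info = nm)
  }
  # stage-1 spot check
  m1 <- tiny_stage1()
  x1 <- matrix(stats::rnorm(prod(dims)), prod(dims), 1)
  G1 <- matrix(stats::rnorm(prod(dims) * 2), prod(dims), 2)
  f1 <- hs$stage1_fw(m1, x1, dims)
  g1 <- hs$stage1_bw(m1, f1, G1)
  for (nm in c("enc1.W", "bott.W", "dec1.Wm", "head.W")) {
    ng <- numgrad(function(v) {
      mod <- m1; mod$params[[nm]][] <- v
      sum(G1 * hs$stage1_fw(mod, x1, dims)$logits)
    }, as.vector(m1$params[[nm]]))
    expect_equal(as.vector(g1[[nm]]), ng, tolerance = 1e-4, info = nm)
  }
})

test_that("hyperbolic attention gate keeps gradients exact", {
  model <- tiny_poinunet(use_hyperbolic_attention = TRUE)
  dims <- c(4L, 4L, 4L)
  set.seed(8)
  x <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  G <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  fwd <- hs$stage2_fw(model, x, dims)
  g <- hs$stage2_bw(model, fwd, G)
  for (nm in c("enc1.We", "enc1.Wh", "sigma")) {
    ng <- numgrad(function(v) {
      mod <- model; mod$params[[nm]][] <- v
      sum(G * hs$stage2_fw(mod, x, dims)$logits)
    }, as.vector(model$params[[nm]]))
    expect_equal(as.vector(g[[nm]]), ng, tolerance = 1e-4, info = nm)
  }
})

test_that("forward pass is deterministic", {
  model <- tiny_poinunet()
  dims <- c(4L, 4L, 4L)
  x <- matrix(stats::rnorm(prod(dims) * 3), prod(dims), 3)
  expect_identical(hs$stage2_fw(model, x, dims)$logits,
                   hs$stage2_fw(model, x, dims)$logits)
})

test_that("crop_to_roi geometry and round trip", {
  dm <- c(20L, 20L, 20L)
  z <- array(0, dm)
  v <- seg_volume(z, z, z, c(1, 1, 1))
  mask <- array(0L, dm)
  # empty mask: full volume fallback
  cr <- crop_to_roi(v, mask, margin = 4, depth = 3)
  expect_identical(dim(cr$volume$channels$water), dm)
  # single voxel at center, margin 4: 9^3 before padding
  mask[10, 10, 10] <- 1L
  cr1 <- crop_to_roi(v, mask, margin = 4, depth = 1)
  expect_identical(dim(cr1$volume$channels$water), c(9L, 9L, 9L))
  # padding to the pooling multiple
  cr3 <- crop_to_roi(v, mask, margin = 4, depth = 3)
  expect_true(all(dim(cr3$volume$channels$water) %% 4L == 0L))
  # exact re-embedding
  pd <- dim(cr3$volume$channels$water)
  lab <- array(sample(0:2, prod(pd), TRUE), pd)
  un <- uncrop_labels(lab, cr3$crop_record)
  expect_identical(dim(un), dm)
  r <- cr3$crop_record
  expect_identical(un[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3]],
                   lab[1:(r$hi[1] - r$lo[1] + 1), 1:(r$hi[2] - r$lo[2] + 1),
                       1:(r$hi[3] - r$lo[3] + 1)])
  # growing the margin never drops foreground
  set.seed(9)
  mask2 <- array(as.integer(stats::runif(prod(dm)) < 0.01), dm)
  prev <- -1
  for (mg in c(0, 2, 4, 8)) {
    cc <- crop_to_roi(v, mask2, margin = mg, depth = 2)
    r <- cc$crop_record
    inside <- sum(mask2[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3]])
    expect_identical(inside, sum(mask2))
    expect_gte(inside, prev)
    prev <- inside
  }
})

test_that("two-stage prediction with an oracle stage-1 mask", {
  ph <- generate_phantom(tiny_phantom_config(seed = 11))
  model <- build_poinunet(model_config(base_channels = 2, depth = 2,
                                       patch_size = 8), seed = 2)
  oracle <- array(as.integer(ph$labels$labels > 0), dim(ph$labels$labels))
  pred <- two_stage_predict(ph$volume, oracle, model, margin = 4)
  expect_identical(dim(pred$labels), dim(ph$labels$labels))
  expect_identical(pred$spacing, ph$labels$spacing)
  # outside the crop box everything is background
  cr <- crop_to_roi(ph$volume, oracle, margin = 4,
                    depth = model$config$depth)
  r <- cr$crop_record
  outside <- pred$labels
  outside[r$lo[1]:r$hi[1], r$lo[2]:r$hi[2], r$lo[3]:r$hi[3]] <- 0L
  expect_true(all(outside == 0L))
  # equals stage 2 applied to the true ROI crop
  x <- hs$volume_to_matrix(cr$volume)
  lg <- hs$model_forward(model, x, dim(cr$volume$channels$water))
  direct <- array(max.col(hs$softmax_rows(lg), ties.method = "first") - 1L,
                  dim(cr$volume$channels$water))
  expect_identical(pred$labels, uncrop_labels(direct, cr$crop_record))
})

test_that("checkpoints round-trip and reject unknown versions", {
  model <- tiny_poinunet()
  p <- tempfile(fileext = ".rds")
  save_checkpoint(model, p)
  m2 <- load_checkpoint(p)
  expect_equal(m2$params, model$params)
  expect_identical(m2$config$base_channels, model$config$base_channels)
  bad <- unclass(model)
  bad$version <- "other"
  saveRDS(bad, p)
  expect_error(load_checkpoint(p), "version")
})
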