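#' Training configuration
#'
#' Defaults follow the reference optimization recipe: 600 epochs, batch
#' size 2, SGD with momentum 0.9 and polynomial learning-rate decay of
#' power 0.9 for Euclidean parameters, Riemannian SGD at learning rate
#' 0.1 for manifold parameters (curvature pre-parameter and ball
#' points), capped at 10,000 manifold iterations.
#'
#' @param epochs number of epochs.
#' @param batch_size samples per optimization step.
#' @param euclid_lr initial Euclidean learning rate.
#' @param euclid_momentum SGD momentum for Euclidean parameters.
#' @param poly_power polynomial decay power.
#' @param poincare_lr Riemannian SGD learning rate for manifold
#'   parameters.
#' @param poincare_max_iters cap on manifold update steps, after which
#'   manifold parameters freeze.
#' @param seed master RNG seed.
#' @param patch_size training patch edge in voxels (patches are sampled
#'   only when smaller than the volume).
#' @param val_fraction fraction of samples held out for validation.
#' @param augment apply random flip/rotation/scaling augmentation.
#' @param loss a \code{\link{loss_weights}} object.
#' @param model a \code{\link{model_config}} object.
#' @export
train_config <- function(epochs = 600, batch_size = 2, euclid_lr = 0.01,
                         euclid_momentum = 0.9, poly_power = 0.9,
                         poincare_lr = 0.1, poincare_max_iters = 10000,
                         seed = 1L, patch_size = 96, val_fraction = 0.1,
                         augment = TRUE, loss = loss_weights(),
                         model = model_config()) {
  if (epochs < 1 || batch_size < 1) stop("train_config: invalid sizes")
  if (euclid_lr <= 0 || poincare_lr <= 0)
    stop("train_config: learning rates must be positive")
  model$patch_size <- as.integer(patch_size)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 euclid_lr = euclid_lr,
                 euclid_momentum = euclid_momentum,
                 poly_power = poly_power, poincare_lr = poincare_lr,
                 poincare_max_iters = as.integer(poincare_max_iters),
                 seed = as.integer(seed),
                 patch_size = as.integer(patch_size),
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 loss = loss, model = model),
            class = "train_config")
}

zero_like <- function(params) lapply(params, function(p) p * 0)

acc_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

# Composite loss and its gradient on the logits for one sample.
sample_loss <- function(model, logits, labels, spacing, lw, k_ref) {
  C <- ncol(logits)
  lab <- as.integer(as.vector(labels))
  ce <- ce_fw_bw(logits, lab, class_weights = NULL)
  probs <- softmax_rows(logits)
  wmap <- if (model$stage == 2L) {
    la <- array(lab == 1L, dim(labels))
    inverse_distance_weights(la, spacing)
  } else NULL
  dice <- idwh_loss(probs, lab, wmap)
  gprob <- idwh_loss_grad(probs, lab, wmap)
  # softmax backward
  gdice_logit <- probs * (gprob - rowSums(gprob * probs))
  eucl <- euclidean_weight_penalty(model)
  if (model$stage == 2L) {
    m <- current_manifold(model)
    k <- curvature_value(m)
    curv <- curvature_penalty(k, k_ref)
  } else {
    curv <- 0
  }
  loss <- combined_loss(ce$loss, curv, dice, eucl, lw)
  glogits <- lw$alpha * ce$grad + lw$delta * gdice_logit
  list(loss = loss, ce = ce$loss, dice = dice, curv = curv, eucl = eucl,
       glogits = glogits)
}

stage_labels <- function(stage, labels) {
  if (stage == 1L) array(as.integer(labels != 0), dim(labels)) else labels
}

stage_input <- function(stage, volume) {
  if (stage == 1L) matrix(as.vector(volume$channels$fat), ncol = 1)
  else volume_to_matrix(volume)
}

# Mean foreground Dice of a model over a list of samples.
validation_dice <- function(model, samples) {
  scores <- vapply(samples, function(s) {
    labs <- stage_labels(model$stage, s$labels$labels)
    dm <- dim(labs)
    x <- stage_input(model$stage, s$volume)
    logits <- model_forward(model, x, dm)
    pred <- array(max.col(logits, ties.method = "first") - 1L, dm)
    fg <- if (model$stage == 1L) 1L else c(1L, 2L)
    mean(vapply(fg, function(cl)
      confusion_metrics(pred, labs, cl)[["dice"]], numeric(1)))
  }, numeric(1))
  mean(scores)
}

#' Train a segmentation model
#'
#' Euclidean parameters are updated by momentum SGD with polynomial
#' learning-rate decay \eqn{lr(t) = lr_0 (1 - t/T)^{0.9}}; manifold
#' parameters (curvature pre-parameter, ball-point biases, class-plane
#' offsets) by Riemannian SGD at \code{poincare_lr}, capped at
#' \code{poincare_max_iters} steps.  The best-validation-Dice checkpoint
#' is retained.  Fully seeded: identical seeds and data give identical
#' trajectories in single-threaded mode.
#'
#' @param stage 1 (ROI U-Net on the fat channel) or 2 (hyperbolic
#'   network on water/fat/fat-fraction).
#' @param dataset nonempty list of samples, each with \code{volume}
#'   (\code{\link{seg_volume}}) and \code{labels}
#'   (\code{\link{label_volume}}).
#' @param cfg a \code{\link{train_config}}.
#' @param run_dir optional directory for the checkpoint and training
#'   log.
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best checkpoint), \code{final_model},
#'   \code{log} (per-epoch data.frame) and \code{config}.
#' @export
train_model <- function(stage, dataset, cfg = train_config(),
                        run_dir = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("train_model: empty dataset")
  stage <- as.integer(stage)
  set.seed(cfg$seed)
  mcfg <- cfg$model
  model <- if (stage == 1L) {
    mcfg$num_classes <- 2L
    build_stage1_unet(mcfg, seed = cfg$seed)
  } else {
    build_poinunet(mcfg, seed = cfg$seed)
  }
  k_ref <- if (stage == 2L) curvature_value(current_manifold(model))
           else NULL
  nval <- if (length(dataset) >= 4) floor(cfg$val_fraction * length(dataset))
          else 0
  train_set <- dataset[seq_len(length(dataset) - nval)]
  val_set <- if (nval > 0) dataset[length(dataset) - nval + seq_len(nval)]
             else train_set
  nW <- weight_decay_names(model)
  nW_count <- sum(vapply(model$params[nW], length, integer(1)))
  momentum <- zero_like(model$params)
  manifold_iters <- 0L
  best <- list(dice = -Inf, params = model$params)
  log <- NULL
  T_total <- cfg$epochs
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$euclid_lr * (1 - (epoch - 1) / T_total)^cfg$poly_power
    ord <- sample(length(train_set))
    comp <- c(loss = 0, ce = 0, dice = 0, curv = 0, eucl = 0)
    nbatch <- 0
    i <- 1
    while (i <= length(ord)) {
      take <- ord[i:min(i + cfg$batch_size - 1, length(ord))]
      i <- i + cfg$batch_size
      gacc <- zero_like(model$params)
      gsig_extra <- 0
      bloss <- c(loss = 0, ce = 0, dice = 0, curv = 0, eucl = 0)
      for (si in take) {
        s <- train_set[[si]]
        dm <- dim(s$labels$labels)
        if (all(cfg$patch_size < dm)) {
          pt <- sample_balanced_patches(s, cfg$patch_size, 1,
                                        seed = sample.int(2^30, 1))[[1]]
        } else pt <- list(volume = s$volume, labels = s$labels)
        if (cfg$augment)
          pt <- augment_patch(pt$volume, pt$labels,
                              seed = sample.int(2^30, 1))
        labs <- stage_labels(stage, pt$labels$labels)
        x <- stage_input(stage, pt$volume)
        pdm <- dim(labs)
        if (stage == 1L) {
          fwd <- stage1_fw(model, x, pdm)
        } else {
          fwd <- stage2_fw(model, x, pdm)
        }
        sl <- sample_loss(model, fwd$logits, labs, pt$labels$spacing,
                          cfg$loss, k_ref)
        bloss <- bloss + c(sl$loss, sl$ce, sl$dice, sl$curv, sl$eucl)
        g <- if (stage == 1L) stage1_bw(model, fwd, sl$glogits)
             else stage2_bw(model, fwd, sl$glogits)
        # curvature penalty gradient flows to sigma only
        if (stage == 2L) {
          m <- current_manifold(model)
          k <- curvature_value(m)
          gsig_extra <- gsig_extra + cfg$loss$gamma *
            curvature_penalty_grad(k, k_ref) * curvature_grad_sigma(m)
        }
        gacc <- acc_grads(gacc, g)
      }
      nb <- length(take)
      for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / nb
      if (stage == 2L)
        gacc[["sigma"]] <- gacc[["sigma"]] + gsig_extra / nb
      # weight decay on the decay group (gradient of the mean-square)
      for (nm in nW)
        gacc[[nm]] <- gacc[[nm]] +
          cfg$loss$epsilon * 2 * model$params[[nm]] / nW_count
      manifold_live <- manifold_iters < cfg$poincare_max_iters
      k_now <- if (stage == 2L) curvature_value(current_manifold(model))
               else NULL
      for (nm in names(model$params)) {
        kind <- model$kind[[nm]]
        if (kind == "euclid") {
          momentum[[nm]] <- cfg$euclid_momentum * momentum[[nm]] -
            lr * gacc[[nm]]
          model$params[[nm]] <- model$params[[nm]] + momentum[[nm]]
        } else if (manifold_live && kind == "ball") {
          model$params[[nm]] <- riemannian_sgd_step(
            model$params[[nm]], gacc[[nm]], cfg$poincare_lr, k_now)
        } else if (manifold_live && kind == "sigma") {
          model$params[[nm]] <- model$params[[nm]] -
            cfg$poincare_lr * gacc[[nm]]
        }
      }
      if (manifold_live && stage == 2L)
        manifold_iters <- manifold_iters + 1L
      comp <- comp + bloss / nb
      nbatch <- nbatch + 1
    }
    comp <- comp / nbatch
    vd <- validation_dice(model, val_set)
    k_log <- if (stage == 2L) curvature_value(current_manifold(model))
             else NA_real_
    log <- rbind(log, data.frame(epoch = epoch, loss = comp[["loss"]],
                                 ce = comp[["ce"]], dice = comp[["dice"]],
                                 curv = comp[["curv"]],
                                 eucl = comp[["eucl"]], val_dice = vd,
                                 k = k_log))
    if (!is.finite(comp[["loss"]]))
      stop("train_model: non-finite loss at epoch ", epoch)
    if (vd >= best$dice) best <- list(dice = vd, params = model$params)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f  k %.4f",
                      epoch, comp[["loss"]], vd,
                      if (is.na(k_log)) 0 else k_log))
  }
  final_model <- model
  model$params <- best$params
  out <- list(model = model, final_model = final_model, log = log,
              config = cfg)
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(run_dir,
                                     paste0("stage", stage, "_best.rds")))
    utils::write.csv(log, file.path(run_dir,
                                    paste0("stage", stage, "_log.csv")),
                     row.names = FALSE)
  }
  out
}
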