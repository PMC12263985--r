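#' Composite loss coefficients
#'
#' Weights of the four loss components: cross-entropy (\code{alpha}),
#' curvature penalty (\code{gamma}), inverse-distance-weighted Dice
#' (\code{delta}) and Euclidean weight decay (\code{epsilon}).
#'
#' @param alpha,gamma,delta,epsilon non-negative reals; defaults 0.5,
#'   0.2, 0.5, 0.2.
#' @export
loss_weights <- function(alpha = 0.5, gamma = 0.2, delta = 0.5,
                         epsilon = 0.2) {
  v <- c(alpha, gamma, delta, epsilon)
  if (any(!is.finite(v)) || any(v < 0))
    stop("loss_weights: coefficients must be non-negative")
  structure(list(alpha = alpha, gamma = gamma, delta = delta,
                 epsilon = epsilon),
            class = "loss_weights")
}

# Boundary shell of the LA mask: LA voxels with a 6-neighbor outside the
# mask (volume edges count as outside).
boundary_shell <- function(mask) {
  dm <- dim(mask)
  m <- mask != 0
  shell <- array(FALSE, dm)
  if (!any(m)) return(shell)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- m
  nb <- array(TRUE, dm)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(nrow(shifts))) {
    s <- shifts[i, ]
    nb <- nb & pad[(2 + s[1]):(dm[1] + 1 + s[1]),
                   (2 + s[2]):(dm[2] + 1 + s[2]),
                   (2 + s[3]):(dm[3] + 1 + s[3])]
  }
  m & !nb
}

#' Inverse-distance weight map from an LA mask
#'
#' Voxels closer to the LA boundary receive higher weights: with
#' \eqn{d(v)} the Euclidean distance (in mm) from voxel \eqn{v} to the
#' LA boundary surface (LA voxels adjacent to non-LA voxels), the weight
#' law is \eqn{1/(1+d)} (alternatives \eqn{1/(1+d)^2} and
#' \eqn{e^{-d/\tau}}), normalized to mean 1 over the grid.  An empty
#' mask yields uniform weights 1.
#'
#' @param la_mask binary 3D array (the LA label).
#' @param spacing mm per axis.
#' @param law weight law, one of \code{"inv"}, \code{"inv2"},
#'   \code{"exp"}.
#' @param tau decay length in mm for the exponential law.
#' @return object of class \code{"distance_weight_map"} with fields
#'   \code{weights} (3D array, mean 1), \code{source_mask},
#'   \code{spacing}.
#' @export
inverse_distance_weights <- function(la_mask, spacing,
                                     law = c("inv", "inv2", "exp"),
                                     tau = 10) {
  law <- match.arg(law)
  dm <- dim(la_mask)
  shell <- boundary_shell(la_mask)
  if (!any(shell)) {
    w <- array(1, dm)
  } else {
    d <- sqrt(.edt_sq(as.vector(shell), as.integer(dm),
                      as.numeric(spacing)))
    w <- switch(law,
                inv = 1 / (1 + d),
                inv2 = 1 / (1 + d)^2,
                exp = exp(-d / tau))
    w <- array(w / mean(w), dm)
  }
  structure(list(weights = w, source_mask = la_mask != 0,
                 spacing = as.numeric(spacing)),
            class = "distance_weight_map")
}

# Coerce prediction/target/weights to (nvox x C) matrices.
as_prob_matrix <- function(x, C = NULL) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4) {
    dm <- dim(x)
    return(matrix(x, prod(dm[1:3]), dm[4]))
  }
  stop("expected (nvox x C) matrix or 4D array")
}

as_onehot <- function(target, C) {
  if (is.matrix(target) && ncol(target) == C) return(target)
  lab <- as.integer(as.vector(if (inherits(target, "label_volume"))
    target$labels else target))
  oh <- matrix(0, length(lab), C)
  oh[cbind(seq_along(lab), lab + 1L)] <- 1
  oh
}

#' Inverse-distance-weighted Dice loss
#'
#' \deqn{L = 1 - \frac{1}{C}\sum_{c=1}^{C}
#' \frac{2\sum_k p_{k,c} y_{k,c} d_k + \epsilon}
#' {\sum_k p_{k,c}^2 d_k + \sum_k y_{k,c}^2 d_k + \epsilon}}
#' with smoothing \eqn{\epsilon = 10^{-6}} guarding empty classes.  With
#' uniform weights this is the standard multi-class soft Dice loss.
#'
#' @param pred per-voxel class probabilities, (nvox x C) matrix (or 4D
#'   array with classes last).
#' @param target one-hot matrix of the same shape, or integer labels.
#' @param w a \code{\link{inverse_distance_weights}} map, a numeric
#'   vector of per-voxel weights, or \code{NULL} for uniform weights.
#' @return scalar loss in \code{[0, 1]}.
#' @export
idwh_loss <- function(pred, target, w = NULL) {
  p <- as_prob_matrix(pred)
  C <- ncol(p)
  y <- as_onehot(target, C)
  if (!all(dim(p) == dim(y))) stop("idwh_loss: shape mismatch")
  d <- idwh_weight_vector(w, nrow(p))
  sm <- 1e-6
  num <- 2 * colSums(p * y * d) + sm
  den <- colSums(p * p * d) + colSums(y * y * d) + sm
  1 - mean(num / den)
}

idwh_weight_vector <- function(w, nvox) {
  if (is.null(w)) return(rep(1, nvox))
  if (inherits(w, "distance_weight_map")) w <- as.vector(w$weights)
  w <- as.numeric(w)
  if (length(w) != nvox) stop("idwh_loss: weight length mismatch")
  w
}

# Gradient of idwh_loss w.r.t. pred (same shape as pred).
idwh_loss_grad <- function(pred, target, w = NULL) {
  p <- as_prob_matrix(pred)
  C <- ncol(p)
  y <- as_onehot(target, C)
  d <- idwh_weight_vector(w, nrow(p))
  sm <- 1e-6
  num <- 2 * colSums(p * y * d) + sm
  den <- colSums(p * p * d) + colSums(y * y * d) + sm
  # d/dp of -(1/C) num/den
  g <- matrix(0, nrow(p), C)
  for (ci in seq_len(C)) {
    g[, ci] <- -(1 / C) *
      (2 * y[, ci] * d * den[ci] - num[ci] * 2 * p[, ci] * d) / den[ci]^2
  }
  g
}

#' Inverse-prevalence class weights
#'
#' Weight proportional to \code{1/prevalence} over the classes present
#' in the batch, normalized to mean 1; absent classes get weight 0.
#'
#' @param target integer labels in \code{0:(C-1)}.
#' @param C number of classes.
#' @export
inverse_prevalence_weights <- function(target, C) {
  lab <- as.integer(as.vector(if (inherits(target, "label_volume"))
    target$labels else target))
  prev <- tabulate(lab + 1L, nbins = C) / length(lab)
  w <- numeric(C)
  present <- prev > 0
  w[present] <- 1 / prev[present]
  w[present] <- w[present] / mean(w[present])
  w
}

#' Class-weighted cross-entropy on voxel logits
#'
#' Weighted negative log softmax likelihood averaged over voxels.  By
#' default the class weights are inversely proportional to the class
#' prevalence in the batch (normalized to mean 1), giving minority
#' voxels such as EAT more influence.
#'
#' @param logits (nvox x C) matrix of per-voxel per-class logits.
#' @param target integer labels (0-based) or one-hot matrix.
#' @param class_weights per-class non-negative weights; \code{NULL} for
#'   inverse-prevalence weights computed from the batch.
#' @return scalar loss \eqn{\ge 0}.
#' @export
hmlr_cross_entropy <- function(logits, target, class_weights = NULL) {
  ce <- ce_fw_bw(logits, target, class_weights)
  ce$loss
}

# Forward + gradient in one pass (gradient w.r.t. logits).
ce_fw_bw <- function(logits, target, class_weights = NULL) {
  p <- as_prob_matrix(logits)
  C <- ncol(p)
  y <- as_onehot(target, C)
  lab <- max.col(y, ties.method = "first")
  if (is.null(class_weights))
    class_weights <- inverse_prevalence_weights(lab - 1L, C)
  if (any(class_weights < 0)) stop("hmlr_cross_entropy: negative weight")
  pr <- softmax_rows(p)
  wv <- class_weights[lab]
  n <- nrow(p)
  nll <- -log(pmax(pr[cbind(seq_len(n), lab)], 1e-300))
  loss <- mean(wv * nll)
  grad <- (pr - y) * (wv / n)
  list(loss = loss, grad = grad)
}

#' Curvature regularizer
#'
#' \eqn{(\log k - \log k_{ref})^2}: symmetric in log-space, zero at the
#' reference curvature; keeps the learned \eqn{k} from collapsing to the
#' floor or exploding.
#'
#' @param m a \code{\link{manifold_params}} object or a positive
#'   curvature value.
#' @param k_ref reference curvature; defaults to the initial curvature
#'   \eqn{e^0 + l_0}.
#' @export
curvature_penalty <- function(m, k_ref = NULL) {
  if (inherits(m, "manifold_params")) {
    k <- curvature_value(m)
    if (is.null(k_ref)) k_ref <- 1 + m$l_0
  } else {
    k <- m
    if (is.null(k_ref)) k_ref <- 1 + 1e-3
  }
  (log(k) - log(k_ref))^2
}

# d penalty / d k
curvature_penalty_grad <- function(k, k_ref) 2 * (log(k) - log(k_ref)) / k

#' L2 penalty on Euclidean weights
#'
#' Mean of squared entries over the Euclidean weight tensors, excluding
#' manifold parameters (ball points, curvature) and biases.
#'
#' @param params a model object or a list of numeric arrays (all entries
#'   are used when a plain list is given).
#' @export
euclidean_weight_penalty <- function(params) {
  if (inherits(params, "hyperseg_model"))
    params <- params$params[weight_decay_names(params)]
  v <- unlist(params, use.names = FALSE)
  if (length(v) == 0) return(0)
  mean(v^2)
}

# Parameters subject to weight decay: conv weights, head weights and
# class-plane normals; not biases, ball points, zeta or sigma.
weight_decay_names <- function(model) {
  nm <- names(model$params)
  nm[grepl("\\.W", nm) | grepl("^head\\.a", nm)]
}

#' Composite training loss
#'
#' \eqn{\alpha L_{CE} + \gamma L_{curv} + \delta L_{IDWH} +
#' \epsilon L_{weights}} with the configured coefficients.
#'
#' @param ce,curv,idwh,eucl the four loss components.
#' @param w a \code{\link{loss_weights}} object.
#' @export
combined_loss <- function(ce, curv, idwh, eucl, w = loss_weights()) {
  stopifnot(is.finite(ce), is.finite(curv), is.finite(idwh),
            is.finite(eucl))
  w$alpha * ce + w$gamma * curv + w$delta * idwh + w$epsilon * eucl
}
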