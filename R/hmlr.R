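# Hyperbolic multinomial logistic regression (HMLR) head.
#
# Each class y owns a plane (offset p_y on the ball, Euclidean normal
# a_y, positive scale zeta_y).  The per-voxel logit is the standard
# hyperbolic MLR score
#
#   logit_y(z) = zeta_y * lambda_{p_y} * ||a_y|| / sqrt(k) * asinh(s),
#   s = 2 sqrt(k) <(-p_y) (+) z, a_y> / ((1 - k ||(-p_y) (+) z||^2) ||a_y||),
#
# whose sign and magnitude derive from the signed distance to the plane;
# softmax over classes yields voxel posteriors.

# Batched forward: z (nvox x n) inside the ball, planes = list of
# class_plane.  Returns logits (nvox x C) and a cache for the backward.
hmlr_fw <- function(z, planes, k) {
  n <- ncol(z)
  nv <- nrow(z)
  C <- length(planes)
  logits <- matrix(0, nv, C)
  caches <- vector("list", C)
  t <- sqrt(k)
  for (ci in seq_len(C)) {
    pl <- planes[[ci]]
    if (length(pl$offset) != n)
      stop("hmlr: plane dimension does not match feature channels")
    a <- pl$normal
    na <- max(sqrt(sum(a * a)), .NORM_FLOOR)
    p <- pl$offset
    negp <- matrix(rep(-p, each = nv), nv, n)
    ma <- madd_fw(negp, z, k, project = FALSE)
    u <- ma$y
    c2 <- rowSums(u * u)
    nm <- as.vector(u %*% a)
    om <- pmax(1 - k * c2, .NORM_FLOOR)
    s <- 2 * t * nm / (om * na)
    lam <- 2 / (1 - k * sum(p * p))
    M <- pl$zeta * lam * na / t
    logits[, ci] <- M * asinh(s)
    caches[[ci]] <- list(ma = ma, u = u, c2 = c2, nm = nm, om = om,
                         s = s, lam = lam, M = M, a = a, na = na,
                         p = p, zeta = pl$zeta)
  }
  list(logits = logits, caches = caches, k = k, nvox = nv, nch = n)
}

# Backward: gout (nvox x C) upstream gradient on logits.  Returns the
# gradient on the features z, per-class gradients on (offset, normal,
# zeta) and the accumulated curvature gradient.
hmlr_bw <- function(fwd, gout) {
  k <- fwd$k
  t <- sqrt(k)
  nv <- fwd$nvox
  gz <- matrix(0, nv, fwd$nch)
  gplanes <- vector("list", length(fwd$caches))
  gk <- 0
  for (ci in seq_along(fwd$caches)) {
    cc <- fwd$caches[[ci]]
    gy <- gout[, ci]
    as_s <- asinh(cc$s)
    sum_gy_asinh <- sum(gy * as_s)
    # d logit / ds
    gs <- gy * cc$M / sqrt(1 + cc$s^2)
    # s = 2 t nm / (om na):  d/du = (2t/(om na)) (a + 2k nm u / om)
    coef <- gs * 2 * t / (cc$om * cc$na)
    gu <- coef %o% cc$a + cc$u * (coef * 2 * k * cc$nm / cc$om)
    # d/da (through s and through ||a|| in M)
    w_s <- gs * 2 * t / cc$om
    ga <- colSums(cc$u * w_s) / cc$na -
      cc$a * (sum(w_s * cc$nm) / cc$na^3) +
      sum_gy_asinh * cc$zeta * cc$lam / t * (cc$a / cc$na)
    # zeta and lambda_p
    gzeta <- cc$lam * cc$na / t * sum_gy_asinh
    glam <- cc$zeta * cc$na / t * sum_gy_asinh
    gp <- glam * k * cc$lam^2 * cc$p  # d lam/dp = k lam^2 p
    # curvature: explicit in s, in M's 1/sqrt(k), and in lambda_p
    gk <- gk +
      sum(gs * cc$s * (1 / (2 * k) + cc$c2 / cc$om)) -
      sum_gy_asinh * cc$M / (2 * k) +
      glam * cc$lam^2 * sum(cc$p^2) / 2
    # through the Moebius addition u = (-p) (+) z
    mb <- madd_bw(cc$ma$cache, gu)
    gz <- gz + mb$gq2
    gp <- gp - colSums(mb$gq1)
    gk <- gk + mb$gk
    gplanes[[ci]] <- list(offset = gp, normal = ga, zeta = gzeta)
  }
  list(gz = gz, gplanes = gplanes, gk = gk)
}

#' Hyperbolic multinomial logistic regression logits
#'
#' Computes per-voxel per-class logits for a hyperbolic feature field
#' from its distances to the class planes; \code{softmax} of a row gives
#' the voxel posterior.
#'
#' @param z a hyperbolic \code{\link{feature_field}} (or an
#'   (nvox x n) matrix of ball points).
#' @param planes list with one \code{\link{class_plane}} per class.
#' @param m a \code{\link{manifold_params}} object (or a positive
#'   curvature scalar).
#' @return (nvox x C) matrix of logits.
#' @export
hmlr_logits <- function(z, planes, m) {
  if (inherits(z, "feature_field")) {
    if (z$space != "hyperbolic")
      stop("hmlr_logits: feature field must be hyperbolic")
    zmat <- z$data
  } else zmat <- as.matrix(z)
  if (length(planes) < 1) stop("hmlr_logits: missing class planes")
  k <- if (inherits(m, "manifold_params")) curvature_value(m) else m
  hmlr_fw(zmat, planes, k)$logits
}

# Numerically stable row-wise softmax.
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}
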