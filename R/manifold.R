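#' Curvature state of the Poincare ball
#'
#' The ball curvature is learned through an exponential parametrization
#' \eqn{k = e^{l_k \sigma} + l_0}: \code{sigma} is the trainable scalar,
#' \code{l_k} a fixed scale hyperparameter and \code{l_0 > 0} a strict
#' floor that keeps the ball from degenerating to Euclidean space.
#'
#' @param sigma trainable real scalar (curvature pre-parameter).
#' @param l_k fixed real scale hyperparameter.
#' @param l_0 fixed positive floor on the curvature, default \code{1e-3}.
#' @param eps_ball clamp margin used when projecting points into the open
#'   ball; must lie in \code{(0, 0.01]}.
#' @return an object of class \code{"manifold_params"}.
#' @export
manifold_params <- function(sigma = 0, l_k = 1, l_0 = 1e-3,
                            eps_ball = 1e-5) {
  if (!is.finite(sigma)) stop("manifold_params: sigma must be finite")
  if (!is.finite(l_k)) stop("manifold_params: l_k must be finite")
  if (!(l_0 > 0)) stop("manifold_params: l_0 must be > 0")
  if (!(eps_ball > 0 && eps_ball <= 0.01))
    stop("manifold_params: eps_ball must be in (0, 0.01]")
  structure(list(sigma = sigma, l_k = l_k, l_0 = l_0,
                 eps_ball = eps_ball),
            class = "manifold_params")
}

#' Derived ball curvature
#'
#' \eqn{k = e^{l_k \sigma} + l_0}; strictly greater than \code{l_0} for
#' every finite \code{sigma} and strictly increasing in \code{sigma} when
#' \code{l_k > 0}.
#'
#' @param m a \code{\link{manifold_params}} object.
#' @return positive scalar curvature.
#' @export
curvature_value <- function(m) {
  if (!is.finite(m$sigma)) stop("curvature_value: non-finite sigma")
  exp(m$l_k * m$sigma) + m$l_0
}

# d k / d sigma, used by the optimizer.
curvature_grad_sigma <- function(m) {
  m$l_k * exp(m$l_k * m$sigma)
}

.NORM_FLOOR <- 1e-12
.ATANH_CLAMP <- 1 - 1e-7

#' Conformal factor of the Poincare ball
#'
#' \eqn{\lambda_p = 2 / (1 - k \|p\|^2)}, the metric scaling factor at a
#' point \code{p} inside the ball of curvature \code{k}.
#'
#' @param p numeric vector (a ball point).
#' @param k positive curvature.
#' @return scalar \eqn{\ge 2}.
#' @export
conformal_factor <- function(p, k) {
  q <- k * sum(p^2)
  if (q >= 1) stop("conformal_factor: point outside the ball (k||p||^2 >= 1)")
  2 / (1 - q)
}

#' Project a vector into the open Poincare ball
#'
#' Interior points are returned unchanged; points with
#' \eqn{\sqrt{k}\|x\| \ge 1 - \epsilon} are radially rescaled to norm
#' \eqn{(1-\epsilon)/\sqrt{k}}, so the ball invariant
#' \eqn{k\|x\|^2 < 1} always holds on output.
#'
#' @param x numeric vector.
#' @param k positive curvature.
#' @param eps clamp margin, default \code{1e-5}.
#' @export
project_to_ball <- function(x, k, eps = 1e-5) {
  nrm <- sqrt(sum(x^2))
  lim <- (1 - eps) / sqrt(k)
  if (nrm > lim) x * (lim / nrm) else x
}

# Row-wise ball projection for (nvox x channels) matrices.
project_rows <- function(x, k, eps = 1e-5) {
  nrm <- sqrt(rowSums(x * x))
  lim <- (1 - eps) / sqrt(k)
  bad <- nrm > lim
  if (any(bad)) x[bad, ] <- x[bad, , drop = FALSE] * (lim / nrm[bad])
  x
}

#' Moebius addition on the Poincare ball
#'
#' The gyrogroup addition
#' \deqn{q_1 \oplus q_2 = \frac{(1 + 2k\langle q_1,q_2\rangle + k\|q_2\|^2)
#'   q_1 + (1 - k\|q_1\|^2) q_2}{1 + 2k\langle q_1,q_2\rangle +
#'   k^2\|q_1\|^2\|q_2\|^2}.}
#' The result is projected back into the open ball with margin \code{eps}.
#'
#' @param q1,q2 numeric vectors inside the ball for curvature \code{k}.
#' @param k positive curvature.
#' @param eps ball projection margin.
#' @return numeric vector inside the ball.
#' @export
mobius_add <- function(q1, q2, k, eps = 1e-5) {
  cc <- sum(q1 * q2)
  b1 <- sum(q1 * q1)
  b2 <- sum(q2 * q2)
  den <- 1 + 2 * k * cc + k^2 * b1 * b2
  if (abs(den) < 1e-12) stop("mobius_add: degenerate denominator")
  y <- ((1 + 2 * k * cc + k * b2) * q1 + (1 - k * b1) * q2) / den
  project_to_ball(y, k, eps)
}

#' Moebius scalar multiplication
#'
#' \eqn{s \otimes q = \tanh(s\,\mathrm{atanh}(\sqrt{k}\|q\|))\,
#' q/(\sqrt{k}\|q\|)}; the origin maps to itself for any \code{s}.
#'
#' @param s real scalar.
#' @param q numeric vector inside the ball.
#' @param k positive curvature.
#' @param eps ball projection margin.
#' @export
mobius_scalar_mul <- function(s, q, k, eps = 1e-5) {
  nrm <- sqrt(sum(q * q))
  if (nrm < .NORM_FLOOR) return(q * 0)
  t <- sqrt(k)
  u <- min(t * nrm, .ATANH_CLAMP)
  y <- tanh(s * atanh(u)) * q / (t * nrm)
  project_to_ball(y, k, eps)
}

#' Exponential map on the Poincare ball
#'
#' Maps a tangent vector \code{v} at base point \code{P} to the ball:
#' \deqn{\exp_P(v) = P \oplus \big(\tanh(\sqrt{k}\,\lambda_P\|v\|/2)\,
#' v/(\sqrt{k}\|v\|)\big),}
#' the standard (Ganea-style) form, mutually inverse with
#' \code{\link{log_map}}.
#'
#' @param P base point inside the ball.
#' @param v tangent vector.
#' @param k positive curvature.
#' @param eps ball projection margin.
#' @export
exp_map <- function(P, v, k, eps = 1e-5) {
  nrm <- sqrt(sum(v * v))
  if (nrm < .NORM_FLOOR) return(P)
  lam <- conformal_factor(P, k)
  t <- sqrt(k)
  w <- tanh(t * lam * nrm / 2) * v / (t * nrm)
  mobius_add(P, w, k, eps)
}

#' Logarithmic map on the Poincare ball
#'
#' Inverse of \code{\link{exp_map}}:
#' \deqn{\log_P(q) = \frac{2}{\sqrt{k}\,\lambda_P}\,
#' \mathrm{atanh}(\sqrt{k}\|(-P)\oplus q\|)\,
#' \frac{(-P)\oplus q}{\|(-P)\oplus q\|}.}
#'
#' @param P base point inside the ball.
#' @param q target point inside the ball.
#' @param k positive curvature.
#' @export
log_map <- function(P, q, k) {
  w <- mobius_add(-P, q, k, eps = .Machine$double.eps)
  nrm <- sqrt(sum(w * w))
  if (nrm < .NORM_FLOOR) return(q * 0)
  lam <- conformal_factor(P, k)
  t <- sqrt(k)
  u <- min(t * nrm, .ATANH_CLAMP)
  (2 / (t * lam)) * atanh(u) * w / nrm
}

#' Per-class decision plane of the hyperbolic classifier
#'
#' A class is represented by an offset point \code{offset} on the ball, a
#' nonzero Euclidean normal vector \code{normal}, and a positive logit
#' scale \code{zeta}.
#'
#' @param offset numeric vector inside the ball (\eqn{p_y}).
#' @param normal nonzero numeric vector (\eqn{a_y}).
#' @param zeta positive logit scale.
#' @export
class_plane <- function(offset, normal, zeta = 1) {
  if (length(offset) != length(normal))
    stop("class_plane: offset and normal dimension mismatch")
  if (sqrt(sum(normal^2)) <= 0)
    stop("class_plane: zero normal vector")
  if (!(zeta > 0)) stop("class_plane: zeta must be positive")
  structure(list(offset = offset, normal = normal, zeta = zeta),
            class = "class_plane")
}

#' Signed hyperbolic distance from a point to a class plane
#'
#' \deqn{d(z, H_y) = \frac{1}{\sqrt{k}} \mathrm{asinh}\!\left(
#' \frac{2\sqrt{k}\,\langle (-p_y)\oplus z,\ a_y\rangle}
#' {(1 - k\|(-p_y)\oplus z\|^2)\,\|a_y\|}\right).}
#' Positive on the side the normal points to; take \code{abs()} for a
#' metric distance.
#'
#' @param z numeric vector inside the ball.
#' @param plane a \code{\link{class_plane}}.
#' @param k positive curvature.
#' @export
dist_to_plane <- function(z, plane, k) {
  a <- plane$normal
  na <- sqrt(sum(a^2))
  if (na <= 0) stop("dist_to_plane: zero normal vector")
  u <- mobius_add(-plane$offset, z, k, eps = .Machine$double.eps)
  c2 <- sum(u * u)
  t <- sqrt(k)
  s <- 2 * t * sum(u * a) / max((1 - k * c2) * na, .NORM_FLOOR)
  asinh(s) / t
}

#' One Riemannian SGD step on the ball
#'
#' Rescales the Euclidean gradient by the inverse squared conformal
#' factor (normalized so the flat limit recovers plain SGD),
#' \eqn{r = 4 g / \lambda_p^2 = g\,(1 - k\|p\|^2)^2}, and retracts along
#' the exponential map: \eqn{p' = \exp_p(-\mathrm{lr}\, r)}, projected
#' into the open ball.  As \eqn{k \to 0} the update approaches
#' \eqn{p - \mathrm{lr}\, g}.
#'
#' @param param ball point being optimized.
#' @param euclidean_grad Euclidean gradient at \code{param}.
#' @param lr positive learning rate.
#' @param k positive curvature.
#' @param eps ball projection margin.
#' @export
riemannian_sgd_step <- function(param, euclidean_grad, lr, k, eps = 1e-5) {
  r <- euclidean_grad * (1 - k * sum(param^2))^2
  project_to_ball(exp_map(param, -lr * r, k, eps), k, eps)
}

## ---------------------------------------------------------------------
## Batched (row-wise) kernels with analytic backward passes.  A feature
## field is an (nvox x channels) matrix; every row is one channel vector.
## These are internal: the network trains through them.

# exp map at the origin, row-wise: y = tanh(sqrt(k) r)/(sqrt(k) r) * x.
exp0_fw <- function(x, k, eps = 1e-5) {
  r <- sqrt(rowSums(x * x))
  t <- sqrt(k)
  tr <- t * r
  small <- tr < 1e-9
  g <- ifelse(small, 1, tanh(tr) / pmax(tr, .NORM_FLOOR))
  y <- x * g
  # projection to the open ball (rarely active; treated as identity in
  # the backward pass)
  y <- project_rows(y, k, eps)
  list(y = y, cache = list(x = x, r = r, g = g, k = k, small = small))
}

exp0_bw <- function(cache, gout) {
  x <- cache$x; r <- cache$r; g <- cache$g; k <- cache$k
  t <- sqrt(k)
  tr <- t * r
  sech2 <- 1 / cosh(tr)^2
  dgdr <- ifelse(cache$small, 0, (sech2 - g) / pmax(r, .NORM_FLOOR))
  dgdk <- ifelse(cache$small, 0, (sech2 - g) / (2 * k))
  gx_dot <- rowSums(gout * x)
  gx <- gout * g + x * (gx_dot * dgdr / pmax(r, .NORM_FLOOR))
  gk <- sum(gx_dot * dgdk)
  list(gx = gx, gk = gk)
}

# log map at the origin, row-wise: x = atanh(sqrt(k) rho)/(sqrt(k) rho) y.
log0_fw <- function(y, k) {
  rho <- sqrt(rowSums(y * y))
  t <- sqrt(k)
  u <- pmin(t * rho, .ATANH_CLAMP)
  small <- u < 1e-9
  h <- ifelse(small, 1, atanh(u) / pmax(u, .NORM_FLOOR))
  x <- y * h
  list(x = x, cache = list(y = y, rho = rho, u = u, h = h, k = k,
                           small = small))
}

log0_bw <- function(cache, gout) {
  y <- cache$y; rho <- cache$rho; u <- cache$u; h <- cache$h; k <- cache$k
  inv <- 1 / (1 - u^2)
  dhdrho <- ifelse(cache$small, 0, (inv - h) / pmax(rho, .NORM_FLOOR))
  dhdk <- ifelse(cache$small, 0, (inv - h) / (2 * k))
  gy_dot <- rowSums(gout * y)
  gy <- gout * h + y * (gy_dot * dhdrho / pmax(rho, .NORM_FLOOR))
  gk <- sum(gy_dot * dhdk)
  list(gy = gy, gk = gk)
}

# Row-wise Moebius addition of two (n x d) matrices, with backward.
madd_fw <- function(q1, q2, k, eps = 1e-5, project = TRUE) {
  cc <- rowSums(q1 * q2)
  b1 <- rowSums(q1 * q1)
  b2 <- rowSums(q2 * q2)
  A <- 1 + 2 * k * cc + k * b2
  B <- 1 - k * b1
  D <- 1 + 2 * k * cc + k^2 * b1 * b2
  if (any(abs(D) < 1e-12)) stop("mobius addition: degenerate denominator")
  y <- (q1 * A + q2 * B) / D
  if (project) y <- project_rows(y, k, eps)
  list(y = y, cache = list(q1 = q1, q2 = q2, cc = cc, b1 = b1, b2 = b2,
                           A = A, B = B, D = D, y = y, k = k))
}

madd_bw <- function(cache, gout) {
  q1 <- cache$q1; q2 <- cache$q2; k <- cache$k
  A <- cache$A; B <- cache$B; D <- cache$D; y <- cache$y
  g1 <- rowSums(gout * q1)
  g2 <- rowSums(gout * q2)
  gy <- rowSums(gout * y)
  gq1 <- (gout * A + q2 * (2 * k * g1) - q1 * (2 * k * g2) -
            q2 * (2 * k * gy) - q1 * (2 * k^2 * cache$b2 * gy)) / D
  gq2 <- (gout * B + (q1 + q2) * (2 * k * g1) -
            q1 * (2 * k * gy) - q2 * (2 * k^2 * cache$b1 * gy)) / D
  gk <- sum((g1 * (2 * cache$cc + cache$b2) - g2 * cache$b1 -
               gy * (2 * cache$cc + 2 * k * cache$b1 * cache$b2)) / D)
  list(gq1 = gq1, gq2 = gq2, gk = gk)
}
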