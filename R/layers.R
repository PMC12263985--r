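# Layer primitives with hand-written backward passes.  All layers act on
# (nvox x channels) matrices in voxel-major order (see src/kernels.cpp
# for the layout contract).  Weight matrices are (27*Cin x Cout); the
# helper below also accepts 3x3x3xCinxCout arrays.

weights_to_mat <- function(w) {
  if (is.matrix(w)) return(w)
  dm <- dim(w)
  if (length(dm) != 5 || dm[1] != 3 || dm[2] != 3 || dm[3] != 3)
    stop("conv weights must be (27*Cin x Cout) or 3x3x3xCinxCout")
  cin <- dm[4]; cout <- dm[5]
  m <- matrix(0, 27 * cin, cout)
  for (co in seq_len(cout))
    for (ci in seq_len(cin))
      m[(ci - 1) * 27 + (1:27), co] <- as.vector(w[, , , ci, co])
  m
}

relu_fw <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

conv_block_fw <- function(x, dims, w, b) {
  pre <- .conv3d_fw(x, dims, w, b)
  r <- relu_fw(pre)
  list(y = r$y, cache = list(x = x, dims = dims, w = w, mask = r$mask))
}

conv_block_bw <- function(cache, gout) {
  g <- gout * cache$mask
  bw <- .conv3d_bw(cache$x, cache$dims, cache$w, g)
  list(gx = bw$gx, gw = bw$gw, gb = as.vector(bw$gb))
}

#' 3D convolution block
#'
#' \eqn{\sigma(X * W + b)}: a 3x3x3 convolution with stride 1 and
#' shape-preserving zero padding, followed by ReLU.
#'
#' @param x a Euclidean \code{\link{feature_field}}.
#' @param weights (27*Cin x Cout) matrix or 3x3x3xCinxCout array.
#' @param bias length-Cout numeric.
#' @return a Euclidean \code{\link{feature_field}} of the same spatial
#'   shape with \code{Cout} channels.
#' @export
conv_block <- function(x, weights, bias) {
  if (!inherits(x, "feature_field") || x$space != "euclidean")
    stop("conv_block: x must be a Euclidean feature_field")
  w <- weights_to_mat(weights)
  if (nrow(w) != 27 * ncol(x$data))
    stop("conv_block: weight shape does not match input channels")
  if (length(bias) != ncol(w))
    stop("conv_block: bias length does not match output channels")
  out <- conv_block_fw(x$data, x$dims, w, as.numeric(bias))
  feature_field(out$y, x$dims, "euclidean")
}

#' Poincare embedding of a Euclidean feature field
#'
#' Maps every channel vector through the exponential map at the origin
#' under the current curvature, then projects into the open ball, so the
#' output satisfies \eqn{k\|v\|^2 < 1} voxel-wise.
#'
#' @param f a Euclidean \code{\link{feature_field}}.
#' @param m a \code{\link{manifold_params}} object.
#' @return a hyperbolic \code{\link{feature_field}}.
#' @export
poincare_embed <- function(f, m) {
  if (!inherits(f, "feature_field") || f$space != "euclidean")
    stop("poincare_embed: f must be a Euclidean feature_field")
  k <- curvature_value(m)
  y <- exp0_fw(f$data, k, m$eps_ball)$y
  feature_field(y, f$dims, "hyperbolic", curvature = k)
}

# Moebius convolution, tangent-space approximation:
# log0 -> Euclidean 3x3x3 conv -> exp0 -> Moebius-add a learned bias
# point (bias second, Ganea convention).
mconv_fw <- function(h, dims, w, bias_point, k, eps = 1e-5) {
  lg <- log0_fw(h, k)
  pre <- .conv3d_fw(lg$x, dims, w, numeric(ncol(w)))
  ex <- exp0_fw(pre, k, eps)
  bp <- project_to_ball(bias_point, k, eps)
  bmat <- matrix(rep(bp, each = nrow(h)), nrow(h), length(bp))
  ad <- madd_fw(ex$y, bmat, k, eps)
  list(y = ad$y,
       cache = list(lg = lg, x_tan = lg$x, dims = dims, w = w,
                    ex = ex, ad = ad, k = k))
}

mconv_bw <- function(cache, gout) {
  mb <- madd_bw(cache$ad$cache, gout)
  gbias <- colSums(mb$gq2)
  eb <- exp0_bw(cache$ex$cache, mb$gq1)
  cw <- .conv3d_bw(cache$x_tan, cache$dims, cache$w, eb$gx)
  lb <- log0_bw(cache$lg$cache, cw$gx)
  gk <- mb$gk + eb$gk + lb$gk
  list(gh = lb$gy, gw = cw$gw, gbias = gbias, gk = gk)
}

#' Moebius convolution on a hyperbolic feature field
#'
#' Tangent-space approximation of a hyperbolic convolution: log map at
#' the origin, Euclidean 3x3x3 convolution, exponential map back, then
#' Moebius addition of a learned bias point.
#'
#' @param f a hyperbolic \code{\link{feature_field}}.
#' @param weights (27*Cin x Cout) matrix or 3x3x3xCinxCout array.
#' @param bias length-Cout numeric, a ball point added via Moebius
#'   addition.
#' @param m a \code{\link{manifold_params}} object.
#' @export
mobius_conv <- function(f, weights, bias, m) {
  if (!inherits(f, "feature_field") || f$space != "hyperbolic")
    stop("mobius_conv: f must be a hyperbolic feature_field")
  k <- curvature_value(m)
  w <- weights_to_mat(weights)
  out <- mconv_fw(f$data, f$dims, w, as.numeric(bias), k, m$eps_ball)
  feature_field(out$y, f$dims, "hyperbolic", curvature = k)
}

# Dual Euclidean/hyperbolic encoder block:
#   c   = conv_block(x)                      (shared stem, width w)
#   F_e = c
#   F_h = mconv(exp0(c))                     (hyperbolic branch, width w)
#   out = maxpool2(concat[F_e, log0(F_h)])   (2w channels, dims/2)
# The pre-pool concatenation is the skip connection.
dual_block_fw <- function(x, dims, We, be, Wh, bh, k, eps = 1e-5) {
  cb <- conv_block_fw(x, dims, We, be)
  em <- exp0_fw(cb$y, k, eps)
  mc <- mconv_fw(em$y, dims, Wh, bh, k, eps)
  lg <- log0_fw(mc$y, k)
  skip <- cbind(cb$y, lg$x)
  mp <- .maxpool2_fw(skip, dims)
  list(y = mp$y, skip = skip, dims_out = dims %/% 2L,
       cache = list(cb = cb, em = em, mc = mc, lg = lg,
                    argmax = mp$argmax, nvox = nrow(skip), dims = dims))
}

# gout: gradient on pooled output; gskip: gradient fed directly into the
# pre-pool skip tensor by the decoder (may be NULL).
dual_block_bw <- function(cache, gout, gskip = NULL) {
  gcat <- .maxpool2_bw(gout, cache$argmax, cache$nvox)
  if (!is.null(gskip)) gcat <- gcat + gskip
  w <- ncol(cache$cb$y)
  ge <- gcat[, seq_len(w), drop = FALSE]
  gh_tan <- gcat[, w + seq_len(w), drop = FALSE]
  lb <- log0_bw(cache$lg$cache, gh_tan)
  mb <- mconv_bw(cache$mc$cache, lb$gy)
  eb <- exp0_bw(cache$em$cache, mb$gh)
  gc_total <- ge + eb$gx
  cb <- conv_block_bw(cache$cb$cache, gc_total)
  list(gx = cb$gx, gWe = cb$gw, gbe = cb$gb, gWh = mb$gw,
       gbh = mb$gbias, gk = lb$gk + mb$gk + eb$gk)
}

#' Dual Euclidean/hyperbolic encoder block
#'
#' One encoder stage: a shared convolution block feeds a Euclidean branch
#' and a hyperbolic branch (Poincare embedding followed by Moebius
#' convolution); the hyperbolic features are mapped back through the log
#' map at the origin, both branches are concatenated along channels and
#' downsampled with 2x MaxPooling.  Halves each spatial dimension and
#' doubles the nominal width.
#'
#' @param x a Euclidean \code{\link{feature_field}} with even spatial
#'   dims.
#' @param We,be Euclidean conv weights/bias (width w).
#' @param Wh,bh hyperbolic branch conv weights and ball-point bias.
#' @param m a \code{\link{manifold_params}} object.
#' @return a Euclidean \code{\link{feature_field}} with 2w channels at
#'   half resolution.
#' @export
dual_encoder_block <- function(x, We, be, Wh, bh, m) {
  if (!inherits(x, "feature_field") || x$space != "euclidean")
    stop("dual_encoder_block: x must be a Euclidean feature_field")
  if (any(x$dims %% 2L != 0L))
    stop("dual_encoder_block: spatial dims must be even")
  k <- curvature_value(m)
  out <- dual_block_fw(x$data, x$dims, weights_to_mat(We), as.numeric(be),
                       weights_to_mat(Wh), as.numeric(bh), k, m$eps_ball)
  feature_field(out$y, out$dims_out, "euclidean")
}
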