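# Poincare-ball core: curvature, Moebius arithmetic, manifold maps,
# plane distances, Riemannian step, and the analytic backward passes.

test_that("curvature parametrization matches the exponential form", {
  m <- manifold_params(sigma = 0, l_k = 1)
  expect_equal(curvature_value(m), 1.001)
  # sigma -> -Inf approaches the floor from above, never attained
  expect_gt(curvature_value(manifold_params(sigma = -40)), 1e-3)
  expect_lt(curvature_value(manifold_params(sigma = -40)), 1e-3 + 1e-12)
  expect_equal(curvature_value(manifold_params(sigma = 1, l_k = 0.5)),
               exp(0.5) + 1e-3)
  # strictly increasing in sigma for l_k > 0, bounded below by l_0
  # (below sigma ~ -40, exp(l_k*sigma) drops under the ulp of l_0 and
  # the increase is no longer representable in float64)
  sig <- seq(-40, 50, length.out = 41)
  ks <- vapply(sig, function(s) curvature_value(manifold_params(sigma = s)),
               numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_true(all(ks > 1e-3))
  expect_gte(curvature_value(manifold_params(sigma = -50)), 1e-3)
  expect_error(manifold_params(sigma = NaN), "finite")
  expect_error(manifold_params(l_0 = 0), "l_0")
  expect_error(manifold_params(eps_ball = 0.5), "eps_ball")
})

test_that("conformal factor", {
  expect_equal(conformal_factor(c(0, 0, 0), 1), 2)
  expect_equal(conformal_factor(c(0.4, 0.3), 1e-9), 2, tolerance = 1e-6)
  expect_equal(conformal_factor(c(sqrt(0.5), 0), 1), 4)
  expect_error(conformal_factor(c(1, 0), 1), "outside")
})

test_that("Moebius addition identities and examples", {
  expect_equal(mobius_add(c(0.3, 0), c(0.4, 0), 1)[1],
               (0.3 + 0.4) / (1 + 0.3 * 0.4), tolerance = 1e-12)
  expect_equal(mobius_add(c(0.3, 0), c(0.4, 0), 1), c(0.625, 0),
               tolerance = 1e-12)
  set.seed(1)
  for (k in c(1e-3, 0.1, 1, 2)) {
    for (i in 1:250) {
      q1 <- rand_ball_point(3, k)
      q2 <- rand_ball_point(3, k)
      expect_equal(mobius_add(q1, numeric(3), k), q1, tolerance = 1e-6)
      expect_equal(mobius_add(-q1, q1, k), numeric(3), tolerance = 1e-6)
      expect_equal(
        mobius_add(-q1, mobius_add(q1, q2, k, eps = 1e-12), k, eps = 1e-12),
        q2, tolerance = 1e-6)
    }
  }
})

test_that("Moebius scalar multiplication", {
  q <- c(0.3, -0.2, 0.1)
  expect_equal(mobius_scalar_mul(1, q, 0.7), q, tolerance = 1e-9)
  expect_equal(mobius_scalar_mul(0, q, 0.7), c(0, 0, 0))
  expect_equal(mobius_scalar_mul(2, c(0.5, 0), 1), c(0.8, 0),
               tolerance = 1e-9)  # tanh double angle: 2*0.5/(1+0.25)
})

test_that("exp and log maps are mutually inverse", {
  expect_equal(exp_map(c(0.1, 0.2), c(0, 0), 1), c(0.1, 0.2))
  expect_equal(exp_map(c(0, 0), c(1, 0), 1), c(tanh(1), 0),
               tolerance = 1e-6)
  expect_equal(log_map(c(0, 0), c(tanh(1), 0), 1), c(1, 0),
               tolerance = 1e-6)
  expect_equal(log_map(c(0.1, -0.2), c(0.1, -0.2), 1), c(0, 0))
  # round trips: base points at moderate radius (<= 0.6 of the ball
  # boundary; closer to the rim tanh saturates in float64), tangent
  # norms up to 2
  set.seed(2)
  for (i in 1:300) {
    k <- stats::runif(1, 0.01, 2)
    P <- rand_ball_point(3, k, max_frac = 0.6)
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, 2)
    q <- exp_map(P, v, k, eps = 1e-9)
    expect_equal(log_map(P, q, k), v, tolerance = 1e-5)
    q2 <- rand_ball_point(3, k, max_frac = 0.6)
    expect_equal(exp_map(P, log_map(P, q2, k), k, eps = 1e-9), q2,
                 tolerance = 1e-5)
  }
})

test_that("Euclidean limit at k = 1e-6", {
  set.seed(3)
  k <- 1e-6
  for (i in 1:50) {
    z <- stats::rnorm(3) * 0.3
    p <- stats::rnorm(3) * 0.3
    a <- stats::rnorm(3)
    expect_equal(mobius_add(z, p, k), z + p, tolerance = 1e-4)
    expect_equal(exp_map(p, z, k), p + z, tolerance = 1e-4)
    expect_equal(dist_to_plane(z, class_plane(p, a), k),
                 2 * sum((z - p) * a) / sqrt(sum(a^2)), tolerance = 1e-4)
  }
})

test_that("distance to class plane: sign and degeneracies", {
  k <- 0.5
  p <- c(0.1, 0.2, -0.1)
  a <- c(1, -1, 2)
  pl <- class_plane(p, a)
  # the offset point itself lies on its plane
  expect_equal(dist_to_plane(p, pl, k), 0)
  set.seed(4)
  z <- rand_ball_point(3, k)
  expect_equal(dist_to_plane(z, class_plane(p, -a), k),
               -dist_to_plane(z, pl, k), tolerance = 1e-12)
  expect_error(class_plane(p, c(0, 0, 0)), "zero normal")
})

test_that("projection and ball invariant under chained additions", {
  k <- 1
  x <- c(2, 0, 0)
  px <- project_to_ball(x, k, 1e-5)
  expect_equal(sqrt(sum(px^2)), 1 - 1e-5)
  expect_equal(project_to_ball(c(0.2, 0.1), k), c(0.2, 0.1))
  set.seed(5)
  q <- numeric(3)
  for (i in 1:10000) {
    q <- mobius_add(q, stats::rnorm(3) * 0.4, k)
    if (i %% 1000 == 0) expect_lt(k * sum(q^2), 1)
  }
  expect_lt(k * sum(q^2), 1)
})

test_that("Riemannian SGD step", {
  p <- c(0.2, -0.1)
  expect_equal(riemannian_sgd_step(p, c(0, 0), 0.1, 1), p)
  # flat limit recovers plain SGD
  g <- c(0.5, 0.3)
  expect_equal(riemannian_sgd_step(p, g, 0.1, 1e-6), p - 0.1 * g,
               tolerance = 1e-4)
  # ball invariant for any gradient magnitude
  set.seed(6)
  for (i in 1:50) {
    k <- stats::runif(1, 0.1, 2)
    st <- riemannian_sgd_step(rand_ball_point(3, k),
                              stats::rnorm(3) * 10^stats::runif(1, 0, 4),
                              0.5, k)
    expect_lt(k * sum(st^2), 1)
  }
})

test_that("batched hyperbolic backward passes match finite differences", {
  set.seed(7)
  k <- 0.8
  X <- matrix(stats::rnorm(12) * 0.7, 4, 3)
  G <- matrix(stats::rnorm(12), 4, 3)
  fw <- hs$exp0_fw(X, k)
  bw <- hs$exp0_bw(fw$cache, G)
  expect_equal(matrix(numgrad(function(v)
    sum(G * hs$exp0_fw(matrix(v, 4, 3), k)$y), as.vector(X)), 4, 3),
    bw$gx, tolerance = 1e-5)
  expect_equal(numgrad(function(kk) sum(G * hs$exp0_fw(X, kk)$y), k),
               bw$gk, tolerance = 1e-5)

  Y <- fw$y
  fl <- hs$log0_fw(Y, k)
  bl <- hs$log0_bw(fl$cache, G)
  expect_equal(matrix(numgrad(function(v)
    sum(G * hs$log0_fw(matrix(v, 4, 3), k)$x), as.vector(Y)), 4, 3),
    bl$gy, tolerance = 1e-5)
  expect_equal(numgrad(function(kk) sum(G * hs$log0_fw(Y, kk)$x), k),
               bl$gk, tolerance = 1e-5)

  Q1 <- matrix(stats::rnorm(12) * 0.3, 4, 3)
  Q2 <- matrix(stats::rnorm(12) * 0.3, 4, 3)
  fm <- hs$madd_fw(Q1, Q2, k, project = FALSE)
  bm <- hs$madd_bw(fm$cache, G)
  expect_equal(matrix(numgrad(function(v)
    sum(G * hs$madd_fw(matrix(v, 4, 3), Q2, k, project = FALSE)$y),
    as.vector(Q1)), 4, 3), bm$gq1, tolerance = 1e-5)
  expect_equal(matrix(numgrad(function(v)
    sum(G * hs$madd_fw(Q1, matrix(v, 4, 3), k, project = FALSE)$y),
    as.vector(Q2)), 4, 3), bm$gq2, tolerance = 1e-5)
  expect_equal(numgrad(function(kk)
    sum(G * hs$madd_fw(Q1, Q2, kk, project = FALSE)$y), k), bm$gk,
    tolerance = 1e-5)
})

test_that("HMLR backward matches finite differences", {
  set.seed(8)
  k <- 1.001
  nvox <- 5; n <- 4; C <- 3
  Z <- hs$exp0_fw(matrix(stats::rnorm(nvox * n) * 0.5, nvox, n), k)$y
  planes <- lapply(1:C, function(i)
    list(offset = rand_ball_point(n, k, 0.3), normal = stats::rnorm(n),
         zeta = stats::runif(1, 0.5, 2)))
  G <- matrix(stats::rnorm(nvox * C), nvox, C)
  fw <- hs$hmlr_fw(Z, planes, k)
  bw <- hs$hmlr_bw(fw, G)
  expect_equal(matrix(numgrad(function(v)
    sum(G * hs$hmlr_fw(matrix(v, nvox, n), planes, k)$logits),
    as.vector(Z)), nvox, n), bw$gz, tolerance = 1e-4)
  for (ci in 1:C) {
    gp <- numgrad(function(v) {
      pl <- planes; pl[[ci]]$offset <- v
      sum(G * hs$hmlr_fw(Z, pl, k)$logits)
    }, planes[[ci]]$offset)
    ga <- numgrad(function(v) {
      pl <- planes; pl[[ci]]$normal <- v
      sum(G * hs$hmlr_fw(Z, pl, k)$logits)
    }, planes[[ci]]$normal)
    gz <- numgrad(function(v) {
      pl <- planes; pl[[ci]]$zeta <- v
      sum(G * hs$hmlr_fw(Z, pl, k)$logits)
    }, planes[[ci]]$zeta)
    expect_equal(gp, bw$gplanes[[ci]]$offset, tolerance = 1e-4)
    expect_equal(ga, bw$gplanes[[ci]]$normal, tolerance = 1e-4)
    expect_equal(gz, bw$gplanes[[ci]]$zeta, tolerance = 1e-4)
  }
  expect_equal(numgrad(function(kk)
    sum(G * hs$hmlr_fw(Z, planes, kk)$logits), k), bw$gk,
    tolerance = 1e-4)
})
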