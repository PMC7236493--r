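test_that("kernel_eval computes linear and gaussian kernels", {
  expect_equal(kernel_eval(c(1, 2), c(3, -1), kernel_config("linear")), 1)
  kc <- kernel_config("gaussian", 1)
  expect_equal(kernel_eval(c(1, 0), c(1, 0), kc), 1)
  expect_equal(kernel_eval(c(1, 0), c(0, 0), kc), exp(-0.5))
  expect_equal(kernel_eval(c(1, 0), c(0, 0), kernel_config("gaussian", 1e6)), 1,
               tolerance = 1e-9)
  expect_error(kernel_eval(c(1, 2), c(1, 2, 3), kc), "mismatch")
  ## matrix form agrees with pairwise evaluation
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  K <- kernel_matrix(X, X, kc)
  for (i in 1:4) for (j in 1:4)
    expect_equal(K[i, j], kernel_eval(X[i, ], X[j, ], kc), tolerance = 1e-12)
})

test_that("gradient representer matches the kernel derivative (finite differences)", {
  set.seed(11)
  for (d in 1:3) for (r in 1:8) {
    x <- rnorm(d); xi <- rnorm(d)
    j <- sample(d, 1); s <- sample(c(0.5, 1, 2), 1)
    kc <- kernel_config("gaussian", s)
    h <- 1e-5
    xp <- xi; xp[j] <- xp[j] + h
    xm <- xi; xm[j] <- xm[j] - h
    fd <- (kernel_eval(x, xp, kc) - kernel_eval(x, xm, kc)) / (2 * h)
    expect_equal(grad_representer_eval(x, xi, j, s), fd, tolerance = 1e-6)
  }
  ## zero at the anchor, antisymmetric under exchange
  x <- c(0.3, -0.2); xi <- c(-1, 0.5)
  expect_equal(grad_representer_eval(xi, xi, 1, 1), 0)
  expect_equal(grad_representer_eval(x, xi, 2, 1),
               -grad_representer_eval(xi, x, 2, 1))
})

test_that("representer dot product matches the mixed second kernel derivative", {
  set.seed(12)
  for (d in 1:3) for (r in 1:8) {
    xi <- rnorm(d); xp <- rnorm(d)
    j <- sample(d, 1); q <- sample(d, 1); s <- 1
    h <- 1e-4
    e_j <- numeric(d); e_j[j] <- h
    e_q <- numeric(d); e_q[q] <- h
    kc <- kernel_config("gaussian", s)
    fd <- (kernel_eval(xi + e_j, xp + e_q, kc) - kernel_eval(xi + e_j, xp - e_q, kc) -
           kernel_eval(xi - e_j, xp + e_q, kc) + kernel_eval(xi - e_j, xp - e_q, kc)) / (4 * h^2)
    v <- grad_representer_dot(xi, j, xp, q, s)
    expect_equal(v, fd, tolerance = 1e-4)
    expect_equal(v, grad_representer_dot(xp, q, xi, j, s))  # symmetry
  }
  ## coincident anchors, same variable: exactly 1/sigma^2 across the width grid
  for (s in c(0.25, 0.5, 1, 2, 4)) {
    x <- rnorm(3)
    expect_equal(grad_representer_dot(x, 2, x, 2, s), 1 / s^2)
  }
})

test_that("averaging representer matches the convolution quadrature oracle (d = 1)", {
  icfg <- invariance_config("averaging", sigma_k = 1, sigma_p = 0.5, d = 1)
  set.seed(13)
  for (r in 1:6) {
    x <- rnorm(1); xi <- rnorm(1)
    quad <- integrate(function(u) exp(-(x - u)^2 / 2) * dnorm(xi - u, 0, 0.5),
                      -10, 10)$value - exp(-(x - xi)^2 / 2)
    expect_equal(avg_representer_eval(x, xi, icfg), quad, tolerance = 1e-5)
  }
  ## sigma_p -> 0: averaging over a point neighbourhood changes nothing
  icfg0 <- invariance_config("averaging", sigma_k = 1, sigma_p = 1e-6, d = 1)
  expect_equal(avg_representer_eval(0.4, -0.3, icfg0), 0, tolerance = 1e-6)
  ## decay at long range
  expect_lt(abs(avg_representer_eval(50, 0, icfg)), 1e-10)
})

test_that("averaging dot product matches nested quadrature and is a valid inner product", {
  icfg <- invariance_config("averaging", sigma_k = 1, sigma_p = 0.5, d = 1)
  mu <- function(a, b) integrate(function(u) exp(-(b - u)^2 / 2) * dnorm(a - u, 0, 0.5),
                                 -10, 10)$value
  set.seed(14)
  for (r in 1:4) {
    xi <- rnorm(1); xj <- rnorm(1)
    A <- integrate(function(u) sapply(u, function(uu)
      integrate(function(v) exp(-(uu - v)^2 / 2) * dnorm(xi - uu, 0, 0.5) *
                  dnorm(xj - v, 0, 0.5), -10, 10)$value), -10, 10)$value
    quad <- A - mu(xi, xj) - mu(xj, xi) + exp(-(xi - xj)^2 / 2)
    v <- avg_representer_dot(xi, xj, icfg)
    expect_equal(v, quad, tolerance = 1e-4)
    expect_equal(v, avg_representer_dot(xj, xi, icfg))      # symmetry
  }
  ## d = 1 worked case from the derivation, and diagonal = squared norm >= 0
  expect_gte(avg_representer_dot(0, 0, icfg), 0)
  expect_equal(avg_representer_dot(0, 1, icfg),
               {
                 A <- integrate(function(u) sapply(u, function(uu)
                   integrate(function(v) exp(-(uu - v)^2 / 2) * dnorm(0 - uu, 0, 0.5) *
                               dnorm(1 - v, 0, 0.5), -10, 10)$value), -10, 10)$value
                 A - mu(0, 1) - mu(1, 0) + exp(-0.5)
               }, tolerance = 1e-4)
})

test_that("build_gram assembles symmetric near-PSD block matrices of the right shape", {
  set.seed(15)
  kc <- kernel_config("gaussian", 1)
  ## zero anchors: plain kernel Gram
  X <- matrix(rnorm(10), 5, 2)
  g0 <- build_gram(X, NULL, kc)
  expect_equal(dim(g0$K_fz), c(5, 0))
  expect_equal(g0$K_ff, kernel_matrix(X, X, kc))
  ## 3 anchors, d = 2, gradient: K_zz is 6x6
  A <- matrix(rnorm(6), 3, 2)
  icfg_g <- invariance_config("gradient", sigma_k = 1, d = 2)
  gg <- build_gram(X, A, kc, icfg_g)
  expect_equal(dim(gg$K_zz), c(6, 6))
  expect_equal(nrow(gg$index_map), 6)
  ## averaging: one representer per anchor
  icfg_a <- invariance_config("averaging", sigma_k = 1, sigma_p = 0.5, d = 2)
  ga <- build_gram(X, A, kc, icfg_a)
  expect_equal(dim(ga$K_zz), c(3, 3))
  ## random 20-point sets: smallest eigenvalue of the block matrix >= -1e-6
  for (icfg in list(icfg_g, icfg_a)) {
    Xr <- matrix(rnorm(40), 20, 2)
    Ar <- matrix(rnorm(16), 8, 2)
    g <- build_gram(Xr, Ar, kc, icfg)
    expect_equal(g$full, t(g$full))
    ev <- eigen(g$full, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-6)
  }
  ## K_fz entries agree with pointwise representer evaluation
  expect_equal(ga$K_fz[2, 3], avg_representer_eval(X[2, ], A[3, ], icfg_a),
               tolerance = 1e-10)
  expect_equal(gg$K_fz[4, 5], grad_representer_eval(X[4, ], A[3, ], 1, 1),
               tolerance = 1e-10)
  expect_error(build_gram(X, A, kernel_config("linear"), icfg_a), "gaussian")
})
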