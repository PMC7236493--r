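test_that("weighted SVM solves the max-margin toy and honors weights", {
  ## symmetric pair, large C, linear kernel: boundary x1 = 0, margin 1
  m <- train_wsvm(rbind(c(-1, 0), c(1, 0)), c(-1, 1), c(1, 1), train_config(C = 100))
  expect_equal(decision(m, c(1, 0)), 1, tolerance = 1e-6)
  expect_equal(decision(m, c(0, 5)), 0, tolerance = 1e-6)
  ## weight-1 fit identical to a standard C-SVM (e1071 cross-check)
  skip_if_not_installed("e1071")
  b <- make_blobs(15, sep = 2, seed = 21)
  m1 <- train_wsvm(b$x, b$y, rep(1, 30), train_config(C = 1))
  sv <- e1071::svm(b$x, factor(b$y), kernel = "linear", cost = 1, scale = FALSE)
  dec <- attr(predict(sv, b$x, decision.values = TRUE), "decision.values")[, 1]
  if (colnames(attr(predict(sv, b$x, decision.values = TRUE), "decision.values")) == "-1/1")
    dec <- -dec
  expect_equal(decision(m1, b$x), unname(dec), tolerance = 1e-3)
  ## zero-weight samples are inert
  b2 <- make_blobs(10, sep = 3, seed = 22)
  W <- rep(1, 20); W[c(1, 11)] <- 0
  m2 <- train_wsvm(b2$x, b2$y, W, train_config(C = 5))
  m3 <- train_wsvm(b2$x[-c(1, 11), ], b2$y[-c(1, 11)], W[-c(1, 11)], train_config(C = 5))
  expect_equal(decision(m2, b2$x), decision(m3, b2$x), tolerance = 1e-5)
  expect_error(train_wsvm(b2$x, rep(1, 20), W, train_config()), "both classes")
})

test_that("probability_to_bounds maps probabilities to the margin scale", {
  expect_equal(probability_to_bounds(0.5, 0.1), list(z_minus = -0.1, z_plus = 0.1))
  expect_equal(probability_to_bounds(1, 0), list(z_minus = 1, z_plus = 1))
  expect_equal(probability_to_bounds(0.25, 0.1), list(z_minus = -0.6, z_plus = -0.4))
  expect_error(probability_to_bounds(1.2, 0.1), "\\[0, 1\\]")
})

test_that("probabilistic SVM collapses to a plain SVM without uncertain points", {
  b <- make_blobs(12, sep = 2, seed = 23)
  mp <- train_psvm(b$x, b$y, NULL, train_config(C = 2))
  mw <- train_wsvm(b$x, b$y, rep(1, 24), train_config(C = 2))
  expect_equal(decision(mp, b$x), decision(mw, b$x), tolerance = 1e-5)
})

test_that("a maximally uncertain point placed symmetrically sits on the boundary", {
  ## two symmetric certain pairs + one uncertain point at p = 0.5 on the axis
  X <- rbind(c(-1, 1), c(-1, -1), c(1, 1), c(1, -1), c(0, 0.7))
  y <- c(-1, -1, 1, 1, NA)
  p <- c(NA, NA, NA, NA, 0.5)
  m <- train_psvm(X, y, p, train_config(C = 10, C_tilde = 10, epsilon = 0.05))
  expect_equal(decision(m, c(0, 0.7)), 0, tolerance = 1e-4)
})

test_that("LUPI rejects privileged information as gamma tends to zero", {
  set.seed(24)
  X <- matrix(rnorm(30), 15, 2)
  y <- ifelse(X[, 1] + 0.5 * rnorm(15) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  ## well-conditioned correcting space so slack interpolation is cheap
  Xs <- matrix(seq(-2, 2, length.out = 15), 15, 1)
  ks <- kernel_config("gaussian", 0.1)
  msvm <- train_wsvm(X, y, rep(1, 15), train_config(C = 1))
  gaps <- vapply(c(1, 0.1, 0.01, 0.001), function(g) {
    ml <- train_lupi(X, Xs, y, train_config(C = 1, gamma_lupi = g,
                                            correcting_kernel = ks))
    max(abs(decision(ml, X) - decision(msvm, X)))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))      # monotone approach
  expect_lt(gaps[4], 0.01)
})

test_that("identical privileged vectors give a constant correcting function", {
  b <- make_blobs(10, sep = 1.5, seed = 25)
  Xs <- matrix(1, 20, 1)
  m <- train_lupi(b$x, Xs, b$y, train_config(C = 1, gamma_lupi = 1))
  Ks <- kernel_matrix(Xs, Xs, m$correcting_kernel)
  corr <- as.numeric(Ks %*% m$a_star) + m$b_star
  expect_lt(diff(range(corr)), 1e-6)
  expect_error(train_lupi(b$x, Xs[1:5, , drop = FALSE], b$y, train_config()),
               "every training sample")
})

test_that("invariance SVM reduces to a labeled-only SVM without anchors or with a huge tube", {
  b <- make_blobs(8, sep = 2.5, seed = 26)
  Xu <- matrix(rnorm(10), 5, 2)
  kc <- kernel_config("gaussian", 1)
  icfg <- invariance_config("averaging", sigma_k = 1, sigma_p = 0.5, d = 2)
  m0 <- train_insvm(b$x, b$y, NULL, train_config(kernel = kc))
  mB <- train_insvm(b$x, b$y, Xu, train_config(kernel = kc, epsilon = 100,
                                               invariance = icfg))
  expect_equal(decision(mB, b$x), decision(m0, b$x), tolerance = 1e-5)
  expect_error(train_insvm(b$x, b$y, Xu,
                           train_config(kernel = kernel_config("linear"),
                                        invariance = icfg)), "gaussian")
})

test_that("semi-supervised fit keeps labeled accuracy close to the supervised fit", {
  ## two interleaved arcs, half the points unlabeled
  set.seed(27)
  th <- runif(40, 0, pi)
  X <- rbind(cbind(cos(th[1:20]), sin(th[1:20])),
             cbind(1 - cos(th[21:40]), 0.4 - sin(th[21:40])))
  y <- rep(c(-1, 1), each = 20)
  lab <- c(1:10, 21:30)
  kc <- kernel_config("gaussian", 0.7)
  icfg <- invariance_config("averaging", sigma_k = 0.7, sigma_p = 0.35, d = 2)
  m_semi <- train_insvm(X[lab, ], y[lab], X[-lab, ],
                        train_config(kernel = kc, epsilon = 0.1, invariance = icfg))
  m_sup <- train_insvm(X[lab, ], y[lab], NULL, train_config(kernel = kc))
  expect_true(all(is.finite(decision(m_semi, X))))
  acc_semi <- mean(classify(m_semi, X[lab, ]) == y[lab])
  acc_sup <- mean(classify(m_sup, X[lab, ]) == y[lab])
  expect_gte(acc_semi, acc_sup - 0.05)
})

test_that("every trainer matches its independently typed QP oracle on random problems", {
  skip_if_not_installed("pracma")
  set.seed(30)
  for (r in 1:6) {
    n <- sample(12:25, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.5, 1, 5), 1)
    ## weighted
    W <- runif(n)
    mw <- train_wsvm(X, y, W, train_config(C = C))
    expect_equal(fitted_wsvm_obj(mw, X, y, W, C), oracle_wsvm_obj(X, y, W, C),
                 tolerance = 1e-5)
    ## probabilistic
    yp <- y; p <- rep(NA_real_, n)
    unc <- sample(n, 4)
    while (length(unique(yp[-unc])) < 2) unc <- sample(n, 4)
    yp[unc] <- NA; p[unc] <- runif(4)
    mp <- train_psvm(X, yp, p, train_config(C = C, C_tilde = 2, epsilon = 0.1))
    expect_equal(fitted_psvm_obj(mp, X, yp, p, C, 2, 0.1),
                 oracle_psvm_obj(X, yp, p, C, 2, 0.1), tolerance = 1e-5)
    ## privileged information (linear kernels, input-space oracle)
    Xs <- matrix(runif(n * 2), n, 2)
    ml <- train_lupi(X, Xs, y, train_config(C = C, gamma_lupi = 0.5))
    expect_equal(fitted_lupi_obj(ml, C), oracle_lupi_obj(X, Xs, y, C, 0.5),
                 tolerance = 1e-5)
    ## local invariances (both functionals)
    kind <- if (r %% 2 == 0) "averaging" else "gradient"
    icfg <- invariance_config(kind, sigma_k = 1,
                              sigma_p = if (kind == "averaging") 0.5 else NULL, d = 2)
    cfg <- train_config(kernel = kernel_config("gaussian", 1), epsilon = 0.1,
                        invariance = icfg)
    Xu <- matrix(rnorm(8), 4, 2)
    mi <- train_insvm(X, y, Xu, cfg, anchors = "unlabeled")
    gram <- build_gram(X, Xu, cfg$kernel, icfg)
    expect_equal(fitted_insvm_obj(mi, gram, y, 0.1),
                 oracle_insvm_obj(gram, y, 0.1), tolerance = 1e-5)
  }
})

test_that("dual solutions respect their box constraints", {
  set.seed(31)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rep(c(-1, 1), 10)
  W <- runif(n)
  m <- train_wsvm(X, y, W, train_config(C = 3))
  expect_true(all(m$alpha >= -1e-8 & m$alpha <= 3 * W + 1e-8))
})

test_that("decision and classify behave as a signed kernel expansion", {
  b <- make_blobs(10, sep = 2, seed = 32)
  m <- train_wsvm(b$x, b$y, rep(1, 20), train_config(C = 1))
  expect_equal(classify(m, b$x), ifelse(decision(m, b$x) >= 0, 1, -1))
  ## exact zero goes to +1
  m0 <- m; m0$coef[] <- 0; m0$b <- 0
  expect_equal(classify(m0, b$x[1, ]), 1)
  ## scaling the expansion scales decisions, classes unchanged
  m2 <- m; m2$coef <- 2 * m$coef; m2$b <- 2 * m$b
  expect_equal(decision(m2, b$x), 2 * decision(m, b$x), tolerance = 1e-10)
  expect_equal(classify(m2, b$x), classify(m, b$x))
  expect_error(decision(m, c(1, 2, 3)), "dimension")
})

test_that("assemble_training_sets applies the censoring-weighting rules", {
  tau <- 18
  time <- c(18, 9, 0.001, 9, 18)
  status <- c(0, 1, 0, 0, 1)
  x <- matrix(seq_len(10), 5, 2)
  d <- survival_dataset(time, status, x, tau = tau)
  ## wsvm / conditional: early-censored points inherit the cohort survival
  sw <- assemble_training_sets(d, "wsvm", "km")
  expect_equal(sw$W[c(1, 2, 5)], c(1, 1, 1))   # events / completed follow-up
  expect_equal(sw$y[c(1, 2, 5)], c(-1, 1, 1))
  curve <- km_fit(d)
  s3 <- km_survival_at(curve, tau) / km_survival_at(curve, 0.001)  # z = tau - t_i
  expect_equal(sw$W[3], if (s3 >= 0.5) s3 else 1 - s3)
  expect_equal(sw$y[3], if (s3 >= 0.5) -1 else 1)
  ## wsvm / proportional
  swp <- assemble_training_sets(d, "wsvm", "prop")
  expect_equal(swp$W[4], 0.5)
  expect_equal(swp$y[4], -1)
  ## psvm: censored points become uncertain with the event probability
  sp <- assemble_training_sets(d, "psvm", "km")
  expect_true(all(is.na(sp$y[c(3, 4)])))
  s4 <- km_survival_at(curve, tau) / km_survival_at(curve, 9)
  expect_equal(sp$p[4], 1 - s4)
  spp <- assemble_training_sets(d, "psvm", "prop")
  expect_equal(spp$p[4], 0.5)
  ## lupi: privileged info per scheme; events pinned to 0
  sl <- assemble_training_sets(d, "lupi", "km")
  expect_equal(ncol(sl$x_star), 1)
  expect_equal(sl$x_star[2, 1], 0)    # event
  expect_equal(sl$x_star[1, 1], 1)    # completed follow-up
  expect_equal(sl$x_star[4, 1], s4)
  expect_equal(sl$y[c(3, 4)], c(-1, -1))
  slp <- assemble_training_sets(d, "lupi", "prop")
  expect_equal(ncol(slp$x_star), 2)
  expect_equal(slp$x_star[2, 2], 0)   # event weight pinned to 0
  expect_equal(slp$x_star[4, ], c(9, 0.5))
  ## insvm: labeled vs unlabeled split
  si <- assemble_training_sets(d, "insvm", "km")
  expect_equal(nrow(si$x_l), 3)
  expect_equal(nrow(si$x_u), 2)
  ## censored at exactly tau is a nonevent everywhere
  expect_equal(sw$y[1], -1)
  expect_equal(sw$W[1], 1)
})
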