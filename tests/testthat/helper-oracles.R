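## Independent oracles used across the suite. All QP oracles are typed
## directly from the primal optimization problems (input-space weight vectors
## where the kernel is linear, expansion coefficients otherwise) and solved
## with pracma::quadprog, a different solver and assembly than the package's
## training path.

## brute-force product-limit estimate evaluated just after time t
oracle_km_at <- function(time, status, t) {
  s <- 1
  for (u in sort(unique(time[status == 1]))) {
    if (u > t) break
    d <- sum(time == u & status == 1)
    n_at_risk <- sum(time >= u)
    s <- s * (1 - d / n_at_risk)
  }
  s
}

## primal weighted-SVM objective (linear kernel, input space)
oracle_wsvm_obj <- function(X, y, W, C) {
  n <- nrow(X); d <- ncol(X)
  H <- diag(c(rep(1, d), 1e-8, rep(1e-8, n)))
  cv <- c(rep(0, d + 1), C * W)
  A <- cbind(X * y, y, diag(n))
  sol <- pracma::quadprog(H, cv, A = -A, b = rep(-1, n),
                          lb = c(rep(-1e4, d + 1), rep(0, n)))
  sol$fval
}

oracle_psvm_obj <- function(X, y, p, C, Ct, eps) {
  cert <- which(!is.na(y)); unc <- which(is.na(y))
  nS <- length(cert); nU <- length(unc); d <- ncol(X)
  zb <- probability_to_bounds(p[unc], eps)
  H <- diag(c(rep(1, d), rep(1e-8, 1 + nS + 2 * nU)))
  cv <- c(rep(0, d + 1), rep(C, nS), rep(Ct, 2 * nU))
  A1 <- cbind(X[cert, , drop = FALSE] * y[cert], y[cert], diag(nS), matrix(0, nS, 2 * nU))
  A2 <- cbind(X[unc, , drop = FALSE], 1, matrix(0, nU, nS), diag(nU), matrix(0, nU, nU))
  A3 <- cbind(-X[unc, , drop = FALSE], -1, matrix(0, nU, nS), matrix(0, nU, nU), diag(nU))
  A <- rbind(A1, A2, A3); b <- c(rep(1, nS), zb$z_minus, -zb$z_plus)
  sol <- pracma::quadprog(H, cv, A = -A, b = -b,
                          lb = c(rep(-1e4, d + 1), rep(0, nS + 2 * nU)))
  sol$fval
}

oracle_lupi_obj <- function(X, Xs, y, C, gam) {
  n <- nrow(X); d <- ncol(X); k <- ncol(Xs)
  H <- diag(c(rep(1, d), 1e-8, rep(gam, k), 1e-8))
  cv <- c(rep(0, d), 0, C * colSums(Xs), C * n)
  A1 <- cbind(X * y, y, Xs, 1)
  A2 <- cbind(matrix(0, n, d + 1), Xs, 1)
  sol <- pracma::quadprog(H, cv, A = -rbind(A1, A2), b = -c(rep(1, n), rep(0, n)),
                          lb = rep(-1e4, d + k + 2), ub = rep(1e4, d + k + 2))
  sol$fval
}

oracle_insvm_obj <- function(gram, y, eps, C_lab = 1, C_inv = 1) {
  l <- length(y); m <- ncol(gram$K_fz)
  nv <- 2 * l + 3 * m + 1
  H <- diag(1e-8, nv)
  H[1:(l + m), 1:(l + m)] <- gram$full + diag(1e-8, l + m)
  cv <- c(rep(0, l + m + 1), rep(C_lab, l), rep(C_inv, 2 * m))
  Ff <- cbind(gram$K_ff, gram$K_fz)
  A1 <- cbind(y * Ff, y, diag(l), matrix(0, l, 2 * m))
  if (m > 0) {
    Z <- cbind(t(gram$K_fz), gram$K_zz)
    A2 <- cbind(Z, 1, matrix(0, m, l), diag(m), matrix(0, m, m))
    A3 <- cbind(-Z, -1, matrix(0, m, l), matrix(0, m, m), diag(m))
    A <- rbind(A1, A2, A3); b <- c(rep(1, l), rep(-eps, 2 * m))
  } else {
    A <- A1; b <- rep(1, l)
  }
  sol <- pracma::quadprog((H + t(H)) / 2, cv, A = -A, b = -b,
                          lb = c(rep(-1e4, l + m + 1), rep(0, l + 2 * m)))
  sol$fval
}

## primal objectives of fitted models, evaluated from decisions + slacks
fitted_wsvm_obj <- function(m, X, y, W, C) {
  K <- kernel_matrix(m$anchors, m$anchors, m$kernel)
  xi <- pmax(0, 1 - y * decision(m, X))
  0.5 * sum(m$coef * (K %*% m$coef)) + C * sum(W * xi)
}

fitted_psvm_obj <- function(m, X, y, p, C, Ct, eps) {
  K <- kernel_matrix(m$anchors, m$anchors, m$kernel)
  f <- decision(m, X)
  cert <- !is.na(y); unc <- is.na(y)
  zb <- probability_to_bounds(p[unc], eps)
  0.5 * sum(m$coef * (K %*% m$coef)) +
    C * sum(pmax(0, 1 - y[cert] * f[cert])) +
    Ct * sum(pmax(0, zb$z_minus - f[unc])) +
    Ct * sum(pmax(0, f[unc] - zb$z_plus))
}

fitted_lupi_obj <- function(m, C) {
  K <- kernel_matrix(m$anchors, m$anchors, m$kernel)
  Ks <- kernel_matrix(m$x_star, m$x_star, m$correcting_kernel)
  corr <- as.numeric(Ks %*% m$a_star) + m$b_star
  0.5 * sum(m$coef * (K %*% m$coef)) +
    m$gamma_lupi / 2 * sum(m$a_star * (Ks %*% m$a_star)) + C * sum(corr)
}

fitted_insvm_obj <- function(m, gram, y, eps, C_lab = 1, C_inv = 1) {
  cc_all <- c(m$coef, m$coef_z)
  g_lab <- as.numeric(cbind(gram$K_ff, gram$K_fz) %*% cc_all) + m$b
  0.5 * sum(cc_all * (gram$full %*% cc_all)) +
    C_lab * sum(pmax(0, 1 - y * g_lab)) +
    (if (ncol(gram$K_fz) > 0) {
      g_rep <- as.numeric(cbind(t(gram$K_fz), gram$K_zz) %*% cc_all) + m$b
      C_inv * (sum(pmax(0, -eps - g_rep)) + sum(pmax(0, g_rep - eps)))
    } else 0)
}

## metrics from a hand-filled 2x2 confusion matrix
oracle_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pa <- c(tp + fn, fp + tn) / n       # truth margins (+1, -1)
  pb <- c(tp + fp, fn + tn) / n       # prediction margins
  joint <- c(tp, fn, fp, tn) / n
  ## MI over the 2x2 joint
  mi <- 0
  probs <- matrix(c(tp, fn, fp, tn) / n, 2, 2, byrow = TRUE)
  for (i in 1:2) for (j in 1:2) {
    pj <- probs[i, j]
    if (pj > 0) mi <- mi + pj * log(pj / (pa[i] * pb[j]))
  }
  list(accuracy = (tp + tn) / n,
       matthews = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       nmi = if ((h(pa) + h(pb)) == 0) NA_real_ else max(0, min(1, mi / ((h(pa) + h(pb)) / 2))),
       sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
}

## two well-separated gaussian blobs with labels
make_blobs <- function(n_per, d = 2, sep = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, -sep / 2), n_per, d),
             matrix(rnorm(n_per * d, sep / 2), n_per, d))
  list(x = X, y = rep(c(-1, 1), each = n_per))
}

## calibrated scenario shared by protocol-level tests (rate fixed once from
## the calibration routine under the default coefficients)
calibrated_config <- function(n = 300, censor_frac = 0.10, frailty = NULL, seed = 7) {
  sim_config(n = n, censor_frac = censor_frac, frailty = frailty,
             gompertz = list(alpha = 0.1, gamma = 0.003278121), seed = seed)
}
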