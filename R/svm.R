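#' Training configuration for the survival SVM trainers
#'
#' @param C Soft-margin cost on labeled/certain observations (> 0).
#' @param C_tilde Cost on the epsilon-tube constraints of uncertain
#'   observations (probabilistic SVM); defaults to `C`.
#' @param gamma_lupi Trade-off on the correcting-space norm in the LUPI
#'   trainer (>= 0); as it tends to 0 the privileged information is rejected
#'   and the fit approaches a standard SVM.
#' @param epsilon Half-width of the insensitive tube (probabilistic and
#'   invariance constraints), >= 0.
#' @param kernel Decision-space [kernel_config()].
#' @param correcting_kernel Correcting-space kernel (LUPI), on the privileged
#'   vectors.
#' @param invariance An [invariance_config()] for the local-invariance SVM.
#' @param C_lab,C_inv Costs on the hinge and invariance slack sums of the
#'   local-invariance trainer (both default 1, the unweighted form).
#' @return Object of class `train_config`.
#' @export
train_config <- function(C = 1, C_tilde = C, gamma_lupi = 1, epsilon = 0.1,
                         kernel = kernel_config("linear"),
                         correcting_kernel = kernel_config("linear"),
                         invariance = NULL, C_lab = 1, C_inv = 1) {
  if (C <= 0 || C_tilde <= 0) stop("C and C_tilde must be positive")
  if (gamma_lupi < 0) stop("gamma_lupi must be non-negative")
  if (epsilon < 0) stop("epsilon must be non-negative")
  structure(list(C = C, C_tilde = C_tilde, gamma_lupi = gamma_lupi,
                 epsilon = epsilon, kernel = kernel,
                 correcting_kernel = correcting_kernel,
                 invariance = invariance, C_lab = C_lab, C_inv = C_inv),
            class = "train_config")
}

.check_two_classes <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
}

.new_model <- function(method, anchors, coef, b, kernel, ...) {
  structure(c(list(method = method, anchors = as.matrix(anchors),
                   coef = as.numeric(coef), b = as.numeric(b),
                   kernel = kernel), list(...)),
            class = c(paste0(method, "_model"), "censvm_model"))
}

#' @export
print.censvm_model <- function(x, ...) {
  nsv <- sum(abs(x$coef) > 1e-8)
  cat(sprintf("censvm_model (%s): %d anchors (%d active), kernel %s, b = %.4f\n",
              x$method, nrow(x$anchors), nsv, x$kernel$kind, x$b))
  invisible(x)
}

## Exact bias: given the optimal expansion (decision values g sans bias), the
## primal objective is convex piecewise-linear in b, f(b) = sum w_i max(0,
## s_i (b - k_i)); its minimum is attained at a kink. Ties broken toward the
## midpoint of the optimal flat segment for stability.
.optimal_bias <- function(k, s, w) {
  keep <- w > 0
  k <- k[keep]; s <- s[keep]; w <- w[keep]
  if (!length(k)) return(0)
  f <- function(b) sum(w * pmax(0, s * (b - k)))
  vals <- vapply(k, f, numeric(1))
  opt <- k[vals <= min(vals) + 1e-12]
  mean(range(opt))
}

#' Train a weighted soft-margin SVM
#'
#' Solves the per-sample weighted C-SVM: each observation carries a weight
#' `W_i` in \[0, 1\] scaling its slack cost, so the dual box constraints are
#' `0 <= alpha_i <= C * W_i`. Weight-1 observations behave as in a standard
#' C-SVM; weight-0 observations are inert. In the survival setting the weights
#' come from the conditional-survival or proportional follow-up rule (see
#' [assemble_training_sets()]).
#'
#' @param x Covariate matrix.
#' @param y Labels +1 / -1 (both classes required).
#' @param W Weights in \[0, 1\].
#' @param cfg A [train_config()].
#' @return A `censvm_model`.
#' @export
train_wsvm <- function(x, y, W, cfg = train_config()) {
  x <- as.matrix(x)
  .check_two_classes(y)
  if (any(W < 0 | W > 1)) stop("weights must lie in [0, 1]")
  n <- nrow(x)
  K <- kernel_matrix(x, x, cfg$kernel)
  Q <- (y %o% y) * K + diag(1e-8, n)
  ub <- cfg$C * W
  sol <- solve_qp(H = Q, c = rep(-1, n),
                  Aeq = matrix(y, 1), beq = 0,
                  lb = rep(0, n), ub = ub)
  alpha <- pmin(pmax(sol$x, 0), ub)
  coef <- alpha * y
  g <- as.numeric(K %*% coef)
  b <- .optimal_bias(k = y - g, s = -y, w = cfg$C * W)
  .new_model("wsvm", x, coef, b, cfg$kernel, alpha = alpha, C = cfg$C, W = W)
}

#' Map a class-1 probability to decision-value bounds
#'
#' Uncertain observations enter the probabilistic SVM through a two-sided
#' constraint `z_minus <= f(x) <= z_plus` on the decision value. The package
#' maps a probability `p` to the margin-scale target `m = 2p - 1` (so p = 0,
#' 0.5, 1 map to -1, 0, +1) and returns the symmetric tube `(m - epsilon,
#' m + epsilon)`.
#'
#' @param p Probability of class +1, in \[0, 1\] (vectorized).
#' @param epsilon Tube half-width, >= 0.
#' @return List with `z_minus` and `z_plus`.
#' @export
probability_to_bounds <- function(p, epsilon) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (epsilon < 0) stop("epsilon must be non-negative")
  m <- 2 * p - 1
  list(z_minus = m - epsilon, z_plus = m + epsilon)
}

#' Train a probabilistic (uncertainty) SVM
#'
#' Certain observations (labels +1/-1) enter hinge constraints with cost `C`;
#' uncertain observations enter two-sided epsilon-insensitive constraints with
#' cost `C_tilde` around the decision-value target derived from their class
#' probability (see [probability_to_bounds()]). Solved in the dual so linear
#' and Gaussian kernels share one path. With no uncertain observations the
#' problem collapses to a standard C-SVM.
#'
#' @param x Covariate matrix (certain rows first is not required).
#' @param y Labels +1 / -1 for certain rows, `NA` for uncertain rows.
#' @param p Class-+1 probability for uncertain rows (`NA` elsewhere).
#' @param cfg A [train_config()] (`C`, `C_tilde`, `epsilon`, `kernel`).
#' @return A `censvm_model`.
#' @export
train_psvm <- function(x, y, p = NULL, cfg = train_config()) {
  x <- as.matrix(x)
  cert <- which(!is.na(y))
  unc <- which(is.na(y))
  .check_two_classes(y[cert])
  if (length(unc) > 0 && (is.null(p) || any(is.na(p[unc]))))
    stop("p required for uncertain rows")
  nS <- length(cert); nU <- length(unc)
  zb <- if (nU) probability_to_bounds(p[unc], cfg$epsilon) else list(z_minus = numeric(0), z_plus = numeric(0))
  idx <- c(cert, unc, unc)
  sgn <- c(y[cert], rep(1, nU), rep(-1, nU))
  K <- kernel_matrix(x, x, cfg$kernel)
  Q <- (sgn %o% sgn) * K[idx, idx] + diag(1e-8, nS + 2 * nU)
  dlin <- c(rep(1, nS), zb$z_minus, -zb$z_plus)
  ub <- c(rep(cfg$C, nS), rep(cfg$C_tilde, 2 * nU))
  sol <- solve_qp(H = Q, c = -dlin,
                  Aeq = matrix(sgn, 1), beq = 0,
                  lb = rep(0, length(sgn)), ub = ub)
  v <- pmin(pmax(sol$x, 0), ub)
  coef <- v * sgn
  g_all <- as.numeric(K[, idx] %*% coef)          # decision values sans bias
  gc_ <- g_all[cert]; gu <- g_all[unc]
  b <- .optimal_bias(k = c(y[cert] - gc_, zb$z_minus - gu, zb$z_plus - gu),
                     s = c(-y[cert], rep(-1, nU), rep(1, nU)),
                     w = c(rep(cfg$C, nS), rep(cfg$C_tilde, 2 * nU)))
  .new_model("psvm", x[idx, , drop = FALSE], coef, b, cfg$kernel,
             C = cfg$C, C_tilde = cfg$C_tilde, epsilon = cfg$epsilon)
}

#' Train an SVM with privileged information (LUPI)
#'
#' The slack of each training observation is modeled as the output of a
#' correcting function fit in a second feature space on privileged vectors
#' `x_star` (available only at training time), constrained non-negative, with
#' `gamma_lupi` weighting the correcting-space norm. Posed directly as a
#' convex QP over the kernel expansions of both spaces (representer theorem).
#' In the survival setting the privileged vector encodes the censoring
#' information (follow-up time and weight, or the conditional survival
#' probability).
#'
#' @param x Decision-space covariates.
#' @param x_star Privileged matrix (one row per observation).
#' @param y Labels +1 / -1.
#' @param cfg A [train_config()] (`C`, `gamma_lupi`, `kernel`,
#'   `correcting_kernel`).
#' @return A `censvm_model` (decision space only; usable without `x_star`).
#' @export
train_lupi <- function(x, x_star, y, cfg = train_config()) {
  x <- as.matrix(x); x_star <- as.matrix(x_star)
  .check_two_classes(y)
  n <- nrow(x)
  if (nrow(x_star) != n) stop("x_star required for every training sample")
  gam <- cfg$gamma_lupi
  if (gam <= 0) stop("gamma_lupi must be > 0 (use a small value for the standard-SVM limit)")
  C <- cfg$C
  K <- kernel_matrix(x, x, cfg$kernel)
  Ks <- kernel_matrix(x_star, x_star, cfg$correcting_kernel)
  ## primal over the kernel expansions (representer theorem in both spaces):
  ## vars: a (n), b, a* (n), b*
  ##   min 1/2 a'Ka + gam/2 a*'K*a* + C sum_i ((K*a*)_i + b*)
  ##   s.t. y_i((Ka)_i + b) + (K*a*)_i + b* >= 1;  (K*a*)_i + b* >= 0
  ## The slacks are the correcting-function outputs, so the constraint rows
  ## are inherently rank-deficient; solved with the active-set solver
  ## pracma::quadprog, which handles degenerate constraint sets.
  nv <- 2 * n + 2
  H <- diag(1e-8, nv)
  H[1:n, 1:n] <- K + diag(1e-8, n)
  is <- (n + 2):(2 * n + 1)
  H[is, is] <- gam * Ks + diag(1e-8, n)
  H <- (H + t(H)) / 2
  cvec <- c(rep(0, n + 1), C * colSums(Ks), C * n)
  A1 <- cbind(y * K, y, Ks, 1)
  A2 <- cbind(matrix(0, n, n + 1), Ks, 1)
  sol <- pracma::quadprog(H, cvec, A = -rbind(A1, A2),
                          b = -c(rep(1, n), rep(0, n)))
  a <- sol$xmin[1:n]; b <- sol$xmin[n + 1]
  a_star <- sol$xmin[is]; b_star <- sol$xmin[nv]
  .new_model("lupi", x, a, b, cfg$kernel,
             a_star = a_star, b_star = b_star,
             correcting_kernel = cfg$correcting_kernel, x_star = x_star,
             gamma_lupi = gam, C = C, obj = sol$fval)
}

## cross products between feature maps of X and the representer columns
## attached to anchor_x (gradient: d columns per anchor; averaging: one).
.repr_cross <- function(X, anchor_x, icfg) {
  X <- as.matrix(X); anchor_x <- as.matrix(anchor_x)
  m <- nrow(anchor_x); d <- ncol(X); s <- icfg$sigma_k
  kcfg <- kernel_config("gaussian", sigma = s)
  Kxa <- kernel_matrix(X, anchor_x, kcfg)
  if (icfg$kind == "gradient") {
    out <- matrix(0, nrow(X), m * d)
    for (a in seq_len(m)) {
      diffs <- sweep(X, 2, anchor_x[a, ])
      out[, (a - 1) * d + seq_len(d)] <- diffs / s^2 * Kxa[, a]
    }
    out
  } else {
    d2 <- .dist2(X, anchor_x)
    .avg_smooth_term(d2, d, s, icfg$sigma_p) - Kxa
  }
}

#' Train a semi-supervised SVM with local invariances
#'
#' Hinge constraints on the labeled observations are combined with two-sided
#' epsilon-insensitive constraints on invariance representers (gradient or
#' local-averaging functionals of the Gaussian kernel) attached to anchor
#' points, so the decision function is encouraged to be locally flat / locally
#' averaged around both labeled and unlabeled data. The decision function is
#' sought in the span of the labeled feature maps and the representers, making
#' the problem a finite convex QP over the block Gram matrix of
#' [build_gram()]. In the survival setting the unlabeled points are the
#' censored observations.
#'
#' @param labeled_x,labeled_y Labeled observations (+1 / -1, both classes).
#' @param unlabeled_x Matrix of unlabeled observations (may have zero rows).
#' @param cfg A [train_config()] whose `invariance` is an
#'   [invariance_config()]; `kernel` must be gaussian.
#' @param anchors `"all"` (labeled + unlabeled, the default) or `"unlabeled"`.
#' @param anchor_subsample Optional cap on the number of anchors (seeded
#'   subsample) to bound the QP size.
#' @param seed Seed for anchor subsampling.
#' @return A `censvm_model` carrying both kernel-expansion and representer
#'   coefficients.
#' @export
train_insvm <- function(labeled_x, labeled_y, unlabeled_x = NULL,
                        cfg = train_config(kernel = kernel_config("gaussian")),
                        anchors = c("all", "unlabeled"),
                        anchor_subsample = NULL, seed = 1L) {
  labeled_x <- as.matrix(labeled_x)
  if (nrow(labeled_x) == 0L) stop("empty labeled set")
  .check_two_classes(labeled_y)
  if (cfg$kernel$kind != "gaussian")
    stop("invariance SVM requires the gaussian kernel")
  anchors <- match.arg(anchors)
  icfg <- cfg$invariance
  if (is.null(unlabeled_x)) unlabeled_x <- matrix(0, 0, ncol(labeled_x))
  unlabeled_x <- as.matrix(unlabeled_x)
  anchor_x <- if (anchors == "all") rbind(labeled_x, unlabeled_x) else unlabeled_x
  if (is.null(icfg)) anchor_x <- anchor_x[0, , drop = FALSE]
  if (!is.null(anchor_subsample) && nrow(anchor_x) > anchor_subsample) {
    old <- .Random.seed_save()
    set.seed(seed)
    anchor_x <- anchor_x[sample.int(nrow(anchor_x), anchor_subsample), , drop = FALSE]
    .Random.seed_restore(old)
  }
  gram <- build_gram(labeled_x, anchor_x, cfg$kernel, icfg)
  l <- nrow(labeled_x)
  mrep <- ncol(gram$K_fz)
  ## dual: g = sum lambda_i y_i phi(x_i) + sum (mu_lo - mu_hi) z_m, with
  ## natural boxes lambda in [0, C_lab], mu in [0, C_inv] and one equality.
  ## variables v = (lambda, mu_lo, mu_hi); expansion coefs c = M v
  nd <- l + 2 * mrep
  M <- matrix(0, l + mrep, nd)
  M[cbind(seq_len(l), seq_len(l))] <- labeled_y
  if (mrep > 0) {
    M[cbind(l + seq_len(mrep), l + seq_len(mrep))] <- 1
    M[cbind(l + seq_len(mrep), l + mrep + seq_len(mrep))] <- -1
  }
  Q <- crossprod(M, gram$full %*% M)
  Q <- (Q + t(Q)) / 2 + diag(1e-8, nd)
  dlin <- c(rep(1, l), rep(-cfg$epsilon, 2 * mrep))
  sgn <- c(labeled_y, rep(1, mrep), rep(-1, mrep))
  ubox <- c(rep(cfg$C_lab, l), rep(cfg$C_inv, 2 * mrep))
  sol <- solve_qp(H = Q, c = -dlin, Aeq = matrix(sgn, 1), beq = 0,
                  lb = rep(0, nd), ub = ubox)
  v <- pmin(pmax(sol$x, 0), ubox)
  cc_all <- as.numeric(M %*% v)
  a <- cc_all[seq_len(l)]
  cc <- if (mrep) cc_all[l + seq_len(mrep)] else numeric(0)
  g_lab <- as.numeric(cbind(gram$K_ff, gram$K_fz) %*% cc_all)
  g_rep <- if (mrep) as.numeric(cbind(t(gram$K_fz), gram$K_zz) %*% cc_all) else numeric(0)
  b <- .optimal_bias(k = c(labeled_y - g_lab, -cfg$epsilon - g_rep, cfg$epsilon - g_rep),
                     s = c(-labeled_y, rep(-1, mrep), rep(1, mrep)),
                     w = c(rep(cfg$C_lab, l), rep(cfg$C_inv, 2 * mrep)))
  .new_model("insvm", labeled_x, a, b, cfg$kernel,
             coef_z = cc, icfg = icfg, anchor_x = gram$anchor_x,
             index_map = gram$index_map,
             obj_dual = sum(dlin * v) - as.numeric(0.5 * crossprod(v, Q %*% v)),
             epsilon = cfg$epsilon, C_lab = cfg$C_lab, C_inv = cfg$C_inv)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Decision value of a trained SVM
#'
#' Evaluates the kernel expansion (plus, for the local-invariance SVM, the
#' representer expansion) and adds the bias.
#'
#' @param model A `censvm_model`.
#' @param x A covariate vector or matrix (rows = observations).
#' @return Numeric decision value(s).
#' @export
decision <- function(model, x) {
  stopifnot(inherits(model, "censvm_model"))
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != ncol(model$anchors)) stop("covariate dimension mismatch")
  f <- as.numeric(kernel_matrix(x, model$anchors, model$kernel) %*% model$coef)
  if (model$method == "insvm" && length(model$coef_z) > 0) {
    f <- f + as.numeric(.repr_cross(x, model$anchor_x, model$icfg) %*% model$coef_z)
  }
  f + model$b
}

#' Classify with a trained SVM
#'
#' Sign of the decision value; exact zeros are assigned to class +1.
#'
#' @inheritParams decision
#' @return Vector of +1 / -1.
#' @export
classify <- function(model, x) {
  ifelse(decision(model, x) >= 0, 1, -1)
}

#' @export
predict.censvm_model <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  if (type == "decision") decision(object, newdata) else classify(object, newdata)
}

#' Build method-specific training samples from a censored dataset
#'
#' Applies the censoring-weighting rules to turn a survival dataset into the
#' inputs of one of the four SVM trainers. Events and completed-follow-up
#' nonevents always carry their binarized label (+1 / -1) at full weight.
#' Censored observations are handled per scheme:
#'
#' * `wsvm`, scheme `km`: most-probable class with weight equal to that
#'   probability -- label -1 with `W = S_z(t_i)` when the conditional survival
#'   `S_z >= 0.5`, else label +1 with `W = 1 - S_z`. Scheme `prop`: label -1
#'   with `W = T_i / tau`.
#' * `psvm`: censored observations are uncertain with event probability
#'   `p = 1 - S_z(t_i)` (`km`) or `p = 1 - T_i / tau` (`prop`).
#' * `lupi`: censored observations keep label -1 (event-free as observed) and
#'   carry privileged information: `x_star = S_z(t_i)` (`km`, scalar; events 0,
#'   nonevents 1) or `x_star = (T_i, W_i)` with `W_i = T_i / tau` (`prop`;
#'   events carry `W = 0`, nonevents `W = 1`).
#' * `insvm`: labeled = events + nonevents, unlabeled = censored.
#'
#' @param data A [survival_dataset].
#' @param method One of `"wsvm"`, `"psvm"`, `"lupi"`, `"insvm"`.
#' @param scheme `"km"` (conditional survival) or `"prop"` (proportional
#'   follow-up).
#' @param curve Optional pre-fit `km_curve` (e.g. fit on a training fold
#'   only); defaults to `km_fit(data)`.
#' @param z Look-ahead horizon for the conditional weight; default
#'   `tau - t_i` per censored observation.
#' @return A list of trainer inputs, class `censvm_samples`.
#' @export
assemble_training_sets <- function(data, method = c("wsvm", "psvm", "lupi", "insvm"),
                                   scheme = c("km", "prop"), curve = NULL, z = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  bz <- binarize(data)
  n <- length(data$time)
  tau <- data$tau
  cs <- bz$censored
  t_c <- data$time[cs]
  if (scheme == "km") {
    if (is.null(curve)) curve <- km_fit(data)
    zlook <- if (is.null(z)) tau - t_c else rep(z, length.out = length(cs))
    S_z <- vapply(seq_along(cs), function(i)
      conditional_weight(curve, t_c[i], zlook[i])$value, numeric(1))
  } else {
    S_z <- NULL
  }
  y <- bz$y
  out <- switch(method,
    wsvm = {
      W <- rep(1, n)
      if (length(cs)) {
        if (scheme == "km") {
          lab <- ifelse(S_z >= 0.5, -1, 1)
          W[cs] <- ifelse(S_z >= 0.5, S_z, 1 - S_z)
          y[cs] <- lab
        } else {
          y[cs] <- -1
          W[cs] <- t_c / tau
        }
      }
      list(x = data$x, y = y, W = W)
    },
    psvm = {
      p <- rep(NA_real_, n)
      if (length(cs)) {
        p[cs] <- if (scheme == "km") 1 - S_z else 1 - t_c / tau
        y[cs] <- NA
      }
      list(x = data$x, y = y, p = p)
    },
    lupi = {
      y[cs] <- -1
      if (scheme == "km") {
        xs <- rep(1, n)               # nonevents: certain survival through tau
        xs[bz$events] <- 0            # events: fixed to 0
        if (length(cs)) xs[cs] <- S_z
        x_star <- matrix(xs, ncol = 1)
      } else {
        W <- rep(1, n)
        W[bz$events] <- 0
        if (length(cs)) W[cs] <- t_c / tau
        x_star <- unname(cbind(pmin(data$time, tau), W))
      }
      list(x = data$x, x_star = x_star, y = y)
    },
    insvm = {
      lab <- c(bz$events, bz$nonevents)
      list(x_l = data$x[lab, , drop = FALSE], y_l = y[lab],
           x_u = data$x[cs, , drop = FALSE])
    })
  structure(c(out, list(method = method, scheme = scheme)),
            class = "censvm_samples")
}
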