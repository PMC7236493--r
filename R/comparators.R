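#' Fit a Cox proportional hazards model
#'
#' Maximum partial likelihood fit (Breslow tie handling) via
#' [survival::coxph()], with the Breslow baseline cumulative hazard attached
#' so the model can predict survival at the administrative horizon. If the
#' fit fails to produce finite coefficients (monotone likelihood /
#' separation, common when n is close to d), a small ridge penalty (1e-6) is
#' added and the refit recorded in the returned object.
#'
#' @param data A [survival_dataset] with at least one event.
#' @return Object of class `cox_model`: `beta`, `baseline` (step data.frame
#'   `time`, `cumhaz`), `converged`, `ridge_used`.
#' @export
cox_fit <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$status) < 1) stop("at least one event required")
  X <- data$x
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(time = data$time, status = data$status, X)
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(colnames(X), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = df, ties = "breslow",
                                     control = survival::coxph.control(iter.max = 50))),
    error = function(e) NULL)
  ridge_used <- FALSE
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
    ## monotone likelihood / separation: retry under a ridge penalty,
    ## escalating until the fit stabilizes
    for (theta in c(1e-6, 1e-2, 1)) {
      rfml <- stats::as.formula(paste("survival::Surv(time, status) ~ ridge(",
                                      paste(colnames(X), collapse = ", "),
                                      ", theta =", theta, ")"))
      fit <- tryCatch(suppressWarnings(survival::coxph(rfml, data = df, ties = "breslow")),
                      error = function(e) NULL)
      ridge_used <- TRUE
      if (!is.null(fit) && all(is.finite(stats::coef(fit)))) break
    }
    if (is.null(fit) || any(!is.finite(stats::coef(fit))))
      stop("Cox fit failed to converge (non-finite coefficients after ridge fallback)")
  }
  beta <- as.numeric(stats::coef(fit))
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(beta = beta, baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 converged = TRUE, ridge_used = ridge_used),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model: %d coefficients%s\n", length(x$beta),
              if (x$ridge_used) " (ridge fallback)" else ""))
  invisible(x)
}

.cumhaz_at <- function(baseline, t) {
  idx <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[idx + 1L]
}

#' Predicted survival, risk score and class from a Cox-type model
#'
#' Predicts event-by-tau (+1) when the estimated survival
#' `S(tau | x) = exp(-Lambda0(tau) exp(lp))` is at most 0.5 (ties at exactly
#' 0.5 go to +1); the continuous risk score used for ROC analysis is
#' `-S(tau | x)`. `tau` beyond the observed range uses the last baseline
#' value.
#'
#' @param model A `cox_model` or `kernel_cox_model`.
#' @param x Covariate vector or matrix.
#' @param tau Administrative horizon.
#' @return For `cox_classify`: vector of +1 / -1. For `cox_score`: `-S(tau|x)`.
#' @export
cox_classify <- function(model, x, tau) {
  s <- -cox_score(model, x, tau)
  ifelse(s <= 0.5, 1, -1)
}

#' @rdname cox_classify
#' @export
cox_score <- function(model, x, tau) {
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  lp <- if (inherits(model, "kernel_cox_model")) {
    as.numeric(kernel_matrix(x, model$anchors, model$kernel) %*% model$alpha)
  } else {
    as.numeric(x %*% model$beta)
  }
  H0 <- .cumhaz_at(model$baseline, tau)
  -exp(-H0 * exp(lp))
}

## negative log partial likelihood (Breslow) and gradient in f.
## Each event observation i contributes -(f_i - log sum_{T_j >= T_i} e^{f_j}).
## Times sorted in decreasing order so the risk-set sum is a cumulative sum;
## tied times share the risk set of the whole tied block (ave over blocks).
.neg_logpl <- function(f, time, status) {
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]
  cs <- cumsum(exp(f[ord]))
  S <- stats::ave(cs, tt, FUN = max)              # sum over {T_j >= T_i}
  ev <- status[ord] == 1
  -sum(f[ord][ev] - log(S[ev]))
}

.neg_logpl_grad <- function(f, time, status) {
  n <- length(f)
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]
  ef <- exp(f[ord])
  S <- stats::ave(cumsum(ef), tt, FUN = max)
  ev <- status[ord] == 1
  ## mu_i = e^{f_i} * sum over events k with T_k <= T_i of 1 / S_k
  acc <- rev(cumsum(rev(ifelse(ev, 1 / S, 0))))
  acc <- stats::ave(acc, tt, FUN = max)           # ties share the full block
  mu <- ef * acc
  g <- numeric(n)
  g[ord] <- mu - as.numeric(ev)
  g
}

#' Fit a kernel Cox regression
#'
#' Minimizes the penalized negative log partial likelihood
#' `-logPL(f) + xi_reg * ||f||_H^2` over `f = sum alpha_i k(., x_i)` (the
#' representer-theorem form; the intercept is not identifiable inside a
#' partial likelihood and is absorbed into the baseline), by BFGS with an
#' analytic gradient from a zero start. Breslow tie handling throughout;
#' the Breslow baseline of the fitted `f` is attached for classification.
#'
#' @param data A [survival_dataset].
#' @param kcfg A [kernel_config()].
#' @param xi_reg Positive regularization weight on the squared RKHS norm.
#' @return Object of class `kernel_cox_model`: `alpha`, `anchors`, `kernel`,
#'   `baseline`, `xi_reg`, `opt` (optimizer diagnostics).
#' @export
kernel_cox_fit <- function(data, kcfg, xi_reg) {
  stopifnot(inherits(data, "survival_dataset"))
  if (xi_reg <= 0) stop("xi_reg must be positive")
  K <- kernel_matrix(data$x, data$x, kcfg)
  time <- data$time; status <- data$status
  obj <- function(alpha) {
    f <- as.numeric(K %*% alpha)
    v <- .neg_logpl(f, time, status) + xi_reg * sum(alpha * f)
    ## line searches can overshoot into exp() overflow: return a large finite
    ## value so the optimizer backtracks
    if (!is.finite(v)) v <- 1e10
    v
  }
  if (!is.finite(obj(rep(0, nrow(K))))) stop("non-finite kernel Cox objective at start")
  grad <- function(alpha) {
    f <- as.numeric(K %*% alpha)
    as.numeric(K %*% (.neg_logpl_grad(f, time, status) + 2 * xi_reg * alpha))
  }
  opt <- stats::optim(rep(0, nrow(K)), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  alpha <- opt$par
  f <- as.numeric(K %*% alpha)
  ## Breslow baseline under the fitted f
  ot <- order(time)
  bl_t <- unique(time[ot][status[ot] == 1])
  cumhaz <- vapply(bl_t, function(tk) {
    sum(time == tk & status == 1) / sum(exp(f[time >= tk]))
  }, numeric(1))
  baseline <- data.frame(time = bl_t, cumhaz = cumsum(cumhaz))
  structure(list(alpha = alpha, anchors = data$x, kernel = kcfg,
                 baseline = baseline, xi_reg = xi_reg,
                 opt = list(value = opt$value, convergence = opt$convergence,
                            grad_norm = sqrt(sum(grad(alpha)^2)))),
            class = "kernel_cox_model")
}

#' @export
print.kernel_cox_model <- function(x, ...) {
  cat(sprintf("kernel_cox_model: %d dual coefficients, kernel %s, xi = %g\n",
              length(x$alpha), x$kernel$kind, x$xi_reg))
  invisible(x)
}

#' @rdname cox_classify
#' @export
kernel_cox_classify <- function(model, x, tau) cox_classify(model, x, tau)

#' @rdname cox_classify
#' @export
kernel_cox_score <- function(model, x, tau) cox_score(model, x, tau)
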