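#' Kernel configuration
#'
#' @param kind `"linear"` or `"gaussian"`.
#' @param sigma Gaussian width sigma (> 0); ignored for the linear kernel.
#' @return Object of class `kernel_config`.
#' @export
kernel_config <- function(kind = c("linear", "gaussian"), sigma = 1) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && (!is.numeric(sigma) || sigma <= 0))
    stop("sigma must be positive for the gaussian kernel")
  structure(list(kind = kind, sigma = sigma), class = "kernel_config")
}

#' Local-invariance configuration
#'
#' Describes which invariance functional is imposed at the anchor points of a
#' semi-supervised SVM: `"gradient"` restricts the partial derivatives of the
#' decision function to be small at the anchors; `"averaging"` restricts the
#' function value to be close to its Gaussian-weighted local average.
#'
#' @param kind `"gradient"` or `"averaging"`.
#' @param sigma_k Gaussian kernel width (> 0).
#' @param sigma_p Gaussian smoothing-density width (> 0); averaging only.
#' @param d Covariate dimension.
#' @return Object of class `invariance_config`.
#' @export
invariance_config <- function(kind = c("gradient", "averaging"),
                              sigma_k, sigma_p = NULL, d) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma_k) || sigma_k <= 0) stop("sigma_k must be positive")
  if (kind == "averaging") {
    if (is.null(sigma_p) || sigma_p <= 0) stop("sigma_p must be positive for averaging")
  }
  if (missing(d) || d < 1) stop("d (covariate count) required")
  structure(list(kind = kind, sigma_k = sigma_k, sigma_p = sigma_p, d = as.integer(d)),
            class = "invariance_config")
}

#' Evaluate a kernel on a pair of vectors
#'
#' Linear: the dot product. Gaussian: `exp(-||x1 - x2||^2 / (2 sigma^2))`.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param cfg A [kernel_config()].
#' @return Scalar kernel value.
#' @export
kernel_eval <- function(x1, x2, cfg) {
  if (length(x1) != length(x2)) stop("kernel_eval: length mismatch")
  if (cfg$kind == "linear") return(sum(x1 * x2))
  exp(-sum((x1 - x2)^2) / (2 * cfg$sigma^2))
}

#' Kernel matrix between two sets of points
#'
#' @param X1,X2 Matrices with observations in rows (equal column count).
#' @param cfg A [kernel_config()].
#' @return `nrow(X1) x nrow(X2)` kernel matrix.
#' @export
kernel_matrix <- function(X1, X2 = X1, cfg) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (ncol(X1) != ncol(X2)) stop("kernel_matrix: dimension mismatch")
  if (cfg$kind == "linear") return(tcrossprod(X1, X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * cfg$sigma^2))
}

#' Representer of the derivative functional, evaluated at a point
#'
#' For the Gaussian kernel, the RKHS representer of the functional
#' `f -> (d f / d x^j)(x_i)` evaluated at `x` is
#' `(1/sigma^2) (x^j - x_i^j) exp(-||x - x_i||^2 / (2 sigma^2))`.
#' This is also the cross inner product between the representer and the
#' feature map of `x`.
#'
#' @param x Evaluation point.
#' @param x_i Anchor point.
#' @param j Variable index, `1 <= j <= d`.
#' @param sigma Gaussian kernel width.
#' @return Scalar.
#' @export
grad_representer_eval <- function(x, x_i, j, sigma) {
  if (length(x) != length(x_i)) stop("length mismatch")
  if (j < 1 || j > length(x)) stop("j out of range")
  (x[j] - x_i[j]) / sigma^2 * exp(-sum((x - x_i)^2) / (2 * sigma^2))
}

#' Inner product between two derivative representers
#'
#' Closed form for the Gaussian kernel: the mixed second derivative of the
#' kernel with respect to component `j` of the first argument and component
#' `q` of the second, evaluated at `(x_i, x_p)`. Two branches: `j != q` and
#' `j == q`.
#'
#' @param x_i,x_p Anchor points.
#' @param j,q Variable indices.
#' @param sigma Gaussian kernel width.
#' @return Scalar.
#' @export
grad_representer_dot <- function(x_i, j, x_p, q, sigma) {
  if (length(x_i) != length(x_p)) stop("length mismatch")
  d <- length(x_i)
  if (j < 1 || j > d || q < 1 || q > d) stop("index out of range")
  k <- exp(-sum((x_i - x_p)^2) / (2 * sigma^2))
  if (j != q) {
    -(x_i[j] - x_p[j]) * (x_i[q] - x_p[q]) / sigma^4 * k
  } else {
    (sigma^2 - (x_i[j] - x_p[j])^2) / sigma^4 * k
  }
}

.dist2 <- function(X1, X2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  d2
}

## Gaussian-convolution building block: integral of k(x, u) p(x_i - u) du
## for k gaussian with width s_k and p a N(0, s_p^2 I_d) density. Variances
## add under convolution, giving ratio (s_k^2/(s_k^2+s_p^2))^(d/2).
.avg_smooth_term <- function(dist2, d, s_k, s_p, as_printed = FALSE) {
  if (as_printed) {
    ## literal published form: widths added, power d on the ratio
    (s_k^d / (s_k + s_p)^d) * exp(-dist2 / (2 * (s_k + s_p)^2))
  } else {
    (s_k^2 / (s_k^2 + s_p^2))^(d / 2) * exp(-dist2 / (2 * (s_k^2 + s_p^2)))
  }
}

#' Representer of the local-averaging functional, evaluated at a point
#'
#' RKHS representer of `f -> integral f(u) p(x_i - u) du - f(x_i)` for the
#' Gaussian kernel (width `sigma_k`) and a centred Gaussian smoothing density
#' (width `sigma_p`). The default form follows the Gaussian-convolution
#' identity (variances add); `as_printed = TRUE` switches to an alternative
#' width-sum form retained for auditing.
#'
#' @param x Evaluation point.
#' @param x_i Anchor point.
#' @param cfg An [invariance_config()] with `kind = "averaging"`.
#' @param as_printed Use the audit variant of the smoothing term.
#' @return Scalar.
#' @export
avg_representer_eval <- function(x, x_i, cfg, as_printed = FALSE) {
  stopifnot(inherits(cfg, "invariance_config"), cfg$kind == "averaging")
  if (length(x) != length(x_i)) stop("length mismatch")
  dist2 <- sum((x - x_i)^2)
  .avg_smooth_term(dist2, cfg$d, cfg$sigma_k, cfg$sigma_p, as_printed) -
    exp(-dist2 / (2 * cfg$sigma_k^2))
}

#' Inner product between two local-averaging representers
#'
#' Closed form via nested Gaussian convolution:
#' `A - B_ij - B_ji + k(x_i, x_j)` where `A` smooths with total variance
#' `sigma_k^2 + 2 sigma_p^2` and `B` with `sigma_k^2 + sigma_p^2`.
#' Symmetric and positive on the diagonal (a squared RKHS norm).
#'
#' @param x_i,x_j Anchor points.
#' @param cfg An [invariance_config()] with `kind = "averaging"`.
#' @param as_printed Use the audit variant of the smoothing terms.
#' @return Scalar.
#' @export
avg_representer_dot <- function(x_i, x_j, cfg, as_printed = FALSE) {
  stopifnot(inherits(cfg, "invariance_config"), cfg$kind == "averaging")
  if (length(x_i) != length(x_j)) stop("length mismatch")
  d2 <- sum((x_i - x_j)^2)
  s_k <- cfg$sigma_k; s_p <- cfg$sigma_p; d <- cfg$d
  A <- if (as_printed) {
    (s_k^d / (s_k + 2 * s_p)^2) * exp(-d2 / (2 * (s_k + 2 * s_p)^2))
  } else {
    (s_k^2 / (s_k^2 + 2 * s_p^2))^(d / 2) * exp(-d2 / (2 * (s_k^2 + 2 * s_p^2)))
  }
  B <- .avg_smooth_term(d2, d, s_k, s_p, as_printed)
  A - 2 * B + exp(-d2 / (2 * s_k^2))
}

#' Assemble the block Gram matrix for a local-invariance SVM
#'
#' Builds all inner products needed to pose the semi-supervised invariance QP
#' over the span of the labeled feature maps and the invariance representers:
#' `K_ff` (labeled x labeled kernel), `K_fz` (labeled x representer cross
#' products) and `K_zz` (representer x representer). Gradient invariance
#' attaches `d` representers (one per variable) to each anchor; averaging
#' attaches one.
#'
#' @param labeled_x Matrix of labeled observations (rows).
#' @param anchor_x Matrix of anchor points (rows); may have zero rows.
#' @param kcfg A gaussian [kernel_config()] (required when `icfg` is given;
#'   its `sigma` must equal `icfg$sigma_k`).
#' @param icfg An [invariance_config()], or `NULL` for a plain kernel Gram.
#' @param jitter Diagonal jitter added to the full block matrix for solver
#'   stability (representer Grams are near-singular for close anchors).
#' @return Object of class `invariance_gram`: list with `K_ff`, `K_fz`,
#'   `K_zz`, `index_map` (data.frame anchor/variable per representer column),
#'   and `full` (the jittered symmetric block matrix).
#' @export
build_gram <- function(labeled_x, anchor_x, kcfg, icfg = NULL, jitter = 1e-8) {
  labeled_x <- as.matrix(labeled_x)
  n <- nrow(labeled_x)
  if (is.null(icfg) || is.null(anchor_x) || nrow(as.matrix(anchor_x)) == 0L) {
    K_ff <- kernel_matrix(labeled_x, labeled_x, kcfg)
    full <- K_ff + diag(jitter, n)
    return(structure(list(K_ff = K_ff, K_fz = matrix(0, n, 0),
                          K_zz = matrix(0, 0, 0),
                          index_map = data.frame(anchor = integer(0), variable = integer(0)),
                          full = full, kcfg = kcfg, icfg = NULL,
                          anchor_x = matrix(0, 0, ncol(labeled_x))),
                     class = "invariance_gram"))
  }
  if (kcfg$kind != "gaussian")
    stop("invariance representers are derived for the gaussian kernel only")
  anchor_x <- as.matrix(anchor_x)
  m <- nrow(anchor_x)
  d <- ncol(labeled_x)
  if (ncol(anchor_x) != d) stop("anchor and labeled dimension mismatch")
  s <- icfg$sigma_k
  K_ff <- kernel_matrix(labeled_x, labeled_x, kcfg)
  Kfa <- kernel_matrix(labeled_x, anchor_x, kcfg)    # n x m gaussian kernel
  Kaa <- kernel_matrix(anchor_x, anchor_x, kcfg)

  if (icfg$kind == "gradient") {
    ## representer columns ordered anchor-major: (a1,v1..vd), (a2,v1..vd), ...
    index_map <- data.frame(anchor = rep(seq_len(m), each = d),
                            variable = rep(seq_len(d), m))
    K_fz <- matrix(0, n, m * d)
    for (a in seq_len(m)) {
      diffs <- sweep(labeled_x, 2, anchor_x[a, ])      # x^j - x_a^j, n x d
      K_fz[, (a - 1) * d + seq_len(d)] <- diffs / s^2 * Kfa[, a]
    }
    K_zz <- matrix(0, m * d, m * d)
    for (a in seq_len(m)) for (p in a:m) {
      dv <- anchor_x[a, ] - anchor_x[p, ]
      blk <- (-outer(dv, dv) / s^4) * Kaa[a, p]
      diag(blk) <- (s^2 - dv^2) / s^4 * Kaa[a, p]
      K_zz[(a - 1) * d + seq_len(d), (p - 1) * d + seq_len(d)] <- blk
      K_zz[(p - 1) * d + seq_len(d), (a - 1) * d + seq_len(d)] <- t(blk)
    }
  } else {
    index_map <- data.frame(anchor = seq_len(m), variable = NA_integer_)
    d2_fa <- .dist2(labeled_x, anchor_x)
    d2_aa <- .dist2(anchor_x, anchor_x)
    s_p <- icfg$sigma_p
    K_fz <- .avg_smooth_term(d2_fa, d, s, s_p) - Kfa
    A <- (s^2 / (s^2 + 2 * s_p^2))^(d / 2) * exp(-d2_aa / (2 * (s^2 + 2 * s_p^2)))
    B <- .avg_smooth_term(d2_aa, d, s, s_p)
    K_zz <- A - 2 * B + Kaa
  }
  full <- rbind(cbind(K_ff, K_fz), cbind(t(K_fz), K_zz))
  full <- (full + t(full)) / 2 + diag(jitter, nrow(full))
  structure(list(K_ff = K_ff, K_fz = K_fz, K_zz = K_zz,
                 index_map = index_map, full = full,
                 kcfg = kcfg, icfg = icfg, anchor_x = anchor_x),
            class = "invariance_gram")
}

#' @export
print.invariance_gram <- function(x, ...) {
  cat(sprintf("invariance_gram: %d labeled, %d representer columns (%s)\n",
              nrow(x$K_ff), ncol(x$K_fz),
              if (is.null(x$icfg)) "no invariance" else x$icfg$kind))
  invisible(x)
}
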