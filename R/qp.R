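#' Solve a convex quadratic program
#'
#' Minimizes `0.5 x'Hx + c'x` subject to `Aeq x = beq`, `Ain x >= bin` and
#' `lb <= x <= ub`, via the deterministic interior-point solver
#' [kernlab::ipop()]. All four SVM trainers in the package pose their
#' optimization problems through this single surface. `H` must be positive
#' semi-definite; callers add diagonal jitter where needed.
#'
#' Unbounded variables are boxed at `+/- box` internally (interior-point
#' solvers require finite boxes); a warning is raised if the solution presses
#' against that artificial box.
#'
#' @param H Symmetric PSD matrix (n x n).
#' @param c Linear term (length n).
#' @param Aeq,beq Equality constraints (may be `NULL`).
#' @param Ain,bin Inequality constraints `Ain x >= bin` (may be `NULL`).
#' @param lb,ub Variable bounds; `-Inf`/`Inf` allowed.
#' @param box Magnitude substituted for infinite bounds.
#' @param sigf,maxiter Solver precision (significant figures) and iteration cap.
#' @return List with `x` (solution), `obj` (objective value) and `status`.
#' @export
solve_qp <- function(H, c, Aeq = NULL, beq = NULL, Ain = NULL, bin = NULL,
                     lb = NULL, ub = NULL, box = 1e4, sigf = 7, maxiter = 100) {
  n <- length(c)
  stopifnot(nrow(H) == n, ncol(H) == n)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  lb <- pmax(lb, -box); ub <- pmin(ub, box)
  A <- rbind(Aeq, Ain)
  b <- c(beq, bin)
  r <- c(rep(0, if (is.null(Aeq)) 0 else nrow(Aeq)),
         rep(1e6, if (is.null(Ain)) 0 else nrow(Ain)))
  if (is.null(A) || nrow(A) == 0L) {            # ipop needs >= 1 constraint row
    A <- matrix(0, 1, n); b <- -1; r <- 2
  }
  sol <- kernlab::ipop(c = c, H = H, A = A, b = b, l = lb, u = ub, r = r,
                       sigf = sigf, maxiter = maxiter)
  status <- kernlab::how(sol)
  if (status != "converged")
    stop(sprintf("QP solver did not converge (status: %s)", status))
  x <- as.numeric(kernlab::primal(sol))
  if (any(abs(x) > 0.99 * box & (lb <= -0.99 * box | ub >= 0.99 * box)))
    warning("QP solution near the artificial variable box; result may be clipped")
  list(x = x, obj = as.numeric(0.5 * crossprod(x, H %*% x) + sum(c * x)),
       status = status)
}
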