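#' Eigen decomposition of an evolution operator
#'
#' Full (generally complex) eigen decomposition, with eigenvalues sorted by
#' descending real part.  When an initial CLD `n0` is supplied, the expansion
#' coefficients `c_i` solving `n0 = sum_i c_i u_i` are returned as well.
#'
#' @param op an `evolution_operator`.
#' @param n0 optional [cld()] giving the initial condition; its DP support
#'   must lie within `1..op$xmax`.
#' @return A list of class `eigen_solution` with `lambdas`, `vectors`, and
#'   (if `n0` given) `coefficients`.
#' @export
eigensystem <- function(op, n0 = NULL) {
  stopifnot(inherits(op, "evolution_operator"))
  e <- eigen(op$matrix)
  ord <- order(Re(e$values), decreasing = TRUE)
  lambdas <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  out <- list(lambdas = lambdas, vectors = vectors, xmax = op$xmax)
  if (!is.null(n0)) {
    stopifnot(inherits(n0, "cld"))
    if (max(n0$dp) > op$xmax)
      abort_validation("`n0` support exceeds operator xmax")
    v <- numeric(op$xmax)
    v[n0$dp] <- n0$abundance
    # The eigenvector basis is defective on the below-support bins (a pure
    # elongation Jordan chain), so solve in the least-squares sense via the
    # SVD pseudo-inverse and let the residual decide representability.
    s <- svd(vectors)
    keep <- s$d > 1e-13 * s$d[1]
    co <- s$v[, keep, drop = FALSE] %*%
      ((Conj(t(s$u[, keep, drop = FALSE])) %*% v) / s$d[keep])
    co <- as.vector(co)
    resid <- max(Mod(vectors %*% co - v))
    if (resid > 1e-8)
      abort_numerical(sprintf(
        paste("initial CLD is not representable in the eigenvector basis",
              "(residual %.3g); the operator is defective there —",
              "perturb beta or start the CLD on the model support"), resid))
    out$coefficients <- co
  }
  class(out) <- "eigen_solution"
  out
}

#' @export
print.eigen_solution <- function(x, ...) {
  cat(sprintf("<eigen_solution> %d eigenvalues, Re(lambda1) = %.3g, Re(lambda2) = %.3g\n",
              length(x$lambdas), Re(x$lambdas[1]), Re(x$lambdas[2])))
  invisible(x)
}

#' Steady-state CLD of an on-surface system
#'
#' A stable stationary CLD exists only when the operator has exactly one zero
#' eigenvalue with all others negative (the steady-state condition).  This
#' returns the corresponding null eigenvector, sign-fixed to be non-negative
#' and normalized to a maximum of 1.
#'
#' @param system a [kinetic_system()] lying on the steady-state surface.
#' @param tol_zero tolerance on `|Re(lambda1)|` (relative to the unit
#'   propagation rate) for accepting the system as on-surface.
#' @return A [cld()] over DP `1..xmax` with `norm = "max1"`.
#' @seealso [solve_gamma()] to place a system on the surface.
#' @export
steady_state_cld <- function(system, tol_zero = 1e-8) {
  op <- build_evolution_operator(system)
  e <- eigensystem(op)
  l1 <- e$lambdas[1]
  if (abs(Re(l1)) > tol_zero)
    abort_no_steady_state(sprintf(
      "not at steady state: Re(lambda1) = %.6g (|.| > tol_zero = %g)",
      Re(l1), tol_zero))
  u <- e$vectors[, 1]
  if (max(abs(Im(u))) > 1e-8 * max(Mod(u)))
    abort_numerical("null eigenvector has a non-negligible imaginary part")
  u <- Re(u)
  i <- which.max(abs(u))
  if (u[i] < 0) u <- -u
  m <- max(u)
  if (min(u) < -1e-8 * m)
    abort_numerical(sprintf(
      "null eigenvector has mixed signs (min/max = %.3g)", min(u) / m))
  u[abs(u) < 1e-14 * m] <- 0
  u[u < 0] <- 0
  cld(seq_len(op$xmax), u / m, norm = "max1")
}

#' Time evolution of a CLD under a kinetic system
#'
#' Propagates an initial CLD through the eigen expansion
#' `N(t) = sum_i c_i u_i exp(lambda_i t)` of the evolution operator, the
#' formal solution of the linear population balance.  Time is in units of the
#' reciprocal propagation rate.
#'
#' @param system a [kinetic_system()].
#' @param n0 initial [cld()].
#' @param t non-negative time.
#' @return A [cld()] over DP `1..xmax` (`norm = "raw"`).
#' @export
time_evolve <- function(system, n0, t) {
  if (!is_scalar_num(t) || t < 0)
    abort_validation("`t` must be a single non-negative number")
  op <- build_evolution_operator(system)
  e <- eigensystem(op, n0 = n0)
  v <- e$vectors %*% (e$coefficients * exp(e$lambdas * t))
  v <- Re(v)
  v[abs(v) < 1e-300] <- 0
  v[v < 0 & v > -1e-12 * max(abs(v))] <- 0
  if (any(v < 0)) v[v < 0] <- 0  # spectral round-off can graze below zero
  cld(seq_len(op$xmax), as.numeric(v), norm = "raw")
}
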