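#' Leading eigenvalue (spectral abscissa) of a kinetic system
#'
#' The largest real part over all eigenvalues of the evolution operator.  A
#' positive value means the CLD proliferates indefinitely, a negative value
#' that it decays to extinction; the steady-state surface is the locus where
#' it is exactly zero.
#'
#' @param system a [kinetic_system()].
#' @return A single real number.
#' @export
leading_eigenvalue <- function(system) {
  op <- build_evolution_operator(system)
  max(Re(eigen(op$matrix, only.values = TRUE)$values))
}

# Internal: steady-state solve for a set list (gamma on the surface plus the
# null eigenvector), via the fast Hessenberg path or the dense eigen oracle.
# Because debranching is uniform on all DP bins, Omega(gamma) =
# Omega0 - gamma I, so the on-surface gamma equals the spectral abscissa of
# Omega0 and the null eigenvector is its leading eigenvector.
solve_steady_state <- function(sets, xmax = 110L,
                               method = c("hessenberg", "eigen")) {
  method <- match.arg(method)
  if (inherits(sets, "enzyme_set")) sets <- list(sets)
  beta <- sys_beta(sets)
  if (all(beta <= 0))
    abort_no_steady_state(
      "no steady state exists: all beta are zero (debranching cannot balance absent branching)")
  # validate geometry via the system constructor (gamma placeholder 0)
  kinetic_system(sets, gamma = 0, xmax = xmax)
  if (method == "hessenberg") {
    res <- .cpp_solve_ss(sys_x0(sets), sys_xmin(sets), beta, as.integer(xmax))
    if (res$ok) {
      if (!res$clean)
        abort_numerical("steady-state eigenvector has mixed signs; perturb beta")
      return(list(gamma = res$gamma,
                  cld = cld(seq_len(xmax), res$cld, norm = "max1")))
    }
    # bracketing failed (pathological spectrum): fall through to eigen
  }
  sys0 <- kinetic_system(sets, gamma = 0, xmax = xmax)
  op0 <- build_evolution_operator(sys0)
  ev <- eigen(op0$matrix)
  i <- which.max(Re(ev$values))
  g <- Re(ev$values[i])
  if (abs(Im(ev$values[i])) > 1e-10)
    abort_numerical("leading eigenvalue is not real; perturb beta")
  if (g <= 0)
    abort_no_steady_state(sprintf(
      "no steady state exists: leading eigenvalue at gamma = 0 is %.3g", g))
  u <- Re(ev$vectors[, i])
  if (u[which.max(abs(u))] < 0) u <- -u
  m <- max(u)
  u[abs(u) < 1e-14 * m] <- 0
  if (min(u) < -1e-8 * m)
    abort_numerical("steady-state eigenvector has mixed signs; perturb beta")
  u[u < 0] <- 0
  list(gamma = g, cld = cld(seq_len(xmax), u / m, norm = "max1"))
}

#' Solve the steady-state condition for gamma
#'
#' Finds the pooled relative debranching activity `gamma*` at which the
#' evolution operator has exactly one zero eigenvalue with all others
#' negative, i.e. the point on the steady-state surface for the given enzyme
#' sets.  Debranching acts uniformly on all DP bins, so raising `gamma`
#' shifts the whole spectrum down rigidly; `gamma*` is located as the largest
#' real root of the operator's characteristic function (bracketed bisection
#' on a Hessenberg recursion), with a dense eigendecomposition fallback.
#'
#' @param sets a list of [enzyme_set()]s (or a single one); at least one must
#'   have `beta > 0`, otherwise no steady state exists.
#' @param xmax integer truncation DP (default 110).
#' @param method `"hessenberg"` (fast recursion) or `"eigen"` (dense oracle).
#' @return The solved `gamma*` (single number).
#' @examples
#' solve_gamma(list(enzyme_set(0.05, 6, 7), enzyme_set(0.02, 9, 14)))
#' @export
solve_gamma <- function(sets, xmax = 110L,
                        method = c("hessenberg", "eigen")) {
  solve_steady_state(sets, xmax = xmax, method = match.arg(method))$gamma
}

#' Tabulate the steady-state surface gamma(beta1, beta2)
#'
#' Solves `gamma*` on a grid of branching ratios for a fixed pair of SBE
#' constraint quadruples.  The slice at `beta2 = 0` reproduces the single-set
#' steady-state line.
#'
#' @param constraints1,constraints2 [sbe_constraints()] for sets (i) and (ii).
#' @param beta1,beta2 ascending grids of branching ratios.  Defaults span
#'   0.005..0.2 (log-spaced, 25 points), reflecting that fitted branching
#'   ratios are always far below 1.
#' @param xmax truncation DP.
#' @return An object of class `surface_grid`: `beta1`, `beta2`, matrix
#'   `gamma` (rows follow `beta1`), and the constraint integers.  Nodes where
#'   no steady state exists are `NA`.
#' @examples
#' s <- steady_state_surface(sbe_constraints(6, 7), sbe_constraints(9, 14),
#'                           beta1 = c(0.02, 0.05), beta2 = c(0, 0.02))
#' s$gamma
#' @export
steady_state_surface <- function(constraints1, constraints2,
                                 beta1 = exp(seq(log(0.005), log(0.2),
                                                 length.out = 25)),
                                 beta2 = exp(seq(log(0.005), log(0.2),
                                                 length.out = 25)),
                                 xmax = 110L) {
  stopifnot(inherits(constraints1, "sbe_constraints"),
            inherits(constraints2, "sbe_constraints"))
  if (length(beta1) == 0 || length(beta2) == 0)
    abort_validation("beta grids must be non-empty")
  if (any(beta1 < 0) || any(beta2 < 0))
    abort_validation("beta grids must be non-negative")
  g <- matrix(NA_real_, length(beta1), length(beta2))
  for (i in seq_along(beta1)) {
    for (j in seq_along(beta2)) {
      sets <- list(
        enzyme_set(beta1[i], constraints1$x0, constraints1$xmin, "(i)"),
        enzyme_set(beta2[j], constraints2$x0, constraints2$xmin, "(ii)"))
      g[i, j] <- tryCatch(solve_gamma(sets, xmax = xmax),
                          amylocld_no_steady_state_error = function(e) NA_real_)
    }
  }
  structure(list(beta1 = beta1, beta2 = beta2, gamma = g,
                 constraints = c(x0_i = constraints1$x0,
                                 xmin_i = constraints1$xmin,
                                 x0_ii = constraints2$x0,
                                 xmin_ii = constraints2$xmin),
                 xmax = as.integer(xmax)),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes, gamma in [%.4g, %.4g], constraints (%d,%d)/(%d,%d)\n",
              length(x$beta1), length(x$beta2),
              min(x$gamma, na.rm = TRUE), max(x$gamma, na.rm = TRUE),
              x$constraints[1], x$constraints[2],
              x$constraints[3], x$constraints[4]))
  invisible(x)
}

#' Export a steady-state surface
#'
#' Writes the solved surface as a long-format TSV (`beta1`, `beta2`, `gamma`)
#' plus a JSON metadata block carrying the constraint integers and `xmax`.
#'
#' @param surface a `surface_grid` from [steady_state_surface()].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the long-format data.frame.
#' @export
write_surface <- function(surface, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(surface, "surface_grid"))
  long <- expand.grid(beta1 = surface$beta1, beta2 = surface$beta2,
                      KEEP.OUT.ATTRS = FALSE)
  long$gamma <- as.vector(surface$gamma)
  if (!is.null(tsv_path))
    utils::write.table(long, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(constraints = as.list(surface$constraints), xmax = surface$xmax,
           n_beta1 = length(surface$beta1), n_beta2 = length(surface$beta2)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(long)
}
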