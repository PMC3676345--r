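#' Branching contribution to the evolution operator
#'
#' Builds the square rate matrix (per unit propagation rate) describing the
#' action of one branching enzyme alone.  A substrate chain of DP `X` is
#' eligible iff `X >= x0 + xmin` (the step function of the evolution
#' equation); an eligible chain is consumed at total rate `beta`, and each of
#' the `X - x0 - xmin + 1` admissible cleavage positions `k` in
#' `[xmin, X - x0]` is equally likely, producing one transferred fragment of
#' DP `k` and one remaining stub of DP `X - k`.  Entry `(Y, X)` is the rate at
#' which DP-`X` chains produce DP-`Y` chains.
#'
#' @param constraints an [sbe_constraints()].
#' @param beta non-negative branching-to-propagation ratio.
#' @param xmax integer truncation DP.
#' @return An `evolution_operator`: list with `xmax` and the dense `matrix`.
#' @examples
#' op <- build_branching_kernel(sbe_constraints(6, 7), beta = 0.05, xmax = 20)
#' # DP 13 has a single admissible cleavage: fragment 7 + stub 6
#' op$matrix[c(6, 7), 13]
#' @export
build_branching_kernel <- function(constraints, beta, xmax) {
  stopifnot(inherits(constraints, "sbe_constraints"))
  if (!is_scalar_num(beta) || beta < 0)
    abort_validation("`beta` must be a single non-negative number")
  if (!is_count(xmax, min = 1L))
    abort_validation("`xmax` must be a positive integer")
  thr <- constraints$x0 + constraints$xmin
  if (xmax < thr)
    abort_validation(sprintf(
      "no eligible substrate: xmax (%d) < X0 + Xmin (%d)", xmax, thr))
  A <- matrix(0, xmax, xmax)
  if (beta > 0) {
    for (X in thr:xmax) {
      ks <- constraints$xmin:(X - constraints$x0)
      w <- beta / length(ks)
      A[X, X] <- A[X, X] - beta
      for (k in ks) {
        A[k, X] <- A[k, X] + w
        A[X - k, X] <- A[X - k, X] + w
      }
    }
  }
  new_evolution_operator(A, xmax)
}

new_evolution_operator <- function(matrix, xmax) {
  structure(list(xmax = as.integer(xmax), matrix = matrix),
            class = "evolution_operator")
}

#' @export
print.evolution_operator <- function(x, ...) {
  cat(sprintf("<evolution_operator> %d x %d, min diag = %g, max offdiag = %g\n",
              x$xmax, x$xmax, min(diag(x$matrix)),
              max(x$matrix - diag(diag(x$matrix)))))
  invisible(x)
}

#' Full normalized evolution operator of a kinetic system
#'
#' Assembles elongation (each chain below `xmax` gains one glucose per unit
#' time, i.e. unit rate from DP `X` to `X + 1`), the branching kernels of all
#' enzyme sets, and the uniform debranching loss `gamma` on every DP bin.
#' Chains at the truncation DP `xmax` no longer elongate; they are removed by
#' branching and debranching only, so the per-column loss satisfies
#' `1(X < xmax) + gamma + sum_j beta_j * H(X - X0_j - Xmin_j)`.
#'
#' @param system a [kinetic_system()].
#' @return An `evolution_operator`.
#' @examples
#' sys <- kinetic_system(enzyme_set(0.05, 6, 7), gamma = 0.03, xmax = 40)
#' op <- build_evolution_operator(sys)
#' # column losses follow the closed-form identity
#' -diag(op$matrix)[1:15]
#' @export
build_evolution_operator <- function(system) {
  if (!inherits(system, "kinetic_system"))
    abort_validation("`system` must be a kinetic_system")
  n <- system$xmax
  A <- matrix(0, n, n)
  for (X in seq_len(n - 1)) {          # elongation
    A[X + 1, X] <- A[X + 1, X] + 1
    A[X, X] <- A[X, X] - 1
  }
  for (s in system$sets)
    A <- A + build_branching_kernel(s$constraints, s$beta, n)$matrix
  diag(A) <- diag(A) - system$gamma    # uniform debranching loss
  new_evolution_operator(A, n)
}
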