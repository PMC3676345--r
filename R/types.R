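#' Branching-enzyme chain-length constraints
#'
#' A starch branching enzyme (SBE) cleaves an alpha-(1->4) bond and transfers
#' the released fragment onto a new alpha-(1->6) position.  Two minimum-length
#' constraints restrict the reaction: the transferred moiety must have degree
#' of polymerization (DP) at least `xmin`, and the remaining stub must have DP
#' at least `x0`.  A chain of DP `X` is therefore an eligible substrate only
#' when `X >= x0 + xmin`.
#'
#' @param x0 integer, minimum DP of the remaining stub (>= 1).
#' @param xmin integer, minimum DP of the transferred fragment (>= 1).
#' @return An object of class `sbe_constraints` with fields `x0` and `xmin`.
#' @examples
#' sbe_constraints(6, 7)
#' @export
sbe_constraints <- function(x0, xmin) {
  if (!is_count(x0)) abort_validation("`x0` must be an integer >= 1")
  if (!is_count(xmin)) abort_validation("`xmin` must be an integer >= 1")
  structure(list(x0 = as.integer(x0), xmin = as.integer(xmin)),
            class = "sbe_constraints")
}

#' @export
print.sbe_constraints <- function(x, ...) {
  cat(sprintf("<sbe_constraints> X0 = %d, Xmin = %d (eligible X >= %d)\n",
              x$x0, x$xmin, x$x0 + x$xmin))
  invisible(x)
}

#' An enzyme set: one starch synthase, one branching and one debranching enzyme
#'
#' The model lumps the biosynthetic machinery into "enzyme sets", each
#' contributing elongation at the common unit propagation rate and branching
#' at the normalized rate `beta` (branching activity of the set divided by the
#' total propagation activity of the system it belongs to).  Fitted values of
#' `beta` are always far below 1 for natural starches.
#'
#' @param beta non-negative branching-to-propagation ratio.
#' @param x0,xmin SBE minimum-length constraints (see [sbe_constraints()]).
#' @param label optional text tag, e.g. `"(i)"`.
#' @return An object of class `enzyme_set`.
#' @examples
#' enzyme_set(0.05, x0 = 6, xmin = 7, label = "(i)")
#' @export
enzyme_set <- function(beta, x0, xmin, label = "") {
  if (!is_scalar_num(beta) || beta < 0)
    abort_validation("`beta` must be a single non-negative number")
  structure(list(label = as.character(label), beta = as.numeric(beta),
                 constraints = sbe_constraints(x0, xmin)),
            class = "enzyme_set")
}

#' @export
print.enzyme_set <- function(x, ...) {
  cat(sprintf("<enzyme_set%s> beta = %g, X0 = %d, Xmin = %d\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$beta, x$constraints$x0, x$constraints$xmin))
  invisible(x)
}

#' A kinetic system of substrate-competing enzyme sets
#'
#' Bundles one or more [enzyme_set()]s acting on a common substrate pool, the
#' pooled relative debranching activity `gamma` (debranching rate of all sets
#' divided by total propagation rate) and the DP truncation `xmax` at which
#' the evolution operator is cut off.
#'
#' @param sets a list of [enzyme_set()] objects (or a single one).
#' @param gamma non-negative pooled debranching ratio.
#' @param xmax integer truncation DP; must exceed `x0 + xmin` of every set.
#' @return An object of class `kinetic_system`.
#' @examples
#' sys <- kinetic_system(
#'   list(enzyme_set(0.05, 6, 7, "(i)"), enzyme_set(0.02, 9, 14, "(ii)")),
#'   gamma = 0.05)
#' sys
#' @export
kinetic_system <- function(sets, gamma, xmax = 110L) {
  if (inherits(sets, "enzyme_set")) sets <- list(sets)
  if (!is.list(sets) || length(sets) < 1L ||
      !all(vapply(sets, inherits, logical(1), "enzyme_set")))
    abort_validation("`sets` must be a non-empty list of enzyme_set objects")
  if (!is_scalar_num(gamma) || gamma < 0)
    abort_validation("`gamma` must be a single non-negative number")
  if (!is_count(xmax, min = 2L))
    abort_validation("`xmax` must be an integer >= 2")
  need <- max(vapply(sets, function(s) s$constraints$x0 + s$constraints$xmin,
                     numeric(1))) + 1L
  if (xmax < need)
    abort_validation(sprintf(
      "`xmax` (%d) must be at least max(X0 + Xmin) + 1 = %d", xmax, need))
  structure(list(sets = sets, gamma = as.numeric(gamma),
                 xmax = as.integer(xmax)),
            class = "kinetic_system")
}

#' @export
print.kinetic_system <- function(x, ...) {
  cat(sprintf("<kinetic_system> %d set(s), gamma = %g, Xmax = %d\n",
              length(x$sets), x$gamma, x$xmax))
  for (s in x$sets)
    cat(sprintf("  %-6s beta = %-8g X0 = %-3d Xmin = %d\n",
                s$label, s$beta, s$constraints$x0, s$constraints$xmin))
  invisible(x)
}

# internal accessors used throughout the fit/solve layer
sys_x0   <- function(sets) vapply(sets, function(s) s$constraints$x0, integer(1))
sys_xmin <- function(sets) vapply(sets, function(s) s$constraints$xmin, integer(1))
sys_beta <- function(sets) vapply(sets, function(s) s$beta, numeric(1))

#' Chain-length distribution container
#'
#' Holds the relative number of debranched glucan chains `Nde(X)` at each DP.
#' DP values must be strictly increasing positive integers; gaps are allowed
#' (and preserved).  `norm = "max1"` asserts the distribution is scaled to a
#' maximum of 1.
#'
#' @param dp strictly increasing integer DP values.
#' @param abundance non-negative relative abundances aligned with `dp`.
#' @param norm `"raw"` or `"max1"`.
#' @return An object of class `cld` (also a data.frame via [as.data.frame()]).
#' @examples
#' x <- cld(6:10, c(0.2, 0.6, 1, 0.8, 0.5), norm = "max1")
#' as.data.frame(x)
#' @export
cld <- function(dp, abundance, norm = c("raw", "max1")) {
  norm <- match.arg(norm)
  if (length(dp) != length(abundance) || length(dp) == 0L)
    abort_validation("`dp` and `abundance` must be equal-length, non-empty")
  if (any(!is.finite(dp)) || any(dp != round(dp)) || any(dp < 1))
    abort_validation("`dp` must contain integers >= 1")
  if (any(diff(dp) <= 0))
    abort_validation("`dp` must be strictly increasing (no duplicates)")
  if (any(!is.finite(abundance)) || any(abundance < 0))
    abort_validation("`abundance` must be finite and non-negative")
  if (norm == "max1" && abs(max(abundance) - 1) > 1e-12)
    abort_validation("norm = \"max1\" requires max(abundance) == 1")
  structure(list(dp = as.integer(dp), abundance = as.numeric(abundance),
                 norm = norm),
            class = "cld")
}

#' Rescale a CLD to a maximum of 1
#'
#' @param x a [cld()].
#' @return A `cld` with `norm = "max1"`.
#' @export
normalize_cld <- function(x) {
  stopifnot(inherits(x, "cld"))
  m <- max(x$abundance)
  if (m <= 0) abort_validation("cannot normalize an all-zero CLD")
  cld(x$dp, x$abundance / m, norm = "max1")
}

#' @export
as.data.frame.cld <- function(x, ...) {
  data.frame(dp = x$dp, abundance = x$abundance)
}

#' @export
print.cld <- function(x, ...) {
  cat(sprintf("<cld> %d DP bins, DP %d..%d, norm = %s, max = %g at DP %d\n",
              length(x$dp), min(x$dp), max(x$dp), x$norm,
              max(x$abundance), x$dp[which.max(x$abundance)]))
  invisible(x)
}

# abundance at given dp values (0 where absent)
cld_at <- function(x, dp) {
  idx <- match(dp, x$dp)
  out <- ifelse(is.na(idx), 0, x$abundance[idx])
  as.numeric(out)
}
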