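#' Fitting configuration
#'
#' Collects the ranges, integer search grids and options used by the fitting
#' procedure.  Defaults follow the conventions of fluorophore-assisted
#' carbohydrate electrophoresis (FACE) data: the single-lamella (SL) range
#' starts at the shortest chain SBEs can produce (DP 6) and ends near DP 30;
#' the trans-lamella (TL) range starts where the SL model first deviates from
#' the data (auto-detected, falling back to DP 32) and ends near DP 67, past
#' which chains are presumed to span three lamellae and are not modelled.
#'
#' @param sl_start,sl_end SL fit range in DP.
#' @param tl_start `"auto"` (detect the deviation point) or an integer DP.
#' @param tl_end last DP entering the TL fit.
#' @param x0_grid,xmin_grid integer search grids for the SBE constraints.
#' @param objective_scale `"log10"` (default; CLD features span about four
#'   decades) or `"linear"`.
#' @param xmax truncation DP of the evolution operator.
#' @param model `"competing"` (sets share one substrate pool) or
#'   `"independent"` (each set has its own pool, adding the ratio h(ii/i)).
#' @param tl_fallback DP used when deviation detection finds nothing.
#' @param deviation_threshold decades of excess abundance (for 3 consecutive
#'   DPs) that define the TL deviation point.
#' @param screen_xmax reduced truncation used only in the coarse screening
#'   pass over the integer grid (final refits always use `xmax`).
#' @param refine_top number of shortlisted candidates refined by full
#'   continuous optimization.
#' @param shortlist number of screened candidates receiving a quick
#'   continuous pre-refinement before the `refine_top` cut.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(sl_start = 6L, sl_end = 30L, tl_start = "auto",
                       tl_end = 67L, x0_grid = 2:12, xmin_grid = 4:20,
                       objective_scale = c("log10", "linear"),
                       xmax = 110L, model = c("competing", "independent"),
                       tl_fallback = 32L, deviation_threshold = 0.05,
                       screen_xmax = 60L, refine_top = 32L,
                       shortlist = 1500L) {
  objective_scale <- match.arg(objective_scale)
  model <- match.arg(model)
  if (!is_count(sl_start) || !is_count(sl_end) || !is_count(tl_end))
    abort_validation("range endpoints must be positive integers")
  if (!(identical(tl_start, "auto") || is_count(tl_start)))
    abort_validation("`tl_start` must be \"auto\" or a positive integer")
  if (!(sl_start < sl_end && sl_end < tl_end && tl_end <= xmax))
    abort_validation("need sl_start < sl_end < tl_end <= xmax")
  if (length(x0_grid) == 0 || length(xmin_grid) == 0)
    abort_validation("integer grids must be non-empty")
  if (any(x0_grid < 1) || any(xmin_grid < 1))
    abort_validation("integer grids must be >= 1")
  structure(list(sl_start = as.integer(sl_start), sl_end = as.integer(sl_end),
                 tl_start = if (identical(tl_start, "auto")) "auto"
                            else as.integer(tl_start),
                 tl_end = as.integer(tl_end),
                 x0_grid = as.integer(sort(unique(x0_grid))),
                 xmin_grid = as.integer(sort(unique(xmin_grid))),
                 objective_scale = objective_scale,
                 xmax = as.integer(xmax), model = model,
                 tl_fallback = as.integer(tl_fallback),
                 deviation_threshold = deviation_threshold,
                 screen_xmax = as.integer(min(screen_xmax, xmax)),
                 refine_top = as.integer(refine_top),
                 shortlist = as.integer(shortlist)),
            class = "fit_config")
}

#' Least-squares objective between two CLDs
#'
#' Sum of squared residuals between observed and model abundances over a DP
#' range, on the log10 or linear scale.
#'
#' @param obs,model [cld()] objects.
#' @param range integer vector `c(first_dp, last_dp)`.
#' @param scale `"log10"` or `"linear"`.
#' @return The scalar sum of squared residuals over DPs present in `obs`
#'   within the range (model abundance taken as 0 where absent).
#' @export
cld_objective <- function(obs, model, range, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(obs, "cld"), inherits(model, "cld"), length(range) == 2)
  dps <- obs$dp[obs$dp >= range[1] & obs$dp <= range[2]]
  if (length(dps) == 0) abort_validation("ranges do not overlap")
  ov <- cld_at(obs, dps)
  mv <- cld_at(model, dps)
  if (scale == "log10") {
    bad <- which(ov <= 0 | mv <= 0)
    if (length(bad) > 0)
      abort_validation(sprintf(
        "non-positive abundance on log scale at DP %s",
        paste(dps[bad], collapse = ", ")))
    sum((log10(ov) - log10(mv))^2)
  } else {
    sum((ov - mv)^2)
  }
}

# ---------------------------------------------------------------------------
# Internal search machinery

# Integer candidates for the two-set search.  Two symmetries cut the grid:
# the branching kernel is invariant under swapping X0 and Xmin (both cleavage
# products enter the CLD, so only the unordered pair matters — echoing that
# CLD data cannot distinguish the stub minimum from the fragment minimum),
# and set labels (i)/(ii) are interchangeable.  Canonical form: per-set
# X0 <= Xmin where both grids allow it, sets ordered by (X0+Xmin, X0, Xmin).
candidate_grid <- function(x0_grid, xmin_grid) {
  per <- expand.grid(x0 = x0_grid, xmin = xmin_grid, KEEP.OUT.ATTRS = FALSE)
  per <- per[order(per$x0, per$xmin), , drop = FALSE]
  key <- paste(pmin(per$x0, per$xmin), pmax(per$x0, per$xmin))
  per <- per[!duplicated(key), , drop = FALSE]
  ord <- order(per$x0 + per$xmin, per$x0, per$xmin)
  per <- per[ord, , drop = FALSE]
  np <- nrow(per)
  ia <- rep(seq_len(np), times = np - seq_len(np) + 1L)
  ib <- unlist(lapply(seq_len(np), function(i) i:np))
  cbind(x0a = per$x0[ia], xmina = per$xmin[ia],
        x0b = per$x0[ib], xminb = per$xmin[ib])
}

screen_beta_grid <- function() {
  g <- c(0.01, 0.03, 0.08, 0.2) # log-spaced across the beta << 1 regime
  as.matrix(expand.grid(b1 = g, b2 = g, KEEP.OUT.ATTRS = FALSE))
}

# prepare the normalized observation vector on the requested scale
prep_obs <- function(obs, range, scale) {
  dps <- obs$dp[obs$dp >= range[1] & obs$dp <= range[2]]
  if (length(dps) < 10)
    abort_validation(sprintf(
      "only %d usable points in range [%d, %d]; at least 10 required",
      length(dps), range[1], range[2]))
  v <- cld_at(obs, dps)
  m <- max(v)
  if (m <= 0) abort_validation("observed abundance is zero over the range")
  v <- v / m
  if (scale == "log10") {
    if (any(v <= 0))
      abort_validation(sprintf(
        "non-positive abundance on log scale at DP %s",
        paste(dps[v <= 0], collapse = ", ")))
    list(dp = as.integer(dps), y = log10(v), scale_factor = m)
  } else {
    list(dp = as.integer(dps), y = v, scale_factor = m)
  }
}

# objective for one candidate at given betas (sum or mean, per window rule)
cand_objective <- function(ints, beta, xmax, dp, y, log_scale, support_rule,
                           tol = 1e-14) {
  if (support_rule) {
    floor_dp <- min(ints[1], ints[2], ints[3], ints[4])
    keep <- dp >= floor_dp
    if (sum(keep) < 10) return(list(ok = FALSE))
    r <- .cpp_sse(ints[c(1, 3)], ints[c(2, 4)], beta, xmax,
                  dp[keep], y[keep], log_scale, TRUE, tol)
    if (!r$ok || r$n < 10) return(list(ok = FALSE))
    list(ok = TRUE, value = r$sse / r$n, sse = r$sse, n = r$n,
         gamma = r$gamma)
  } else {
    r <- .cpp_sse(ints[c(1, 3)], ints[c(2, 4)], beta, xmax, dp, y,
                  log_scale, FALSE, tol)
    if (!r$ok) return(list(ok = FALSE))
    list(ok = TRUE, value = r$sse, sse = r$sse, n = r$n, gamma = r$gamma)
  }
}

# continuous beta optimization for one integer candidate; log-parameterized
# Nelder-Mead with the bound beta <= 1 (steady states with beta near or above
# 1 are drastically unlike natural amylopectin and act as degenerate sinks
# for the objective)
refine_candidate <- function(ints, beta0, xmax, dp, y, log_scale,
                             support_rule, reltol = 1e-10, maxit = 400,
                             tol = 1e-12) {
  fn <- function(p) {
    if (any(p > 0) || any(p < -20)) return(1e12 + sum(abs(p)))
    r <- cand_objective(ints, exp(p), xmax, dp, y, log_scale, support_rule,
                        tol = tol)
    if (!r$ok) return(1e12)
    r$value
  }
  o <- stats::optim(log(pmin(pmax(beta0, 1e-6), 1)), fn,
                    method = "Nelder-Mead",
                    control = list(reltol = reltol, maxit = maxit))
  list(beta = exp(o$par), value = o$value)
}

#' Fit the substrate-competing two-set model over a DP range
#'
#' Exhaustive search over the integer SBE-constraint grids for both enzyme
#' sets with nested continuous optimization of the two branching ratios.  At
#' every candidate, gamma is solved on the steady-state surface — it is never
#' a free parameter.  The search is deterministic: all integer candidates are
#' screened against a fixed coarse beta grid, the best `refine_top` are
#' refined by Nelder-Mead, and the winner is polished at high precision.
#' Ties are broken by lower objective, then smaller `X0 + Xmin`.
#'
#' @param obs observed [cld()] (rescaled internally to max 1 over the range).
#' @param cfg a [fit_config()].
#' @param range integer `c(first_dp, last_dp)`; defaults to the SL range.
#' @param support_rule if `TRUE` (the TL convention) only DPs at or above the
#'   candidate's support floor `min(X0, Xmin)` enter the objective, and
#'   candidates are compared by mean squared residual over their usable
#'   window; with `FALSE` (the SL convention) every DP in the range counts.
#' @return A list of class `range_fit`: fitted `sets` (pair of
#'   [enzyme_set()]), solved `gamma`, `sse`, `n_points`, the full `model`
#'   CLD (max-1 normalized) and the scale factor applied to `obs`.
#' @export
fit_competing_range <- function(obs, cfg = fit_config(), range = NULL,
                                support_rule = FALSE) {
  stopifnot(inherits(obs, "cld"), inherits(cfg, "fit_config"))
  if (is.null(range)) range <- c(cfg$sl_start, cfg$sl_end)
  po <- prep_obs(obs, range, cfg$objective_scale)
  log_scale <- cfg$objective_scale == "log10"
  cand <- candidate_grid(cfg$x0_grid, cfg$xmin_grid)
  keep <- (cand[, "x0a"] + cand[, "xmina"] + 1L <= cfg$xmax) &
          (cand[, "x0b"] + cand[, "xminb"] + 1L <= cfg$xmax)
  if (!support_rule) {
    # model support starts at the joint floor min(X0, Xmin); a candidate
    # whose floor lies above the first observed DP predicts zero abundance
    # there and can never win on a log-scale range
    floor_dp <- pmin(pmin(cand[, "x0a"], cand[, "xmina"]),
                     pmin(cand[, "x0b"], cand[, "xminb"]))
    keep <- keep & floor_dp <= po$dp[1]
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    abort_validation("no admissible integer candidates for this xmax")

  sc <- .cpp_screen(cand, screen_beta_grid(), cfg$screen_xmax,
                    po$dp, po$y, log_scale, support_rule,
                    if (support_rule) 10L else 0L, 1e-8)
  ok <- is.finite(sc[, 1])
  if (!any(ok))
    abort_no_steady_state("no candidate achieves a steady state over the grid")
  ord <- order(sc[, 1], cand[, 1] + cand[, 2] + cand[, 3] + cand[, 4])
  ord <- ord[is.finite(sc[ord, 1])]

  # funnel: quick pre-refinement of the shortlist at reduced truncation,
  # then full-precision refinement of the survivors
  short <- utils::head(ord, cfg$shortlist)
  pre <- vapply(short, function(i) {
    r <- refine_candidate(cand[i, ], sc[i, 2:3], cfg$screen_xmax, po$dp,
                          po$y, log_scale, support_rule, reltol = 1e-6,
                          maxit = 80, tol = 1e-9)
    c(r$value, r$beta)
  }, numeric(3))
  ord2 <- short[order(pre[1, ],
                      rowSums(cand[short, , drop = FALSE]))]
  pre_beta <- pre[2:3, order(pre[1, ],
                             rowSums(cand[short, , drop = FALSE])),
                  drop = FALSE]
  top <- seq_len(min(cfg$refine_top, length(ord2)))

  best <- NULL
  for (k in top) {
    i <- ord2[k]
    ints <- cand[i, ]
    r <- refine_candidate(ints, pre_beta[, k], cfg$xmax, po$dp, po$y,
                          log_scale, support_rule)
    cmp <- c(r$value, sum(ints))
    if (is.null(best) || cmp[1] < best$cmp[1] ||
        (cmp[1] == best$cmp[1] && cmp[2] < best$cmp[2])) {
      best <- list(ints = ints, beta = r$beta, cmp = cmp)
    }
  }
  # high-precision polish of the winner
  pol <- refine_candidate(best$ints, best$beta, cfg$xmax, po$dp, po$y,
                          log_scale, support_rule, reltol = 1e-13,
                          maxit = 2000, tol = 1e-14)
  beta <- pol$beta
  ints <- best$ints
  sets <- list(enzyme_set(beta[1], ints[1], ints[2], "(i)"),
               enzyme_set(beta[2], ints[3], ints[4], "(ii)"))
  ss <- solve_steady_state(sets, xmax = cfg$xmax)
  fin <- cand_objective(ints, beta, cfg$xmax, po$dp, po$y, log_scale,
                        support_rule)
  structure(list(sets = sets, gamma = ss$gamma, sse = fin$sse,
                 n_points = fin$n, model = ss$cld,
                 scale_factor = po$scale_factor, range = range,
                 objective_scale = cfg$objective_scale),
            class = "range_fit")
}

#' @export
print.range_fit <- function(x, ...) {
  cat(sprintf("<range_fit> DP %d..%d, sse = %.4g over %d points, gamma = %.5g\n",
              x$range[1], x$range[2], x$sse, x$n_points, x$gamma))
  for (s in x$sets)
    cat(sprintf("  %-6s beta = %-10.5g X0 = %-3d Xmin = %d\n", s$label,
                s$beta, s$constraints$x0, s$constraints$xmin))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Independent-substrate variant

# evaluate the independent-substrate composite N(i) + h * N(ii), both
# components max-1 single-set steady-state CLDs; returns values at dp after
# max-1 normalization of the composite (NULL if either set is off-surface)
independent_model_values <- function(ints, beta, h, xmax, dp) {
  r1 <- .cpp_solve_ss(ints[1], ints[2], beta[1], xmax)
  if (!r1$ok || !r1$clean) return(NULL)
  comp <- r1$cld
  if (h > 0) {
    r2 <- .cpp_solve_ss(ints[3], ints[4], beta[2], xmax)
    if (!r2$ok || !r2$clean) return(NULL)
    comp <- comp + h * r2$cld
  }
  comp <- comp / max(comp)
  comp[dp]
}

indep_objective <- function(ints, beta, h, xmax, dp, y, log_scale) {
  mv <- independent_model_values(ints, beta, h, xmax, dp)
  if (is.null(mv)) return(NA_real_)
  if (log_scale) {
    if (any(mv <= 0)) return(1e10 * sum(mv <= 0))
    sum((log10(mv) - y)^2)
  } else {
    sum((mv - y)^2)
  }
}

#' Fit the independent-substrate two-set model over a DP range
#'
#' Each enzyme set obeys its own single-set steady-state condition and the
#' composite model is `N(i) + h(ii/i) * N(ii)` (linear abundances, each
#' component normalized to max 1).  Compared with the substrate-competing
#' model there is one additional free parameter, the maxima ratio `h(ii/i)`.
#' The search mirrors [fit_competing_range()]; `h` is constrained to `(0, 1]`
#' with set (i) the dominant component.
#'
#' @inheritParams fit_competing_range
#' @return A list of class `range_fit_independent` with per-set fits, the
#'   fitted `h_ii_over_i`, `sse`, and the composite `model` CLD.
#' @export
fit_independent_range <- function(obs, cfg = fit_config(model = "independent"),
                                  range = NULL) {
  stopifnot(inherits(obs, "cld"), inherits(cfg, "fit_config"))
  if (is.null(range)) range <- c(cfg$sl_start, cfg$sl_end)
  po <- prep_obs(obs, range, cfg$objective_scale)
  log_scale <- cfg$objective_scale == "log10"
  cand <- candidate_grid(cfg$x0_grid, cfg$xmin_grid)

  # screening: cache single-set component CLDs per (x0, xmin, beta) node
  bg <- c(0.01, 0.03, 0.1)
  hg <- c(0.02, 0.1, 0.5)
  per <- unique(rbind(cand[, 1:2, drop = FALSE],
                      cand[, 3:4, drop = FALSE]))
  colnames(per) <- c("x0", "xmin")
  comp_cache <- new.env(parent = emptyenv())
  get_comp <- function(x0, xmin, b) {
    key <- paste(x0, xmin, b, sep = "_")
    v <- comp_cache[[key]]
    if (is.null(v)) {
      r <- .cpp_solve_ss(x0, xmin, b, cfg$screen_xmax)
      v <- if (r$ok && r$clean) r$cld else NA
      comp_cache[[key]] <- v
    }
    v
  }
  nscore <- rep(Inf, nrow(cand))
  npars <- matrix(NA_real_, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    ints <- cand[i, ]
    best <- Inf; bp <- c(NA, NA, NA)
    for (b1 in bg) {
      c1 <- get_comp(ints[1], ints[2], b1)
      if (length(c1) == 1 && is.na(c1[1])) next
      for (b2 in bg) {
        c2 <- get_comp(ints[3], ints[4], b2)
        if (length(c2) == 1 && is.na(c2[1])) next
        for (h in hg) {
          comp <- c1 + h * c2
          mv <- (comp / max(comp))[po$dp]
          s <- if (log_scale) {
            if (any(mv <= 0)) 1e10 * sum(mv <= 0)
            else sum((log10(mv) - po$y)^2)
          } else sum((mv - po$y)^2)
          if (s < best) { best <- s; bp <- c(b1, b2, h) }
        }
      }
    }
    nscore[i] <- best; npars[i, ] <- bp
  }
  if (!any(is.finite(nscore)))
    abort_no_steady_state("no candidate achieves a steady state over the grid")
  ord <- order(nscore, cand[, 1] + cand[, 2] + cand[, 3] + cand[, 4])
  top <- utils::head(ord[is.finite(nscore[ord])],
                     max(10L, cfg$refine_top %/% 2L))
  best <- NULL
  for (i in top) {
    ints <- cand[i, ]
    fn <- function(p) {
      if (any(p[1:2] > 0) || any(p < -20)) return(1e12 + sum(abs(p)))
      h <- min(exp(p[3]), 1)
      s <- indep_objective(ints, exp(p[1:2]), h, cfg$xmax, po$dp, po$y,
                           log_scale)
      if (is.na(s)) 1e12 else s
    }
    o <- stats::optim(log(pmax(c(npars[i, 1:2], min(npars[i, 3], 1)), 1e-6)),
                      fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
    if (is.null(best) || o$value < best$value)
      best <- list(ints = ints, par = o$par, value = o$value)
  }
  o <- stats::optim(best$par, function(p) {
    if (any(p[1:2] > 0) || any(p < -20)) return(1e12 + sum(abs(p)))
    h <- min(exp(p[3]), 1)
    s <- indep_objective(best$ints, exp(p[1:2]), h, cfg$xmax, po$dp, po$y,
                         log_scale)
    if (is.na(s)) 1e12 else s
  }, method = "Nelder-Mead", control = list(reltol = 1e-13, maxit = 3000))
  beta <- exp(o$par[1:2]); h <- min(exp(o$par[3]), 1)
  ints <- best$ints
  set1 <- enzyme_set(beta[1], ints[1], ints[2], "(i)")
  set2 <- enzyme_set(beta[2], ints[3], ints[4], "(ii)")
  ss1 <- solve_steady_state(list(set1), xmax = cfg$xmax)
  ss2 <- solve_steady_state(list(set2), xmax = cfg$xmax)
  comp <- ss1$cld$abundance + h * ss2$cld$abundance
  model <- cld(seq_len(cfg$xmax), comp / max(comp), norm = "max1")
  structure(list(sets = list(set1, set2),
                 gammas = c(ss1$gamma, ss2$gamma),
                 h_ii_over_i = h, sse = o$value,
                 n_points = length(po$dp), model = model,
                 scale_factor = po$scale_factor, range = range,
                 objective_scale = cfg$objective_scale),
            class = "range_fit_independent")
}

#' @export
print.range_fit_independent <- function(x, ...) {
  cat(sprintf("<range_fit_independent> DP %d..%d, sse = %.4g, h(ii/i) = %.4g\n",
              x$range[1], x$range[2], x$sse, x$h_ii_over_i))
  for (k in seq_along(x$sets)) {
    s <- x$sets[[k]]
    cat(sprintf("  %-6s beta = %-10.5g X0 = %-3d Xmin = %-3d gamma = %.5g\n",
                s$label, s$beta, s$constraints$x0, s$constraints$xmin,
                x$gammas[k]))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# TL residual machinery

#' Detect the start of the trans-lamella range
#'
#' The TL range begins where the fitted SL model first deviates
#' systematically from the observation: the smallest DP at or above
#' `sl_end - 5` where the observed abundance exceeds the SL model by more
#' than `deviation_threshold` decades for three consecutive DPs.  Falls back
#' to `tl_fallback` (with a warning) when no such point exists.
#'
#' @param obs observed [cld()] in SL-normalized units (max 1 over SL range).
#' @param sl_model fitted SL model [cld()] (max-1 normalized).
#' @param cfg a [fit_config()].
#' @return The detected DP (integer).
#' @export
detect_tl_start <- function(obs, sl_model, cfg = fit_config()) {
  stopifnot(inherits(obs, "cld"), inherits(sl_model, "cld"))
  from <- cfg$sl_end - 5L
  dps <- obs$dp[obs$dp >= from]
  if (length(dps) < 3) {
    warning("observation too short to search for a TL deviation; using fallback")
    return(cfg$tl_fallback)
  }
  ov <- cld_at(obs, dps)
  mv <- cld_at(sl_model, dps)
  excess <- ifelse(ov > 0 & mv > 0, log10(ov) - log10(mv),
                   ifelse(ov > 0 & mv <= 0, Inf, -Inf))
  over <- excess > cfg$deviation_threshold
  for (k in seq_len(length(dps) - 2)) {
    if (over[k] && over[k + 1] && over[k + 2] &&
        dps[k + 1] == dps[k] + 1L && dps[k + 2] == dps[k] + 2L)
      return(dps[k])
  }
  warning(sprintf("no TL deviation found; falling back to DP %d",
                  cfg$tl_fallback))
  cfg$tl_fallback
}

#' Extract and displace the type-2 TL residual
#'
#' Subtracts the fitted SL model from the observation (in linear abundance,
#' never log) for `X >= tl_start`, then displaces the residual to start at
#' `X' = 1` — the protruding portion of a long chain behaves like a fresh
#' short chain for the TL enzyme sets.  Bins with non-positive residual are
#' dropped (they carry no type-2 signal); the original DP axis is retained
#' as the `orig_dp` attribute.
#'
#' @param obs observed [cld()] in SL-normalized units.
#' @param sl_model fitted SL model [cld()].
#' @param tl_start first DP of the TL range.
#' @return A [cld()] on the displaced axis with attribute `orig_dp`, or
#'   `NULL` when every residual is non-positive (the "no TL component"
#'   signal, i.e. `h(iii/i) = 0`).
#' @export
extract_type2_residual <- function(obs, sl_model, tl_start) {
  stopifnot(inherits(obs, "cld"), inherits(sl_model, "cld"),
            is_count(tl_start))
  dps <- obs$dp[obs$dp >= tl_start]
  if (length(dps) == 0) return(NULL)
  resid <- cld_at(obs, dps) - cld_at(sl_model, dps)
  keep <- resid > 0
  if (!any(keep)) return(NULL)
  out <- cld(dps[keep] - tl_start + 1L, resid[keep], norm = "raw")
  attr(out, "orig_dp") <- dps[keep]
  attr(out, "tl_start") <- as.integer(tl_start)
  out
}

#' Maxima ratio of the TL component to the SL component
#'
#' With the SL CLD normalized to a maximum of 1 (`h(i) = 1`), `h(iii/i)` is
#' simply the maximum of the fitted type-2 TL component expressed in the same
#' units.
#'
#' @param tl_component the fitted TL component [cld()] in SL-normalized
#'   units, or `NULL` (the no-TL signal).
#' @return `h(iii/i)` (0 when there is no TL component).
#' @export
compute_h_ratio <- function(tl_component) {
  if (is.null(tl_component)) return(0)
  stopifnot(inherits(tl_component, "cld"))
  max(tl_component$abundance)
}

#' Compose the overall model CLD from SL and TL components
#'
#' Linear-abundance sum of the SL model (max 1) and the TL model shifted back
#' to the original axis (displacement removed) and scaled to a maximum of
#' `h`.  It is the number distributions, never their logarithms, that add.
#'
#' @param sl_model SL model [cld()] (max-1).
#' @param tl_model TL model [cld()] on the displaced axis (max-1), or `NULL`.
#' @param h maxima ratio `h(iii/i)`.
#' @param tl_start first DP of the TL range (displacement offset).
#' @return The composed [cld()] (`norm = "raw"`; maximum is that of the SL
#'   component).
#' @export
compose_overall <- function(sl_model, tl_model, h, tl_start) {
  stopifnot(inherits(sl_model, "cld"))
  if (is.null(tl_model) || h <= 0) {
    return(cld(sl_model$dp, sl_model$abundance, norm = "raw"))
  }
  stopifnot(inherits(tl_model, "cld"), is_count(tl_start))
  tl_dp <- tl_model$dp + tl_start - 1L
  tl_ab <- tl_model$abundance / max(tl_model$abundance) * h
  all_dp <- sort(unique(c(sl_model$dp, tl_dp)))
  ab <- cld_at(sl_model, all_dp)
  idx <- match(tl_dp, all_dp)
  ab[idx] <- ab[idx] + tl_ab
  cld(all_dp, ab, norm = "raw")
}

# ---------------------------------------------------------------------------

#' Fit the full two-tier model to an experimental CLD
#'
#' Runs the complete fitting procedure: (1) fit the SL range with the
#' substrate-competing (or independent-substrate) model, gamma always solved
#' on the steady-state surface; (2) locate the start of the TL range where
#' the SL model deviates from the data (unless `cfg$tl_start` is given as an
#' integer); (3) subtract the SL model, displace the positive residual to
#' `X' = 1`; (4) fit the displaced type-2 TL CLD — always with the
#' substrate-competing model; (5) compute `h(iii/i)` and compose the overall
#' model CLD.
#'
#' @param obs observed [cld()]; must cover the SL range and extend to the TL
#'   range for a TL fit to be attempted.
#' @param cfg a [fit_config()].
#' @return An object of class `fit_result` with elements `sl` (SL range
#'   fit), `tl` (TL range fit or `NULL`), `h_iii_over_i`, `h_ii_over_i` (for
#'   the independent SL model), `tl_start_used`, `sse_sl`, `sse_tl`,
#'   `model_cld` (composed), `residuals` (per-DP table), and `cfg`.
#' @export
fit_cld <- function(obs, cfg = fit_config()) {
  stopifnot(inherits(obs, "cld"), inherits(cfg, "fit_config"))
  if (min(obs$dp) > cfg$sl_start || max(obs$dp) < cfg$sl_end)
    abort_validation(sprintf(
      "observation (DP %d..%d) must cover the SL range [%d, %d]",
      min(obs$dp), max(obs$dp), cfg$sl_start, cfg$sl_end))

  sl_range <- c(cfg$sl_start, cfg$sl_end)
  fit_sl <- function(range) {
    if (cfg$model == "competing") fit_competing_range(obs, cfg, range)
    else fit_independent_range(obs, cfg, range)
  }
  sl <- withCallingHandlers(
    fit_sl(sl_range),
    error = function(e) {
      if (inherits(e, "amylocld_error"))
        abort(paste0("SL fit: ", conditionMessage(e)), class(e)[1])
    })

  # observation in SL-normalized units (max 1 over the SL fit range)
  obs_n <- cld(obs$dp, obs$abundance / sl$scale_factor, norm = "raw")

  tl_start <- if (identical(cfg$tl_start, "auto"))
    detect_tl_start(obs_n, sl$model, cfg) else cfg$tl_start
  if (tl_start < cfg$sl_end) { # deviation inside the SL window: refit once
    sl_range <- c(cfg$sl_start, tl_start - 1L)
    sl <- fit_sl(sl_range)
    obs_n <- cld(obs$dp, obs$abundance / sl$scale_factor, norm = "raw")
  }

  obs_tl <- cld(obs_n$dp[obs_n$dp <= cfg$tl_end],
                obs_n$abundance[obs_n$dp <= cfg$tl_end], norm = "raw")
  resid <- extract_type2_residual(obs_tl, sl$model, tl_start)

  tl <- NULL; h <- 0; tl_model <- NULL; sse_tl <- NA_real_
  if (!is.null(resid)) {
    h <- max(resid$abundance) # SL-normalized units: h(i) = 1
    resid_n <- normalize_cld(resid)
    tl_range <- c(1L, cfg$tl_end - tl_start + 1L)
    tl <- tryCatch(
      fit_competing_range(resid_n, cfg, range = tl_range,
                          support_rule = TRUE),
      amylocld_validation_error = function(e) NULL,
      amylocld_no_steady_state_error = function(e) NULL)
    if (!is.null(tl)) {
      tl_model <- tl$model
      sse_tl <- tl$sse
    } else {
      h <- 0 # too little residual structure to support a TL fit
    }
  }

  composed <- compose_overall(sl$model, tl_model, h, tl_start)
  dps <- obs_n$dp
  tab <- data.frame(
    dp = dps,
    observed = obs_n$abundance,
    sl_model = cld_at(sl$model, dps),
    tl_model = if (is.null(tl_model)) 0 else {
      shifted <- cld(tl_model$dp + tl_start - 1L,
                     tl_model$abundance * h, norm = "raw")
      cld_at(shifted, dps)
    },
    composed = cld_at(composed, dps))
  tab$residual <- tab$observed - tab$composed

  structure(list(sl = sl, tl = tl, h_iii_over_i = h,
                 h_ii_over_i = if (inherits(sl, "range_fit_independent"))
                   sl$h_ii_over_i else NA_real_,
                 tl_start_used = as.integer(tl_start),
                 sse_sl = sl$sse, sse_tl = sse_tl,
                 model_cld = composed, residuals = tab, cfg = cfg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> two-tier amylopectin CLD fit\n")
  cat(sprintf("  SL range %d..%d  sse = %.4g\n", x$sl$range[1], x$sl$range[2],
              x$sse_sl))
  for (s in x$sl$sets)
    cat(sprintf("    %-6s beta = %-10.5g X0 = %-3d Xmin = %d\n", s$label,
                s$beta, s$constraints$x0, s$constraints$xmin))
  if (!is.na(x$h_ii_over_i))
    cat(sprintf("    h(ii/i)  = %.5g\n", x$h_ii_over_i))
  cat(sprintf("  TL start = %d, h(iii/i) = %.5g\n", x$tl_start_used,
              x$h_iii_over_i))
  if (!is.null(x$tl)) {
    cat(sprintf("  TL fit sse = %.4g\n", x$sse_tl))
    tl_labels <- c("(iii)", "(iv)")
    for (k in seq_along(x$tl$sets)) {
      s <- x$tl$sets[[k]]
      cat(sprintf("    %-6s beta = %-10.5g X0 = %-3d Xmin = %d\n",
                  tl_labels[k], s$beta, s$constraints$x0, s$constraints$xmin))
    }
  }
  invisible(x)
}

# flat named vector of the 13 fitted parameters (synthetic round trips)
fit_parameters <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  sl <- fit$sl$sets
  out <- c(beta_i = sl[[1]]$beta, x0_i = sl[[1]]$constraints$x0,
           xmin_i = sl[[1]]$constraints$xmin,
           beta_ii = sl[[2]]$beta, x0_ii = sl[[2]]$constraints$x0,
           xmin_ii = sl[[2]]$constraints$xmin)
  if (!is.null(fit$tl)) {
    tl <- fit$tl$sets
    out <- c(out,
             beta_iii = tl[[1]]$beta, x0_iii = tl[[1]]$constraints$x0,
             xmin_iii = tl[[1]]$constraints$xmin,
             beta_iv = tl[[2]]$beta, x0_iv = tl[[2]]$constraints$x0,
             xmin_iv = tl[[2]]$constraints$xmin)
  }
  c(out, h_iii_over_i = fit$h_iii_over_i)
}
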