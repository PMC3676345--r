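#' Simulator configuration
#'
#' @param system a [kinetic_system()] (its `gamma` is used as-is; place it on
#'   the steady-state surface with [solve_gamma()] for stationary sampling).
#' @param n_initial_chains starting population size.
#' @param initial_dp DP of every starting chain.
#' @param max_events total number of kinetic Monte-Carlo events.
#' @param burn_in_fraction fraction of events discarded before sampling.
#' @param seed integer seed (all randomness flows from it).
#' @param cap_population population size that triggers the supercritical
#'   signal.
#' @param sample_stride events between CLD samples.
#' @param resample if `TRUE` (default), resample the population back to
#'   `n_initial_chains` whenever it drifts beyond +/-50% — on-surface
#'   dynamics are critical, so population size performs an unbiased random
#'   walk; resampling bounds it without biasing the normalized CLD.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(system, n_initial_chains = 5000L, initial_dp = 10L,
                       max_events = 1e6, burn_in_fraction = 0.5,
                       seed = 1L, cap_population = 1e6L,
                       sample_stride = 50L, resample = TRUE) {
  stopifnot(inherits(system, "kinetic_system"))
  if (!is_count(max_events)) abort_validation("`max_events` must be positive")
  if (!is_count(n_initial_chains))
    abort_validation("`n_initial_chains` must be a positive integer")
  if (!is_count(initial_dp) || initial_dp > system$xmax)
    abort_validation("`initial_dp` must be in 1..xmax")
  if (!is_scalar_num(burn_in_fraction) || burn_in_fraction < 0 ||
      burn_in_fraction >= 1)
    abort_validation("`burn_in_fraction` must be in [0, 1)")
  if (cap_population <= n_initial_chains)
    abort_validation("`cap_population` must exceed `n_initial_chains`")
  structure(list(system = system,
                 n_initial_chains = as.integer(n_initial_chains),
                 initial_dp = as.integer(initial_dp),
                 max_events = as.numeric(max_events),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed),
                 cap_population = as.integer(cap_population),
                 sample_stride = as.integer(sample_stride),
                 resample = isTRUE(resample)),
            class = "sim_config")
}

#' Event-level kinetic Monte-Carlo simulation of a chain population
#'
#' Gillespie-style simulation of an explicit population of linear chains
#' under the three elementary reactions of the model: elongation (one glucose
#' added per non-reducing end, propensity = number of chains below `xmax`),
#' constrained branching per enzyme set (propensity = beta_j times the number
#' of eligible chains; victim chain and cleavage position drawn uniformly
#' among admissible choices), and debranching (propensity = gamma times the
#' chain count; the removed chain leaves the population entirely).  Serves as
#' the stochastic oracle for the analytic steady state.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_result`: `cld_estimate` (time-averaged,
#'   max-1 normalized), `event_counts`, `extinction`, `supercritical`,
#'   `monomer_ledger` (glucose added/removed and the maximum discrepancy
#'   between the ledger and the actual population glucose content, 0 when
#'   conservation holds exactly), `final_counts`, `events`, `n_samples`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sys <- cfg$system
  set.seed(cfg$seed)
  raw <- .cpp_simulate(sys_x0(sys$sets), sys_xmin(sys$sets),
                       sys_beta(sys$sets), sys$gamma, sys$xmax,
                       cfg$n_initial_chains, cfg$initial_dp,
                       cfg$max_events, cfg$burn_in_fraction,
                       cfg$cap_population, cfg$sample_stride,
                       cfg$resample)
  est <- NULL
  if (raw$n_samples > 0 && max(raw$cld) > 0)
    est <- cld(seq_len(sys$xmax), raw$cld / max(raw$cld), norm = "max1")
  structure(list(cld_estimate = est,
                 event_counts = raw$event_counts,
                 extinction = raw$extinct,
                 supercritical = raw$supercritical,
                 monomer_ledger = list(
                   added = raw$glucose_added,
                   removed = raw$glucose_removed,
                   max_discrepancy = raw$ledger_max_discrepancy),
                 final_counts = raw$final_counts,
                 events = raw$events, n_samples = raw$n_samples,
                 config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %g events, %g samples, extinct = %s, supercritical = %s\n",
              x$events, x$n_samples, x$extinction, x$supercritical))
  ec <- x$event_counts
  cat(sprintf("  elongation %g | branching %g | debranching %g | resamples %g\n",
              ec[["elongation"]], ec[["branching"]], ec[["debranching"]],
              ec[["resample"]]))
  cat(sprintf("  monomer ledger max discrepancy: %g\n",
              x$monomer_ledger$max_discrepancy))
  invisible(x)
}

#' Count type-1 and type-2 TL chains over a window
#'
#' Type-1 TL chains are the long tail of the SL kinetics (crystalline-lamella
#' connecting chains); type-2 TL chains come from the independent TL enzyme
#' sets and remain in the amorphous lamellae.  Both counts are sums of the
#' relative number distributions over `[tl_start, tl_end]`, in the same
#' (SL-normalized) units.
#'
#' @param sl_model SL model [cld()] (max 1).
#' @param tl_component TL component [cld()] on the original DP axis, scaled
#'   by `h(iii/i)`, or `NULL` for no TL component.
#' @param tl_start,tl_end window in DP.
#' @return A list with `type1`, `type2` and `ratio` (= type2 / type1).
#' @export
classify_tl_chains <- function(sl_model, tl_component, tl_start, tl_end) {
  stopifnot(inherits(sl_model, "cld"))
  win <- tl_start:tl_end
  t1 <- sum(cld_at(sl_model, win))
  if (t1 <= 0)
    abort_validation("type-1 chain count is zero over the window; ratio undefined")
  t2 <- if (is.null(tl_component)) 0 else sum(cld_at(tl_component, win))
  list(type1 = t1, type2 = t2, ratio = t2 / t1)
}
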