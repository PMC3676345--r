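# fitting: objective, TL-range machinery and the range/pipeline fits.
# Search-heavy tests run on reduced integer grids (helper small_fit_config);
# the full default grids are exercised in the acceptance suite.

test_that("objective matches direct summation on both scales", {
  obs <- cld(6:15, c(1, 2, 4, 8, 10, 9, 7, 5, 3, 2) / 10)
  mod <- cld(6:15, c(1.2, 2.1, 3.9, 8.2, 9.7, 9.1, 6.6, 5.2, 3.1, 1.8) / 10)
  expect_equal(cld_objective(obs, obs, c(6, 15), "log10"), 0)
  expect_equal(cld_objective(obs, obs, c(6, 15), "linear"), 0)
  # single-point range, one decade apart -> 1 squared log10 residual
  a <- cld(10, 1); b <- cld(10, 0.1)
  expect_equal(cld_objective(a, b, c(10, 10), "log10"), 1)
  # brute-force loop oracle
  brute <- 0
  for (i in seq_along(obs$dp))
    brute <- brute + (log10(obs$abundance[i]) - log10(mod$abundance[i]))^2
  expect_equal(cld_objective(obs, mod, c(6, 15), "log10"), brute)
  brute_lin <- sum((obs$abundance - mod$abundance)^2)
  expect_equal(cld_objective(obs, mod, c(6, 15), "linear"), brute_lin)
  # zero abundance inside a log-scale range names the DP
  z <- cld(6:15, c(1, 2, 0, 8, 10, 9, 7, 5, 3, 2) / 10)
  expect_error(cld_objective(z, mod, c(6, 15), "log10"), "DP 8",
               class = "amylocld_validation_error")
})

test_that("competing-range fit round-trips a noiseless two-set CLD", {
  sets <- list(enzyme_set(0.12, 6, 7), enzyme_set(0.06, 9, 14))
  ss <- amylocld:::solve_steady_state(sets, xmax = 110L)
  obs <- cld(6:100, ss$cld$abundance[6:100])
  fit <- fit_competing_range(obs, small_fit_config())
  ints <- unlist(lapply(fit$sets, function(s)
    c(s$constraints$x0, s$constraints$xmin)))
  expect_identical(as.integer(ints), c(6L, 7L, 9L, 14L))
  beta <- vapply(fit$sets, `[[`, numeric(1), "beta")
  expect_lt(max(abs(beta - c(0.12, 0.06)) / c(0.12, 0.06)), 1e-3)
  expect_lt(fit$sse, 1e-12)
  # gamma reported on the surface, never free
  expect_equal(fit$gamma, solve_gamma(fit$sets), tolerance = 1e-12)
})

test_that("fits are deterministic and degenerate ranges are rejected", {
  fx <- make_rice_like_fixture(seed = 3, noise_cv = 0.01)
  cfg <- small_fit_config()
  f1 <- fit_competing_range(fx$cld, cfg)
  f2 <- fit_competing_range(fx$cld, cfg)
  expect_identical(f1$sse, f2$sse)
  expect_identical(vapply(f1$sets, `[[`, numeric(1), "beta"),
                   vapply(f2$sets, `[[`, numeric(1), "beta"))
  expect_error(fit_competing_range(fx$cld, cfg, range = c(6, 10)),
               "at least 10", class = "amylocld_validation_error")
})

test_that("independent model at h = 0 reduces to the single-set model", {
  dp <- 6:40
  m1 <- amylocld:::independent_model_values(c(6, 7, 9, 14), c(0.1, 0.05),
                                            0, 110L, dp)
  s1 <- amylocld:::solve_steady_state(list(enzyme_set(0.1, 6, 7)),
                                      xmax = 110L)
  expect_identical(m1, s1$cld$abundance[dp])
})

test_that("independent-substrate fit recovers h(ii/i) on its own synthetic", {
  spec <- synthetic_spec(
    sl_sets = list(enzyme_set(0.15, 6, 7), enzyme_set(0.05, 9, 14)),
    tl_sets = NULL, h_iii_over_i = 0, tl_start = 32L, noise_cv = 0,
    model = "independent", h_ii_over_i = 0.3, seed = 1L)
  obs <- generate_cld(spec)$cld
  fit <- fit_independent_range(obs, small_fit_config(model = "independent"))
  ints <- unlist(lapply(fit$sets, function(s)
    c(s$constraints$x0, s$constraints$xmin)))
  expect_identical(as.integer(ints), c(6L, 7L, 9L, 14L))
  expect_lt(abs(fit$h_ii_over_i - 0.3) / 0.3, 0.05)
  # each set lies on its own single-set steady state
  expect_equal(fit$gammas[1], solve_gamma(fit$sets[1]), tolerance = 1e-10)
  expect_equal(fit$gammas[2], solve_gamma(fit$sets[2]), tolerance = 1e-10)
})

test_that("TL start detection follows the three-consecutive-DP rule", {
  sl <- amylocld:::solve_steady_state(rice_sl_sets(c(0.12, 0.06)),
                                      xmax = 110L)$cld
  obs_same <- cld(6:100, sl$abundance[6:100])
  cfg <- fit_config()
  expect_warning(d <- detect_tl_start(obs_same, sl, cfg), "falling back")
  expect_identical(d, 32L)
  # bump injected from DP 32 onward -> detected at 32
  ab <- sl$abundance[6:100]
  idx <- which(6:100 >= 32)
  ab[idx] <- ab[idx] + 0.2 * max(sl$abundance[32:100])
  expect_identical(detect_tl_start(cld(6:100, ab), sl, cfg), 32L)
  # threshold 0: first DP after sl_end - 5 with any positive excess
  ab2 <- sl$abundance[6:100]
  ab2[6:100 >= 28] <- ab2[6:100 >= 28] * 1.01
  cfg0 <- fit_config(deviation_threshold = 0)
  expect_identical(detect_tl_start(cld(6:100, ab2), sl, cfg0), 28L)
})

test_that("type-2 residual is linear-space, displaced, and round-trips", {
  sl <- amylocld:::solve_steady_state(rice_sl_sets(c(0.12, 0.06)),
                                      xmax = 110L)$cld
  tl <- amylocld:::solve_steady_state(list(enzyme_set(0.1, 4, 9),
                                           enzyme_set(0.03, 8, 16)),
                                      xmax = 110L)$cld
  h <- 0.02; start <- 32L
  comp <- compose_overall(sl, tl, h, start)
  obs <- cld(6:100, amylocld:::cld_at(comp, 6:100))
  res <- extract_type2_residual(obs, sl, start)
  # linear-abundance subtraction reproduces the injected TL component
  expect_equal(res$abundance,
               h * tl$abundance[res$dp], tolerance = 1e-10)
  expect_equal(attr(res, "orig_dp"), res$dp + start - 1L)
  expect_equal(compute_h_ratio(res), h, tolerance = 1e-10)
  # no TL component: obs at or below the SL model everywhere
  expect_null(extract_type2_residual(
    cld(6:100, sl$abundance[6:100]), sl, start))
  expect_identical(compute_h_ratio(NULL), 0)
  # h = 0 composition returns the SL model unchanged
  expect_cld_equal(compose_overall(sl, tl, 0, start),
                   cld(sl$dp, sl$abundance))
})

test_that("composition adds number distributions, not their logarithms", {
  sl <- cld(1:50, exp(-(1:50) / 8))
  tl <- cld(1:10, c(1:5, 5:1) / 5)
  comp <- compose_overall(sl, tl, 0.1, 30L)
  manual <- exp(-(1:50) / 8)
  manual[30:39] <- manual[30:39] + 0.1 * c(1:5, 5:1) / 5
  expect_equal(amylocld:::cld_at(comp, 1:50), manual, tolerance = 1e-12)
})

test_that("full pipeline recovers all 13 parameters from a noiseless fixture", {
  cache <- cached_noiseless_fit()
  fx <- cache$fx
  fit <- cache$fit
  p <- amylocld:::fit_parameters(fit)
  expect_identical(unname(p[c("x0_i", "xmin_i", "x0_ii", "xmin_ii")]),
                   c(6, 7, 9, 14))
  expect_identical(unname(p[c("x0_iii", "xmin_iii", "x0_iv", "xmin_iv")]),
                   c(4, 9, 8, 16))
  reals <- p[c("beta_i", "beta_ii", "beta_iii", "beta_iv", "h_iii_over_i")]
  truth_reals <- c(0.12, 0.06, 0.10, 0.03, 0.02)
  expect_lt(max(abs(reals - truth_reals) / truth_reals), 0.05)
  # composition then re-extraction round-trips the TL component
  res <- extract_type2_residual(
    cld(fit$residuals$dp, fit$residuals$composed),
    fit$sl$model, fit$tl_start_used)
  expect_equal(max(res$abundance), fit$h_iii_over_i, tolerance = 1e-9)
})

test_that("a single three-set competing operator cannot mimic the two-tier CLD", {
  # three sets in one substrate-competing operator, the TL-like set carrying
  # a long minimum transfer length: the long-DP shoulder is not reproduced
  fx <- cached_noiseless_fit()$fx
  obs <- normalize_cld(fx$cld)
  sets3 <- list(enzyme_set(0.12, 6, 7), enzyme_set(0.06, 9, 14),
                enzyme_set(0.054, 4, 40))
  ss3 <- amylocld:::solve_steady_state(sets3, xmax = 110L)
  sse3 <- cld_objective(obs, ss3$cld, c(32, 67), "log10")
  fit <- cached_noiseless_fit()$fit
  comp <- normalize_cld(fit$model_cld)
  sse2 <- cld_objective(obs, comp, c(32, 67), "log10")
  expect_gt(sse3, 10 * sse2)
})
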