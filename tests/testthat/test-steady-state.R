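# steady_state: gamma solving and the steady-state surface

test_that("solve_gamma places the system exactly on the surface", {
  g <- solve_gamma(rice_sl_sets())
  sys <- kinetic_system(rice_sl_sets(), gamma = g, xmax = 110)
  expect_lt(abs(leading_eigenvalue(sys)), 1e-8)

  # fast Hessenberg path agrees with the dense eigen oracle
  ge <- solve_gamma(rice_sl_sets(), method = "eigen")
  expect_lt(abs(g - ge), 1e-10)

  # monotone in beta(i): more branching needs more debranching to balance
  g_hi <- solve_gamma(rice_sl_sets(c(0.05, 0.02)))
  g_lo <- solve_gamma(rice_sl_sets(c(0.02, 0.02)))
  expect_gt(g_hi, g_lo)

  # all beta zero: nothing for debranching to balance
  expect_error(solve_gamma(list(enzyme_set(0, 6, 7), enzyme_set(0, 9, 14))),
               "no steady state",
               class = "amylocld_no_steady_state_error")
})

test_that("gamma shifts the whole spectrum rigidly (uniform debranching)", {
  sets <- rice_sl_sets()
  l0 <- leading_eigenvalue(kinetic_system(sets, gamma = 0, xmax = 80))
  for (g in c(0.01, 0.05, 0.2)) {
    lg <- leading_eigenvalue(kinetic_system(sets, gamma = g, xmax = 80))
    expect_equal(lg, l0 - g, tolerance = 1e-10)
  }
  # no chain creation: leading eigenvalue strictly negative for any gamma
  none <- kinetic_system(enzyme_set(0, 6, 7), gamma = 0.01, xmax = 40)
  expect_lt(leading_eigenvalue(none), 0)
})

test_that("solved gamma is insensitive to doubling the DP truncation", {
  g110 <- solve_gamma(rice_sl_sets(c(0.1, 0.05)), xmax = 110)
  g220 <- solve_gamma(rice_sl_sets(c(0.1, 0.05)), xmax = 220)
  expect_lt(abs(g110 - g220), 1e-6)
})

test_that("surface: slice at beta2 = 0 equals the single-set line", {
  b1 <- c(0.02, 0.05, 0.1)
  s <- steady_state_surface(sbe_constraints(6, 7), sbe_constraints(9, 14),
                            beta1 = b1, beta2 = c(0, 0.02), xmax = 80)
  single <- vapply(b1, function(b)
    solve_gamma(list(enzyme_set(b, 6, 7)), xmax = 80), numeric(1))
  expect_equal(s$gamma[, 1], single, tolerance = 1e-12)

  # a 2 x 2 grid decomposes into 4 independent solves, bitwise
  s2 <- steady_state_surface(sbe_constraints(6, 7), sbe_constraints(9, 14),
                             beta1 = c(0.02, 0.05), beta2 = c(0.01, 0.03),
                             xmax = 80)
  for (i in 1:2) for (j in 1:2) {
    sets <- list(enzyme_set(c(0.02, 0.05)[i], 6, 7),
                 enzyme_set(c(0.01, 0.03)[j], 9, 14))
    expect_identical(s2$gamma[i, j], solve_gamma(sets, xmax = 80))
  }
})

test_that("surface is steeper in beta(i) than in beta(ii) at rice constraints", {
  d <- 1e-4; b <- c(0.05, 0.02)
  g <- function(b1, b2) solve_gamma(rice_sl_sets(c(b1, b2)))
  slope1 <- (g(b[1] + d, b[2]) - g(b[1] - d, b[2])) / (2 * d)
  slope2 <- (g(b[1], b[2] + d) - g(b[1], b[2] - d)) / (2 * d)
  expect_gt(slope1, slope2)
  expect_gt(slope2, 0) # still increasing in beta(ii)
})

test_that("surface shape is retained across constraint quadruples", {
  quads <- list(c(6, 7, 9, 14), c(2, 10, 6, 10), c(7, 9, 6, 7))
  for (q in quads) {
    s <- steady_state_surface(sbe_constraints(q[1], q[2]),
                              sbe_constraints(q[3], q[4]),
                              beta1 = c(0.02, 0.05, 0.1),
                              beta2 = c(0.02, 0.05, 0.1), xmax = 60)
    expect_true(all(is.finite(s$gamma)))
    expect_true(all(s$gamma >= 0))
    expect_true(all(apply(s$gamma, 2, diff) > 0)) # increasing in beta1
    expect_true(all(apply(s$gamma, 1, diff) > 0)) # increasing in beta2
  }
})

test_that("surface export round-trips through TSV with JSON metadata", {
  s <- steady_state_surface(sbe_constraints(6, 7), sbe_constraints(9, 14),
                            beta1 = c(0.02, 0.05), beta2 = c(0.01, 0.03),
                            xmax = 60)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  long <- write_surface(s, tsv_path = tsv, json_path = js)
  back <- utils::read.delim(tsv)
  expect_equal(back$gamma, long$gamma, tolerance = 1e-12)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$constraints$x0_i, 6)
  expect_equal(meta$xmax, 60)
  expect_error(steady_state_surface(sbe_constraints(6, 7),
                                    sbe_constraints(9, 14),
                                    beta1 = numeric(0)),
               class = "amylocld_validation_error")
})
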