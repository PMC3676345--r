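# model_core: branching kernel, evolution operator, eigensystem, steady
# state and time evolution

test_that("branching kernel honours the X0/Xmin eligibility step", {
  op <- build_branching_kernel(sbe_constraints(6, 7), beta = 0.3, xmax = 40)
  # X = 12 < X0 + Xmin = 13: not a substrate, whole column zero
  expect_true(all(op$matrix[, 12] == 0))
  # X = 13: single admissible cleavage -> fragment 7 + stub 6
  expect_equal(op$matrix[7, 13], 0.3)
  expect_equal(op$matrix[6, 13], 0.3)
  expect_equal(op$matrix[13, 13], -0.3)
  expect_equal(sum(op$matrix[, 13] != 0), 3)
  # X = 15: three admissible positions, fragments {7,8,9}, stubs {6,7,8}
  b3 <- 0.3 / 3
  expect_equal(op$matrix[9, 15], b3)
  expect_equal(op$matrix[6, 15], b3)
  expect_equal(op$matrix[7, 15], 2 * b3) # fragment 7 and stub 7
  expect_equal(op$matrix[8, 15], 2 * b3)
  expect_error(build_branching_kernel(sbe_constraints(6, 7), 0.1, xmax = 12),
               "no eligible substrate",
               class = "amylocld_validation_error")
})

test_that("branching kernel equals the exhaustive cleavage enumeration", {
  for (cs in list(c(6, 7), c(9, 14), c(2, 4))) {
    op <- build_branching_kernel(sbe_constraints(cs[1], cs[2]), 0.17, 60)
    expect_equal(op$matrix,
                 branching_kernel_oracle(cs[1], cs[2], 0.17, 60),
                 tolerance = 1e-14)
  }
})

test_that("branching conserves monomers and creates one chain per event", {
  xmax <- 110
  op <- build_branching_kernel(sbe_constraints(6, 7), beta = 0.2, xmax = xmax)
  K <- op$matrix
  for (X in seq_len(xmax)) {
    gains <- K[, X]; gains[X] <- 0
    if (X >= 13) {
      expect_equal(sum(gains), 2 * 0.2)          # two product chains
      expect_equal(sum(seq_len(xmax) * gains), X * 0.2) # glucose conserved
      expect_equal(sum(K[, X]), 0.2)             # net +1 chain per event
    } else {
      expect_true(all(K[, X] == 0))
    }
  }
})

test_that("evolution operator satisfies the per-column loss identity", {
  # single set, beta = gamma = 0: pure elongation bidiagonal
  sys0 <- kinetic_system(enzyme_set(0, 6, 7), gamma = 0, xmax = 30)
  op0 <- build_evolution_operator(sys0)
  expect_equal(diag(op0$matrix), c(rep(-1, 29), 0))
  expect_equal(op0$matrix[cbind(2:30, 1:29)], rep(1, 29))
  expect_equal(sum(op0$matrix != 0), 58) # 29 subdiagonal + 29 diagonal
  # triangular: spectrum is the diagonal; the simple zero at the Xmax bin is
  # numerically robust (the -1 cluster forms one defective block)
  expect_lt(abs(leading_eigenvalue(sys0)), 1e-10)

  # rice constraints, beta > 0, gamma > 0: loss identity for every column
  sys <- kinetic_system(rice_sl_sets(), gamma = 0.031, xmax = 110)
  op <- build_evolution_operator(sys)
  X <- seq_len(110)
  expected_loss <- (X < 110) + 0.031 +
    0.05 * (X >= 13) + 0.02 * (X >= 23)
  gains <- op$matrix; diag(gains) <- 0
  loss <- colSums(gains) - colSums(op$matrix)
  expect_equal(loss, expected_loss, tolerance = 1e-12)
})

test_that("operator kernels account chains: branch +1, debranch -1, elongate 0", {
  sys <- kinetic_system(rice_sl_sets(c(0.05, 0.02)), gamma = 0.04, xmax = 60)
  op <- build_evolution_operator(sys)
  cs <- colSums(op$matrix)
  X <- seq_len(60)
  # column sum = total branching rate (chain creation) - gamma (removal);
  # elongation contributes zero everywhere (including the Xmax boundary)
  expect_equal(cs, 0.05 * (X >= 13) + 0.02 * (X >= 23) - 0.04,
               tolerance = 1e-12)
})

test_that("eigensystem reconstructs initial conditions and flags steady state", {
  sys <- kinetic_system(rice_sl_sets(), gamma = 0.02, xmax = 50)
  op <- build_evolution_operator(sys)
  n0 <- cld(6, 1)
  e <- eigensystem(op, n0 = n0)
  v <- numeric(50); v[6] <- 1
  expect_lt(max(Mod(e$vectors %*% e$coefficients - v)), 1e-10)
  expect_equal(order(Re(e$lambdas), decreasing = TRUE), seq_len(50))

  # on-surface system: exactly one (near-)zero eigenvalue, rest negative
  sysS <- rice_on_surface_system()
  eS <- eigensystem(build_evolution_operator(sysS))
  expect_lt(abs(Re(eS$lambdas[1])), 1e-8)
  expect_lt(Re(eS$lambdas[2]), 0)
})

test_that("steady_state_cld returns the positive null eigenvector", {
  sys <- rice_on_surface_system()
  ss <- steady_state_cld(sys)
  expect_identical(ss$norm, "max1")
  expect_true(all(ss$abundance >= 0))
  # support begins at the smallest X0/Xmin in the system (= 6 for rice)
  expect_equal(min(ss$dp[ss$abundance > 1e-9 * max(ss$abundance)]), 6)
  expect_true(all(ss$abundance[6:110] > 0))
  expect_true(all(ss$abundance[1:5] == 0))

  # over-debranched system decays: informative error reporting Re(lambda1)
  bad <- kinetic_system(rice_sl_sets(), gamma = sys$gamma + 0.05, xmax = 110)
  err <- tryCatch(steady_state_cld(bad), error = identity)
  expect_s3_class(err, "amylocld_no_steady_state_error")
  expect_match(conditionMessage(err), "-0\\.0", all = FALSE)
})

test_that("steady state agrees with long-time power iteration", {
  sys <- rice_on_surface_system()
  op <- build_evolution_operator(sys)
  v <- rep(1, 110) # arbitrary positive start
  M <- diag(110) + 0.2 * op$matrix
  for (i in 1:4000) { v <- M %*% v; v <- v / max(v) }
  ss <- steady_state_cld(sys)
  expect_lt(amylocld:::tv_distance(as.numeric(v), ss$abundance), 1e-8)
})

test_that("time_evolve matches an adaptive ODE integration of dN/dt = Omega N", {
  skip_if_not_installed("deSolve")
  sys <- kinetic_system(rice_sl_sets(), gamma = 0.03, xmax = 40)
  op <- build_evolution_operator(sys)
  n0 <- cld(c(6, 10), c(1, 0.5))
  v0 <- numeric(40); v0[c(6, 10)] <- c(1, 0.5)
  sol <- deSolve::ode(v0, times = c(0, 1, 10, 100),
                      func = function(t, y, p) list(op$matrix %*% y),
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  for (k in 2:4) {
    t <- c(0, 1, 10, 100)[k]
    got <- time_evolve(sys, n0, t)
    expect_equal(got$abundance, pmax(sol[k, -1], 0), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # t = 0 returns n0 exactly (on the full DP axis)
  at0 <- time_evolve(sys, n0, 0)
  expect_equal(amylocld:::cld_at(at0, c(6, 10)), c(1, 0.5), tolerance = 1e-10)
  expect_lt(max(at0$abundance[-c(6, 10)]), 1e-10)
  expect_error(time_evolve(sys, n0, -1), class = "amylocld_validation_error")
})

test_that("on-surface time evolution converges to the steady-state CLD", {
  sys <- rice_on_surface_system()
  n0 <- cld(10, 1)
  lt <- time_evolve(sys, n0, 400)
  ss <- steady_state_cld(sys)
  expect_lt(amylocld:::tv_distance(lt$abundance, ss$abundance), 1e-6)
})
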