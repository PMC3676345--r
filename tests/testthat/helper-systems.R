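# shared fixtures: all built in code, nothing read from disk

rice_sl_sets <- function(beta = c(0.05, 0.02)) {
  list(enzyme_set(beta[1], 6, 7, "(i)"),
       enzyme_set(beta[2], 9, 14, "(ii)"))
}

rice_on_surface_system <- function(beta = c(0.05, 0.02), xmax = 110L) {
  sets <- rice_sl_sets(beta)
  kinetic_system(sets, gamma = solve_gamma(sets, xmax = xmax), xmax = xmax)
}

# brute-force enumeration oracle for the branching kernel: loops over every
# admissible cleavage site, independent of the matrix construction code
branching_kernel_oracle <- function(x0, xmin, beta, xmax) {
  A <- matrix(0, xmax, xmax)
  for (X in seq_len(xmax)) {
    if (X < x0 + xmin) next
    sites <- 0
    for (k in seq_len(X)) if (k >= xmin && (X - k) >= x0) sites <- sites + 1
    A[X, X] <- A[X, X] - beta
    for (k in seq_len(X)) {
      if (k >= xmin && (X - k) >= x0) {
        A[k, X] <- A[k, X] + beta / sites
        A[X - k, X] <- A[X - k, X] + beta / sites
      }
    }
  }
  A
}

# small reduced-grid config so unit tests of the search stay fast; the full
# default grids are exercised in the acceptance suite
small_fit_config <- function(...) {
  fit_config(x0_grid = 4:10, xmin_grid = 5:16, shortlist = 1200L,
             refine_top = 20L, ...)
}

# one shared noiseless small-grid pipeline fit, computed on first use
.fit_cache <- new.env(parent = emptyenv())
cached_noiseless_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    fx <- make_rice_like_fixture(seed = 1, noise_cv = 0)
    .fit_cache$fx <- fx
    .fit_cache$fit <- fit_cld(fx$cld, small_fit_config(tl_start = 32L))
  }
  list(fx = .fit_cache$fx, fit = .fit_cache$fit)
}

expect_cld_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$dp, b$dp)
  expect_equal(a$abundance, b$abundance, tolerance = tol)
}
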