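# Closed-form oracles for the reaction-diffusion solver.

test_that("no reaction gives the uniform profile and zero metabolic rate", {
  pr <- solve_profile(500e-6, 0, stem_params)
  expect_equal(pr$conc, rep(stem_params$c0, length(pr$grid)))
  expect_equal(as.numeric(metabolic_rate(pr, stem_params)), 0)
  expect_equal(nonviable_fraction(pr), 0)
})

test_that("first-order limit reproduces the classical effectiveness factor", {
  # c0 << k_M: eta(phi1) = (3/phi1^2)(phi1 coth phi1 - 1)
  p <- kinetic_params(socr_mean = 1e-17, k_M = 200, c0 = 0.2)
  kappa <- p$k_M / p$c0
  for (phi1 in c(0.5, 2, 5, 20)) {
    s <- spheroscale:::solve_dimensionless(phi1^2 * kappa, p)
    eta_exact <- 3 / phi1^2 * (phi1 / tanh(phi1) - 1)
    expect_lt(abs(s$eta / eta_exact - 1), 0.005)
  }
})

test_that("zeroth-order limit reproduces the parabolic profile", {
  # c0 >> k_M, no anoxic core: c0 - c(0) = A R^2 / (6 D), i.e. u0 = 1-phi2/6
  p <- kinetic_params(socr_mean = 1e-17, k_M = 2e-7, c0 = 0.2)
  for (phi2 in c(1.2, 3, 5)) {
    s <- spheroscale:::solve_dimensionless(phi2, p)
    expect_equal(s$u[1], 1 - phi2 / 6, tolerance = 0.01)
  }
})

test_that("zeroth-order anoxic core matches the piecewise closed form", {
  p <- kinetic_params(socr_mean = 1e-17, k_M = 2e-7, c0 = 0.2)
  u_crit <- 1e-3
  for (xc in c(0.3, 0.5, 0.7)) {
    phi2 <- 6 / (1 - 3 * xc^2 + 2 * xc^3)
    s <- spheroscale:::solve_dimensionless(phi2, p, u_crit = u_crit)
    # analytic profile u(x) = (phi2/6)(x^2 - 3 xc^2 + 2 xc^3 / x), x >= xc;
    # oracle inverts it at the threshold concentration
    ua <- function(x) (phi2 / 6) * (x^2 - 3 * xc^2 + 2 * xc^3 / x)
    x_oracle <- uniroot(function(x) ua(x) - u_crit, c(xc, 1),
                        tol = 1e-12)$root
    expect_lt(abs(s$x_crit / x_oracle - 1), 0.01)
    expect_lt(abs(s$eta / (1 - xc^3) - 1), 0.01)
  }
})

test_that("surface-flux and volume-integral metabolic rates agree", {
  set.seed(31)
  for (i in 1:8) {
    R <- 10^runif(1, -4.5, -2.4)
    socr <- stem_params$socr_mean * runif(1, 0.5, 1.8)
    pr <- solve_profile(R, socr, stem_params)
    B <- metabolic_rate(pr, stem_params)
    expect_lt(abs(attr(B, "B_flux") / as.numeric(B) - 1), 1e-3)
    # rate never exceeds uptake at saturating oxygen
    expect_lte(as.numeric(B),
               socr * stem_params$rho_c * 4 / 3 * pi * R^3 * 1.0001)
    expect_true(pr$conc[length(pr$conc)] == stem_params$c0)
    expect_true(all(diff(pr$conc) > -1e-9))
  }
})

test_that("reaction-limited limit is isometric: B -> uptake at c0", {
  # phi2 <= 0.01: B within 1% of socr rho_c (c0/(kM+c0)) (4/3) pi R^3
  socr <- stem_params$socr_mean
  R <- sqrt(0.01 * stem_params$D * stem_params$c0 /
            (socr * stem_params$rho_c))
  pr <- solve_profile(R, socr, stem_params)
  B <- as.numeric(metabolic_rate(pr, stem_params))
  B_iso <- socr * stem_params$rho_c *
    (stem_params$c0 / (stem_params$k_M + stem_params$c0)) *
    4 / 3 * pi * R^3
  expect_lt(abs(B / B_iso - 1), 0.01)
})

test_that("B increases and Phi is nondecreasing with radius", {
  socr <- stem_params$socr_mean
  R <- ladder_um * 1e-6
  out <- vapply(R, function(r) {
    pr <- solve_profile(r, socr, stem_params)
    c(as.numeric(metabolic_rate(pr, stem_params)), nonviable_fraction(pr))
  }, numeric(2))
  expect_true(all(diff(out[1, ]) > 0))
  expect_true(all(diff(out[2, ]) > -1e-9))
})

test_that("mesh refinement is converged: doubling changes B by < 0.05%", {
  p <- stem_params
  phi2 <- p$socr_mean * p$rho_c * (800e-6)^2 / (p$D * p$c0)
  s1 <- spheroscale:::solve_dimensionless(phi2, p, n0 = 200)
  s2 <- spheroscale:::solve_dimensionless(phi2, p, n0 = 400)
  expect_lt(abs(s1$eta / s2$eta - 1), 5e-4)
})

test_that("lookup-accelerated population solve matches direct solves", {
  pop <- build_population(size_spec(11, ladder_um[11], q2 = 0.01,
                                    n_samples = 100),
                          stem_params, seed = 13)
  sol <- solve_population(pop, stem_params, lookup = get_lookup(stem_params),
                          audit_n = 100)
  expect_lt(attr(sol, "audit_max_dev"), 0.005)
  # direct path agrees too
  sol_d <- solve_population(pop, stem_params, method = "direct")
  expect_equal(sol$B, sol_d$B, tolerance = 0.005)
  expect_equal(sol$phi, sol_d$phi, tolerance = 0.02)
})

test_that("large spheroids are mostly nonviable", {
  pop <- build_population(size_spec(17, 5000, q2 = 0.01, n_samples = 200),
                          stem_params, seed = 3)
  sol <- solve_population(pop, stem_params, lookup = get_lookup(stem_params))
  expect_gt(mean(sol$phi > 10), 0.5)
})

test_that("Hill kinetics is available and reduces sensibly", {
  p <- cell_type_params("stem", kinetic_law = "hill", hill_n = 1)
  pr_mm <- solve_profile(400e-6, p$socr_mean, stem_params)
  pr_h <- solve_profile(400e-6, p$socr_mean, p)
  # Hill with n = 1 is Michaelis-Menten
  expect_equal(as.numeric(metabolic_rate(pr_h, p)),
               as.numeric(metabolic_rate(pr_mm, stem_params)),
               tolerance = 1e-6)
})

test_that("solver failure carries diagnostic context", {
  err <- spheroscale:::solver_failure("test", 25, stem_params,
                                      R = 1e-3, socr = 1e-17)
  expect_s3_class(err, "spheroscale_solver_failure")
  expect_match(conditionMessage(err), "Thiele")
})
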