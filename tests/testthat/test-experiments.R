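# Meta-experiments: plateau detection, variability sweep, sensitivity.

test_that("plateau detector finds the stabilization point", {
  mins <- cbind(f = c(5, 3, 1.2, 1.05, 1.0, 0.98))
  n <- c(25, 50, 100, 200, 400, 1000)
  # 1.2 is 22% above the final 0.98, 1.05 is within 10%: onset at N = 200
  expect_equal(spheroscale:::plateau_point(n, mins, tol = 0.1), 200)
  # flat curve plateaus at the first ladder point
  expect_equal(spheroscale:::plateau_point(n, cbind(rep(1, 6)), tol = 0.1),
               25)
  # still-moving curve: only the terminal point is in-band
  expect_equal(spheroscale:::plateau_point(
    n, cbind(c(5, 4, 3, 2, 1.5, 1)), tol = 0.1), 1000)
  # dips below the band also break stability (two-sided band)
  expect_equal(spheroscale:::plateau_point(
    n, cbind(c(5, 1.0, 0.8, 1.0, 0.99, 1.0)), tol = 0.1), 200)
})

test_that("degenerate zero-variability ladder plateaus immediately", {
  p <- cell_type_params("stem", socr_sd_frac = 0)
  pc <- min_n_analysis(ladder_um[8:10], p, n_ladder = c(10, 20, 40),
                       mode = "marginal", q2 = 0, seed = 1,
                       lookup = get_lookup(stem_params))
  expect_equal(attr(pc, "plateau_n"), 10)
  expect_equal(pc$f_dis, rep(0, 3), tolerance = 1e-12)
})

test_that("marginal functional minima trend downward with N", {
  pc <- min_n_analysis(ladder_um[9:11], stem_params,
                       n_ladder = c(25, 100, 400, 2000),
                       mode = "marginal", seed = 2,
                       lookup = get_lookup(stem_params))
  expect_lt(pc$f_dis[4], pc$f_dis[1])
  expect_lt(pc$f_res[4], pc$f_res[1])
})

test_that("variability sweep degenerates correctly and is monotone", {
  sw <- variability_sweep(ladder_um[8:10], stem_params,
                          n_samples = 3000, seed = 3,
                          lookup = get_lookup(stem_params),
                          intervals = FALSE, tests = FALSE)
  expect_equal(nrow(sw), 3)
  # zero-variability row: exact solve, gamma exactly 1
  expect_equal(sw$gamma_hat[1], 1)
  expect_equal(sw$g_min[1], 0)
  # delta decreases as variability grows, on matched seeds (allow an
  # estimator-noise margin at this desk-scale N; the paired strict check
  # runs at full scale in the acceptance suite)
  expect_lte(sw$delta_hat[3], sw$delta_hat[1] + 0.02)
})

test_that("zero perturbation leaves the sensitivity baseline unchanged", {
  sens <- sensitivity_analysis(ladder_um[9:11], stem_params,
                               perturbation_frac = 0,
                               parameters = c("socr_mean", "D"),
                               n_samples = 100, seed = 4)
  expect_equal(sens$shift, rep(0, nrow(sens)), tolerance = 1e-9)
})

test_that("sensitivity shift direction matches the dimensionless reduction", {
  # socr_mean and D enter only through phi2 = sOCR rho_c R^2/(D c0):
  # +5% sOCR and -5% D (approximately) displace the window identically
  sens <- sensitivity_analysis(ladder_um[9:11], stem_params,
                               perturbation_frac = 0.05,
                               parameters = c("socr_mean", "rho_c"),
                               n_samples = 200, seed = 5)
  # sOCR and rho_c enter phi2 identically: paired shifts must match closely
  up <- sens[sens$direction == 1, ]
  expect_equal(up$delta_hat[up$parameter == "socr_mean"],
               up$delta_hat[up$parameter == "rho_c"], tolerance = 0.02)
})
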