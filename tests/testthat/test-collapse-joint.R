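# Joint collapse: functional, optimizer, validation gates.

test_that("gamma = delta = 0 leaves raw axes", {
  set.seed(41)
  m <- rlnorm(500, -20, 0.3)
  B <- m^0.8 * rlnorm(500, 0, 0.2)
  lp <- rescale_joint(m, B, mean_mass = 1e-9, gamma = 0, delta = 0)
  expect_true(all(lp[, 1] >= log10(min(m)) - 1e-9))
  expect_true(all(lp[, 1] <= log10(max(m)) + 1e-9))
})

test_that("identical distributions give g ~ 0 at every exponent pair", {
  set.seed(42)
  s <- data.frame(mass = rlnorm(500, -20, 0.3))
  s$B <- s$mass^0.8 * rlnorm(500, 0, 0.2)
  attr(s, "mean_mass") <- 1e-9
  for (gd in list(c(1, 0.8), c(0.9, 1.1)))
    expect_equal(g_joint(gd[1], gd[2], list(s, s)), 0, tolerance = 1e-12)
})

test_that("g is invariant to relabeling and common mass rescale", {
  sols <- scaling_triplet(0.8, n = 2000, seed = 43)
  sols_s <- lapply(sols, function(s) {
    s2 <- s
    s2$mass <- s$mass * 50
    s2$B <- s$B                       # B unchanged: rigid x translation
    attr(s2, "mean_mass") <- attr(s, "mean_mass") * 50
    s2
  })
  g0 <- g_joint(1, 0.8, sols)
  expect_equal(g0, g_joint(1, 0.8, rev(sols)), tolerance = 1e-12)
  # common rescale of masses and mean masses shifts log x rigidly only when
  # gamma = 1 (x = m/<m>^gamma); check the argmin-relevant invariance
  expect_equal(g_joint(1, 0.8, sols_s), g0, tolerance = 0.05 * g0 + 1e-9)
})

test_that("joint exponents are recovered on exact synthetic scaling", {
  sols <- scaling_triplet(0.8, n = 1e4, seed = 44)
  fit <- collapse_joint(sols)
  expect_lt(abs(fit$gamma_hat - 1), 0.02)
  expect_lt(abs(fit$delta_hat - 0.8), 0.05)
  expect_lte(fit$gamma_interval[1], fit$gamma_hat)
  expect_gte(fit$gamma_interval[2], fit$gamma_hat)
  # mass marginals are self-similar by construction: gamma = 1 in interval
  expect_true(fit$gamma_interval[1] <= 1 && 1 <= fit$gamma_interval[2])
  # synthetic construction is exactly log-normal: the normality gate and the
  # mean-vector test produce ordinary (uniform-null) p-values, so assert at
  # a level the 3 x alpha chance of a true-null rejection cannot trip
  expect_true(all(fit$hz_pvalues >= 0.001))
  expect_gt(fit$meanvec_pvalue, 0.001)
})

test_that("degenerate no-variability inputs give gamma = 1 exactly", {
  mms <- c(1e-9, 2e-9, 4e-9)
  sols <- lapply(mms, function(mm) {
    s <- data.frame(distribution_index = 1, mass = rep(mm, 5),
                    B = rep(2e-3 * mm^0.93, 5))
    attr(s, "mean_mass") <- mm
    class(s) <- c("spheroid_solutions", "data.frame")
    s
  })
  fit <- collapse_joint(sols)
  expect_true(fit$degenerate)
  expect_equal(fit$gamma_hat, 1)
  expect_equal(fit$delta_hat, 0.93, tolerance = 1e-10)
})

test_that("solved populations couple mass and metabolism", {
  pop <- build_population(size_spec(10, ladder_um[10], q2 = 0.01,
                                    n_samples = 1000),
                          stem_params, seed = 45)
  sol <- solve_population(pop, stem_params,
                          lookup = get_lookup(stem_params))
  # joint law is not the product of marginals: log m and log B correlate
  ct <- cor.test(log(sol$mass), log(sol$B))
  expect_lt(ct$p.value, 1e-6)
  expect_gt(ct$estimate, 0.5)
})

test_that("marginalizing the joint rescale reproduces the marginal curve", {
  sols <- scaling_triplet(0.8, n = 5000, seed = 46)
  s <- sols[[2]]
  lp2 <- rescale_joint(s$mass, s$B, attr(s, "mean_mass"), gamma = 1,
                       delta = 0.8, bins = c(30, 30))
  lp1 <- rescale_marginal(s$B, attr(s, "mean_mass"), delta = 0.8)$curve
  # collapse the surface over the mass axis: B p(B) = int G d(ln m), i.e.
  # sum of G over x cells times the log-bin width
  wx <- diff(range(log10(s$mass))) / 30
  ys <- sort(unique(lp2[, 2]))
  gy <- vapply(ys, function(y) sum(10^lp2[abs(lp2[, 2] - y) < 1e-12, 3]),
               numeric(1)) * log(10) * wx
  # compare against the marginal curve by interpolation in log space
  ok <- ys >= min(lp1[, 1]) & ys <= max(lp1[, 1])
  yhat <- approx(lp1[, 1], lp1[, 2], xout = ys[ok], ties = mean)$y
  resid <- log10(gy[ok]) - yhat
  # agreement within binning error over the bulk of the support
  expect_lt(median(abs(resid), na.rm = TRUE), 0.15)
})

test_that("joint methods print and coef/confint behave", {
  sols <- scaling_triplet(0.85, n = 2000, seed = 47)
  fit <- collapse_joint(sols)
  expect_named(coef(fit), c("gamma", "delta"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(2, 2))
  expect_output(print(fit), "gamma")
})
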