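test_that("radius generator matches the log-normal moment targets", {
  spec <- size_spec(1, 100, q2 = 0.01, n_samples = 1e5, seed = 42)
  r <- generate_radii(spec)
  expect_equal(mean(r), 100e-6, tolerance = 0.01)
  expect_equal(sd(r) / mean(r), 0.10, tolerance = 0.05)
})

test_that("zero-variance spec degenerates to the mean radius", {
  spec <- size_spec(1, 250, q2 = 0, n_samples = 10, seed = 1)
  expect_equal(generate_radii(spec), rep(250e-6, 10))
})

test_that("q2 >= 1 is rejected as an invalid log-normal parameterization", {
  expect_error(size_spec(1, 100, q2 = 1, n_samples = 10), "q2")
})

test_that("size ladder spans 31 to 5000 um geometrically", {
  l <- size_ladder()
  expect_length(l, 17)
  expect_equal(l[1], 31)
  expect_equal(l[17], 5000)
  expect_equal(sd(diff(log(l))), 0, tolerance = 1e-12)
})

test_that("sOCR generator hits its Gaussian moments and stays positive", {
  p <- kinetic_params(socr_mean = 1e-17, socr_sd_frac = 0.2)
  x <- generate_socrs(1e5, p, seed = 7)
  expect_equal(sd(x) / mean(x), 0.20, tolerance = 0.05)
  expect_true(all(x > 0))
  expect_equal(generate_socrs(10, kinetic_params(socr_mean = 1e-17,
                                                 socr_sd_frac = 0), 1),
               rep(1e-17, 10))
})

test_that("populations satisfy the mass-radius and mean-mass contracts", {
  spec <- size_spec(3, 100, q2 = 0.01, n_samples = 500)
  pop <- build_population(spec, stem_params, seed = 5)
  # closed-form sphere volume: <m> = omega (4/3) pi <R>^3
  expect_equal(pop$mean_mass, 4.18879e-12, tolerance = 1e-5)
  expect_equal(pop$masses / pop$radii^3,
               rep(stem_params$omega * 4 / 3 * pi, 500))
  expect_length(pop$radii, 500)
  expect_length(pop$socrs, 500)
  # sample moments converge to spec moments: 3 CV / sqrt(N) band
  expect_lt(abs(mean(pop$radii) / 100e-6 - 1), 3 * 0.1 / sqrt(500))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- size_spec(1, 100, q2 = 0.01, n_samples = 100)
  p1 <- build_population(spec, stem_params, seed = 9)
  p2 <- build_population(spec, stem_params, seed = 9)
  p3 <- build_population(spec, stem_params, seed = 10)
  expect_identical(p1$radii, p2$radii)
  expect_identical(p1$socrs, p2$socrs)
  expect_false(identical(p1$radii, p3$radii))
  # radius and sOCR streams are decoupled
  expect_false(identical(order(p1$radii), order(p1$socrs)))
})

test_that("child seeds are deterministic, distinct and in range", {
  s1 <- child_seed(1, 3)
  expect_identical(s1, child_seed(1, 3))
  expect_false(s1 == child_seed(1, 4))
  expect_false(child_seed(1, 3, 2) == child_seed(1, 3, 3))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("N = 1 populations work and a 17-rung ladder builds", {
  pop <- build_population(size_spec(1, 50, q2 = 0.01, n_samples = 1),
                          stem_params, seed = 1)
  expect_length(pop$radii, 1)
  pops <- build_populations(ladder_um, stem_params, n_samples = 5, seed = 2)
  expect_length(pops, 17)
  expect_equal(vapply(pops, function(p) p$spec$index, numeric(1)), 1:17)
})
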