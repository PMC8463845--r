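# Window identification and classification.

make_sol_df <- function(mm, B, phi = 0, index = 1) {
  s <- data.frame(distribution_index = index, mass = rep(mm, length(B)),
                  B = B, phi = phi)
  attr(s, "mean_mass") <- mm
  class(s) <- c("spheroid_solutions", "data.frame")
  s
}

test_that("viability classification follows the aggregate Phi rule", {
  s_ok <- make_sol_df(1e-9, rlnorm(50, -14, 0.2), phi = 0)
  s_bad <- make_sol_df(1e-9, rlnorm(50, -14, 0.2), phi = 50)
  expect_true(classify_viability(list(s_ok, s_ok)))
  expect_false(classify_viability(list(s_ok, s_bad)))
  # borderline: mean at 9.9% passes, 10.1% fails
  s_b <- make_sol_df(1e-9, rlnorm(50, -14, 0.2), phi = 9.9)
  expect_true(classify_viability(list(s_b)))
  s_b$phi <- 10.1
  expect_false(classify_viability(list(s_b)))
  # quantile rule
  phis <- c(rep(0, 95), rep(60, 5))
  s_q <- make_sol_df(1e-9, rlnorm(100, -14, 0.2), phi = phis)
  expect_true(classify_viability(list(s_q), rule = "quantile", q = 0.9))
  expect_false(classify_viability(list(s_q), rule = "quantile", q = 0.97))
})

test_that("pure isometric synthetic ladder yields one isometric window", {
  sols <- lapply(1:5, function(i) {
    mm <- 1e-9 * 2.6^(i - 1)
    s <- make_scaling_population(mm, 400, delta0 = 1,
                                 seed = child_seed(8, i))
    s$distribution_index <- i
    s$phi <- 0
    s
  })
  wins <- find_windows(sols, mode = "marginal")
  expect_gte(length(wins$windows), 1)
  w1 <- wins$windows[[1]]
  expect_true(w1$isometric)
  expect_true(w1$viable)
  expect_false(w1$relevant)
  expect_gte(length(w1$member_indices), 3)
})

test_that("windows partition: each distribution in at most one window", {
  sols <- lapply(1:6, function(i) {
    mm <- 1e-9 * 2.6^(i - 1)
    d0 <- if (i <= 3) 1 else 0.7    # regime change forces a window break
    s <- make_scaling_population(mm, 400, delta0 = d0,
                                 seed = child_seed(9, i))
    s$distribution_index <- i
    s$phi <- 0
    s
  })
  wins <- find_windows(sols, mode = "marginal")
  members <- unlist(lapply(wins$windows, `[[`, "member_indices"))
  expect_false(any(duplicated(members)))
  for (w in wins$windows) {
    expect_gte(length(w$member_indices), 3)
    expect_true(all(diff(w$member_indices) == 1))  # consecutive rungs
    # relevance implies nonisometric and viable
    if (w$relevant) expect_true(!w$isometric && w$viable)
  }
})

test_that("window search is deterministic", {
  sols <- lapply(1:4, function(i) {
    s <- make_scaling_population(1e-9 * 2.6^(i - 1), 300, delta0 = 1,
                                 seed = child_seed(10, i))
    s$distribution_index <- i
    s$phi <- 0
    s
  })
  w1 <- find_windows(sols, mode = "marginal")
  w2 <- find_windows(sols, mode = "marginal")
  expect_identical(lapply(w1$windows, `[[`, "member_indices"),
                   lapply(w2$windows, `[[`, "member_indices"))
})

test_that("viability is monotone along the solved ladder", {
  pops <- build_populations(ladder_um, stem_params, n_samples = 300,
                            seed = 12)
  sols <- solve_populations(pops, stem_params,
                            lookup = get_lookup(stem_params))
  mphi <- vapply(sols, function(s) mean(s$phi), numeric(1))
  viable <- mphi < 10
  # once a distribution is nonviable every larger one is too
  expect_true(all(diff(viable) <= 0))
  # mean Phi itself is nondecreasing along the ladder
  expect_true(all(diff(mphi) > -1e-9))
  tab <- window_table(find_windows(sols, mode = "marginal"), sols)
  expect_equal(tab$viable, viable)
})

test_that("fewer than 3 distributions is an error", {
  s <- make_scaling_population(1e-9, 100, 1, seed = 1)
  expect_error(find_windows(list(s, s), mode = "marginal"), "at least 3")
})
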