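#' Precompute a dimensionless lookup table for fast population solves
#'
#' In dimensionless variables the oxygen problem depends only on
#' `kappa = k_M / c0` and the squared Thiele-type modulus
#' `phi2 = sOCR * rho_c * R^2 / (D * c0)`. For a fixed parameter set a 1D
#' table of effectiveness factor and critical core fraction against `phi2`
#' therefore summarizes every spheroid, making million-spheroid batches
#' feasible. Interpolation is monotone cubic in `log10(phi2)`.
#'
#' @param params A [kinetic_params()] object.
#' @param phi2_range Range of `phi2` to cover; solves outside it are clamped
#'   at the near-uniform lower end and are an error above the upper end.
#' @param points_per_decade Table resolution (default 24).
#' @return An object of class `oxygen_lookup` with interpolators
#'   `eta(phi2)` and `x_crit(phi2)`.
#' @export
build_oxygen_lookup <- function(params, phi2_range = c(1e-6, 1e8),
                                points_per_decade = 24) {
  stopifnot(inherits(params, "kinetic_params"),
            length(phi2_range) == 2, all(phi2_range > 0))
  lp <- log10(phi2_range)
  grid <- 10^seq(lp[1], lp[2],
                 length.out = ceiling(diff(lp) * points_per_decade) + 1)
  u_crit <- params$C_crit / params$c0
  eta <- numeric(length(grid))
  xc <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- solve_dimensionless(grid[i], params, u_crit = u_crit)
    eta[i] <- s$eta
    xc[i] <- s$x_crit
  }
  lg <- log10(grid)
  eta_fun <- stats::splinefun(lg, log10(eta), method = "monoH.FC")
  xc_fun <- stats::splinefun(lg, xc, method = "monoH.FC")
  structure(list(params = params, phi2_grid = grid, eta = eta, x_crit = xc,
                 .eta_fun = eta_fun, .xc_fun = xc_fun),
            class = "oxygen_lookup")
}

lookup_eval <- function(lk, phi2) {
  rng <- range(lk$phi2_grid)
  if (any(phi2 > rng[2] * (1 + 1e-9)))
    stop("oxygen_lookup: phi2 beyond the tabulated range; rebuild the ",
         "table with a larger phi2_range", call. = FALSE)
  lp <- log10(pmax(phi2, rng[1]))
  list(eta = pmin(10^lk$.eta_fun(lp), 1),
       x_crit = pmin(pmax(lk$.xc_fun(lp), 0), 1))
}

#' @export
print.oxygen_lookup <- function(x, ...) {
  cat(sprintf(
    "Oxygen lookup table: %d nodes, phi2 in [%.3g, %.3g], kappa = %.4g\n",
    length(x$phi2_grid), min(x$phi2_grid), max(x$phi2_grid),
    x$params$k_M / x$params$c0))
  invisible(x)
}

#' Solve the oxygen model for every spheroid of a population
#'
#' Computes per-spheroid metabolic rate `B` (mol/s) and nonviable volume
#' fraction `phi` (%). The default fast path evaluates a dimensionless
#' lookup table (built once per parameter set and reused when passed in) and
#' audits a random subsample against direct solves; `method = "direct"`
#' solves every spheroid individually.
#'
#' @param pop A `spheroid_population` from [build_population()].
#' @param params A [kinetic_params()] object.
#' @param method `"lookup"` (default) or `"direct"`.
#' @param lookup Optional prebuilt [build_oxygen_lookup()] table.
#' @param audit_n Number of random spheroids to re-solve directly as an
#'   accuracy audit of the lookup path (0 disables). Deviations beyond 0.5%
#'   raise a warning.
#' @param audit_seed Seed for the audit subsample.
#' @return An object of class `spheroid_solutions`: a data frame with
#'   columns `distribution_index`, `radius`, `socr`, `mass`, `B`, `phi`, and
#'   attributes `mean_mass` and `n_failed` (direct-solve failures are
#'   reported and skipped, their rows carrying `NA`).
#' @export
solve_population <- function(pop, params, method = c("lookup", "direct"),
                             lookup = NULL, audit_n = 0, audit_seed = 1L) {
  stopifnot(inherits(pop, "spheroid_population"),
            inherits(params, "kinetic_params"))
  method <- match.arg(method)
  n <- length(pop$radii)
  phi2 <- pop$socrs * params$rho_c * pop$radii^2 / (params$D * params$c0)
  fmax <- mm_rate(1, params)
  vol <- (4 / 3) * pi * pop$radii^3
  n_failed <- 0L
  if (method == "lookup") {
    if (is.null(lookup)) {
      hi <- max(phi2) * 1.5
      lookup <- build_oxygen_lookup(params,
                                    phi2_range = c(min(1e-6, max(phi2)),
                                                   max(hi, 1e-4)))
    }
    lv <- lookup_eval(lookup, phi2)
    B <- pop$socrs * params$rho_c * fmax * vol * lv$eta
    phi <- 100 * lv$x_crit^3
    if (audit_n > 0) {
      idx <- with_seed(audit_seed,
                       sample.int(n, size = min(audit_n, n)))
      dev <- vapply(idx, function(i) {
        pr <- solve_profile(pop$radii[i], pop$socrs[i], params)
        abs(as.numeric(metabolic_rate(pr, params)) / B[i] - 1)
      }, numeric(1))
      if (max(dev) > 5e-3)
        warning(sprintf(
          "lookup audit: max relative B deviation %.3g%% exceeds 0.5%%",
          100 * max(dev)))
      attr(B, "audit_max_dev") <- max(dev)
    }
  } else {
    B <- numeric(n); phi <- numeric(n)
    for (i in seq_len(n)) {
      res <- tryCatch({
        pr <- solve_profile(pop$radii[i], pop$socrs[i], params)
        c(as.numeric(metabolic_rate(pr, params)),
          nonviable_fraction(pr))
      }, spheroscale_solver_failure = function(e) {
        warning("spheroid ", i, ": ", conditionMessage(e))
        c(NA_real_, NA_real_)
      })
      if (anyNA(res)) n_failed <- n_failed + 1L
      B[i] <- res[1]; phi[i] <- res[2]
    }
  }
  audit <- attr(B, "audit_max_dev")
  out <- data.frame(distribution_index = pop$spec$index,
                    radius = pop$radii, socr = pop$socrs,
                    mass = pop$masses, B = as.numeric(B), phi = phi)
  attr(out, "mean_mass") <- pop$mean_mass
  attr(out, "n_failed") <- n_failed
  if (!is.null(audit)) attr(out, "audit_max_dev") <- audit
  class(out) <- c("spheroid_solutions", "data.frame")
  out
}

#' Solve a list of populations, sharing one lookup table
#'
#' @param pops List of `spheroid_population` objects (see
#'   [build_populations()]).
#' @inheritParams solve_population
#' @return List of `spheroid_solutions`.
#' @export
solve_populations <- function(pops, params, method = c("lookup", "direct"),
                              lookup = NULL, audit_n = 0) {
  method <- match.arg(method)
  if (method == "lookup" && is.null(lookup)) {
    hi <- max(vapply(pops, function(p) {
      max(p$socrs * params$rho_c * p$radii^2) / (params$D * params$c0)
    }, numeric(1)))
    lookup <- build_oxygen_lookup(params, phi2_range = c(1e-6, hi * 1.5))
  }
  lapply(pops, solve_population, params = params, method = method,
         lookup = lookup, audit_n = audit_n)
}
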