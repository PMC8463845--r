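#' Draw log-normally distributed spheroid radii
#'
#' Radii are log-normal with mean `<R>` and variance `q2 * <R>^2`, i.e. a
#' coefficient of variation `sqrt(q2)`. The log-normal parameters follow from
#' the moment formulas `sigma_ln^2 = log(1 + q2)` and
#' `mu_ln = log(<R>) - sigma_ln^2 / 2`. With `q2 = 0` the distribution
#' degenerates to the point mass at `<R>`.
#'
#' @param spec A [size_spec()]; its `seed` must be set (directly or via
#'   [build_population()]).
#' @return Numeric vector of radii in metres, length `spec$n_samples`.
#' @export
generate_radii <- function(spec) {
  stopifnot(inherits(spec, "size_spec"))
  if (is.null(spec$seed))
    stop("generate_radii: spec$seed is not set", call. = FALSE)
  mean_r <- spec$mean_radius_um * 1e-6
  if (spec$q2 == 0)
    return(rep(mean_r, spec$n_samples))
  sdlog2 <- log1p(spec$q2)
  meanlog <- log(mean_r) - sdlog2 / 2
  with_seed(spec$seed,
            stats::rlnorm(spec$n_samples, meanlog = meanlog,
                          sdlog = sqrt(sdlog2)))
}

#' Draw Gaussian single-cell oxygen consumption rates
#'
#' sOCR values are normal with mean `params$socr_mean` and standard deviation
#' `socr_sd_frac * socr_mean`. Non-positive draws (probability about 3e-7 at
#' a 20% CV) are resampled so every cell has a positive maximal uptake, as
#' the kinetics require; the bulk of the distribution stays exactly Gaussian.
#'
#' @param n Number of draws.
#' @param params A [kinetic_params()] object.
#' @param seed Integer seed.
#' @return Numeric vector of sOCR values (mol s^-1 cell^-1), length `n`.
#' @export
generate_socrs <- function(n, params, seed) {
  stopifnot(inherits(params, "kinetic_params"), n >= 1)
  mu <- params$socr_mean
  sd <- params$socr_sd_frac * mu
  if (sd == 0)
    return(rep(mu, n))
  with_seed(seed, {
    x <- stats::rnorm(n, mu, sd)
    while (any(bad <- x <= 0))
      x[bad] <- stats::rnorm(sum(bad), mu, sd)
    x
  })
}

#' Build one stochastic spheroid population
#'
#' Composes the radius and sOCR generators and attaches masses
#' `m = omega * (4/3) * pi * R^3`. Radii and sOCRs are generated
#' independently, which realizes the random pairing between the two sources
#' of variability. The conditioning mean mass is computed from the
#' *specified* mean radius, `<m> = omega * (4/3) * pi * <R>^3`, not from the
#' sample mean.
#'
#' @param spec A [size_spec()].
#' @param params A [kinetic_params()] object.
#' @param seed Integer seed; overrides `spec$seed` when given. The radius and
#'   sOCR streams use distinct child seeds derived from it.
#' @return An object of class `spheroid_population`: a list with fields
#'   `spec`, `radii` (m), `socrs` (mol/s/cell), `masses` (kg) and
#'   `mean_mass` (kg).
#' @export
#' @examples
#' pop <- build_population(size_spec(1, 100, q2 = 0.01, n_samples = 50),
#'                         cell_type_params("stem"), seed = 1)
#' pop$mean_mass  # 4.18879e-12 kg for <R> = 100 um, omega = 1000
build_population <- function(spec, params, seed = NULL) {
  stopifnot(inherits(spec, "size_spec"), inherits(params, "kinetic_params"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  if (is.null(spec$seed))
    stop("build_population: no seed given", call. = FALSE)
  rspec <- spec
  rspec$seed <- child_seed(spec$seed, 1L)
  radii <- generate_radii(rspec)
  socrs <- generate_socrs(spec$n_samples, params,
                          seed = child_seed(spec$seed, 2L))
  mean_r <- spec$mean_radius_um * 1e-6
  pop <- list(spec = spec,
              radii = radii,
              socrs = socrs,
              masses = params$omega * (4 / 3) * pi * radii^3,
              mean_mass = params$omega * (4 / 3) * pi * mean_r^3)
  class(pop) <- "spheroid_population"
  pop
}

#' Build populations for a whole ladder of size distributions
#'
#' @param mean_radii_um Vector of mean radii, micrometres (see
#'   [size_ladder()]).
#' @param params A [kinetic_params()] object.
#' @param n_samples Spheroids per distribution (recycled over the ladder).
#' @param q2 Second-order moment coefficient (recycled).
#' @param seed Master seed; each distribution gets the child seed
#'   `child_seed(seed, index)`.
#' @param indices Ladder indices to label the distributions with (defaults
#'   to `1:length(mean_radii_um)`); also the index each child seed is
#'   derived from, so a sub-ladder labelled with its original indices
#'   reproduces the same populations as the full ladder.
#' @return A list of `spheroid_population`, one per ladder rung.
#' @export
build_populations <- function(mean_radii_um, params, n_samples, q2 = 0.01,
                              seed, indices = seq_along(mean_radii_um)) {
  k <- length(mean_radii_um)
  stopifnot(length(indices) == k)
  n_samples <- rep_len(n_samples, k)
  q2 <- rep_len(q2, k)
  lapply(seq_len(k), function(i) {
    build_population(
      size_spec(indices[i], mean_radii_um[i], q2 = q2[i],
                n_samples = n_samples[i]),
      params, seed = child_seed(seed, indices[i]))
  })
}

#' Synthetic sample satisfying the joint scaling ansatz exactly
#'
#' Draws masses log-normally around `mean_mass` (self-similar across
#' distributions, so the mass exponent is 1 by construction) and sets
#' `B = m^delta0 * xi` with iid positive log-normal noise `xi` of unit mean.
#' The resulting family satisfies the joint scaling form with exponents
#' `(gamma, delta) = (1, delta0)` exactly, which makes it the reference
#' construction for exponent-recovery validation of the collapse estimators.
#'
#' @param mean_mass Conditioning mean mass (kg or arbitrary positive units).
#' @param n Sample size.
#' @param delta0 True metabolic scaling exponent.
#' @param q2 Size-variability coefficient; the mass log-variance is
#'   `9 * log(1 + q2)` (mass = density x volume of a log-normal radius with
#'   CV `sqrt(q2)`).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   `xi` (default 0.2, the reference single-cell metabolic variability).
#' @param seed Integer seed.
#' @return A solution-like data frame (`mass`, `B`, `phi = NA`) with a
#'   `mean_mass` attribute, ready for the collapse fitters.
#' @export
make_scaling_population <- function(mean_mass, n, delta0, q2 = 0.01,
                                    noise_cv = 0.2, seed) {
  stopifnot(mean_mass > 0, n >= 1, q2 >= 0, noise_cv >= 0)
  with_seed(seed, {
    sdm <- sqrt(9 * log1p(q2))
    m <- stats::rlnorm(n, log(mean_mass) - sdm^2 / 2, sdm)
    sdx <- sqrt(log1p(noise_cv^2))
    xi <- stats::rlnorm(n, -sdx^2 / 2, sdx)
    s <- data.frame(distribution_index = NA_integer_, mass = m,
                    B = m^delta0 * xi, phi = NA_real_)
    attr(s, "mean_mass") <- mean_mass
    class(s) <- c("spheroid_solutions", "data.frame")
    s
  })
}

#' @export
print.spheroid_population <- function(x, ...) {
  cat(sprintf(
    "Spheroid population (distribution %d): N = %d, <R> = %g um\n",
    x$spec$index, x$spec$n_samples, x$spec$mean_radius_um))
  cat(sprintf("  sample mean R = %.4g um, CV = %.3f\n",
              mean(x$radii) * 1e6, stats::sd(x$radii) / mean(x$radii)))
  cat(sprintf("  <m> = %.4g kg (from the specified mean radius)\n",
              x$mean_mass))
  invisible(x)
}

#' Export populations (and optionally solutions) as a data frame
#'
#' One row per spheroid with columns `distribution_index`, `radius_m`,
#' `mass_kg`, `socr`, and, when solutions are supplied, `B_mol_per_s` and
#' `phi_percent`.
#'
#' @param pops List of `spheroid_population`.
#' @param sols Optional list of solution data frames from
#'   [solve_population()], parallel to `pops`.
#' @return A data frame.
#' @export
population_table <- function(pops, sols = NULL) {
  rows <- lapply(seq_along(pops), function(i) {
    p <- pops[[i]]
    d <- data.frame(distribution_index = p$spec$index,
                    radius_m = p$radii, mass_kg = p$masses, socr = p$socrs)
    if (!is.null(sols)) {
      d$B_mol_per_s <- sols[[i]]$B
      d$phi_percent <- sols[[i]]$phi
    }
    d
  })
  do.call(rbind, rows)
}

#' Write / read the population table as delimited text
#'
#' Plain CSV round-trip of [population_table()] output at full double
#' precision. For very large populations prefer [saveRDS()] on the list of
#' populations (compact binary container).
#'
#' @param x Data frame from [population_table()].
#' @param path File path.
#' @export
write_population_csv <- function(x, path) {
  utils::write.csv(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_population_csv
#' @return `read_population_csv()` returns the data frame.
#' @export
read_population_csv <- function(path) {
  utils::read.csv(path)
}
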