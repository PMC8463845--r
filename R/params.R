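#' Kinetic and transport parameters for the oxygen model
#'
#' Bundles the single-cell oxygen consumption rate (sOCR) distribution, the
#' Michaelis-Menten kinetics, the transport constants and the viability
#' threshold used throughout the pipeline. All values are strict SI
#' (m, kg, mol, s); radii supplied elsewhere in micrometres are converted at
#' the interface.
#'
#' @param socr_mean Mean single-cell oxygen consumption rate
#'   (mol s^-1 cell^-1).
#' @param socr_sd_frac Standard deviation of the sOCR as a fraction of its
#'   mean (dimensionless, in `[0, 1)`). Default 0.2, i.e. a 20% coefficient
#'   of variation.
#' @param rho_c Cell density inside the spheroid (cells m^-3).
#' @param k_M Michaelis-Menten constant of the oxygen sink (mol m^-3).
#' @param D Oxygen diffusion coefficient (m^2 s^-1); the spheroid interior is
#'   treated as water-like.
#' @param c0 Oxygen concentration at the spheroid surface (mol m^-3);
#'   default is an air-saturated aqueous medium.
#' @param C_crit Critical oxygen concentration below which tissue is scored
#'   nonviable (mol m^-3).
#' @param omega Spheroid mass density (kg m^-3); water by default.
#' @param kinetic_law `"michaelis_menten"` (default) or `"hill"`.
#' @param hill_n Hill exponent, used only when `kinetic_law = "hill"`.
#'
#' @return An object of class `kinetic_params` (a validated list).
#' @seealso [cell_type_params()] for the bundled cell-type presets.
#' @export
#' @examples
#' p <- cell_type_params("stem")
#' p$socr_mean
kinetic_params <- function(socr_mean,
                           socr_sd_frac = 0.2,
                           rho_c = 1e14,
                           k_M = 0.0412,
                           D = 2e-9,
                           c0 = 0.2,
                           C_crit = 0.04,
                           omega = 1000,
                           kinetic_law = c("michaelis_menten", "hill"),
                           hill_n = 2) {
  kinetic_law <- match.arg(kinetic_law)
  p <- list(socr_mean = socr_mean, socr_sd_frac = socr_sd_frac,
            rho_c = rho_c, k_M = k_M, D = D, c0 = c0, C_crit = C_crit,
            omega = omega, kinetic_law = kinetic_law, hill_n = hill_n)
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

validate_kinetic_params <- function(p) {
  num <- c("socr_mean", "rho_c", "k_M", "D", "c0", "C_crit", "omega")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetic_params: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (p$C_crit >= p$c0)
    stop("kinetic_params: C_crit must be below the surface concentration c0",
         call. = FALSE)
  if (p$socr_sd_frac < 0 || p$socr_sd_frac >= 1)
    stop("kinetic_params: socr_sd_frac must lie in [0, 1)", call. = FALSE)
  if (p$kinetic_law == "hill" && (!is.finite(p$hill_n) || p$hill_n <= 0))
    stop("kinetic_params: hill_n must be positive", call. = FALSE)
  invisible(p)
}

#' Preset kinetic parameters for the two bundled cell phenotypes
#'
#' Returns the default parameter sets for stem-cell-laden and
#' hepatocyte-laden spheroids. Transport constants, cell density and the
#' Michaelis constant are shared between the two phenotypes; only the mean
#' sOCR differs. The sOCR means are calibrated so that the deterministic
#' (zero-variability) metabolic behaviour of the model reproduces the
#' documented reference physiology: see the methods vignette for the
#' calibration anchors and their rationale.
#'
#' @param cell_type `"stem"` or `"hepatocyte"`.
#' @param ... Overrides passed on to [kinetic_params()].
#' @return A `kinetic_params` object.
#' @export
cell_type_params <- function(cell_type = c("stem", "hepatocyte"), ...) {
  cell_type <- match.arg(cell_type)
  defaults <- switch(cell_type,
    stem       = list(socr_mean = .spheroscale_defaults$socr_stem),
    hepatocyte = list(socr_mean = .spheroscale_defaults$socr_hep))
  args <- utils::modifyList(defaults, list(...))
  do.call(kinetic_params, args)
}

# Calibrated defaults (see vignette, "Parameter mapping"): the sOCR means and
# k_M are fixed by deterministic anchors of the reference physiology, the
# remaining constants are standard literature values for aqueous media.
.spheroscale_defaults <- new.env(parent = emptyenv())
.spheroscale_defaults$socr_stem <- 5.607e-17  # mol/s/cell, set in calibration
.spheroscale_defaults$socr_hep <- 2.970e-17   # mol/s/cell, set in calibration

#' Ladder of mean spheroid radii
#'
#' The study design uses 17 size distributions whose mean radii span
#' 31 to 5000 micrometres. The exact intermediate values are generated as a
#' geometric ladder (constant ratio `(5000/31)^(1/16)`, about 1.374), which
#' can be overridden with an explicit vector.
#'
#' @param n Number of size distributions (default 17).
#' @param r_min,r_max Smallest and largest mean radius, in micrometres.
#' @return Numeric vector of mean radii in micrometres, length `n`.
#' @export
#' @examples
#' size_ladder()[c(1, 17)]  # 31 and 5000
size_ladder <- function(n = 17, r_min = 31, r_max = 5000) {
  stopifnot(n >= 2, r_min > 0, r_max > r_min)
  exp(seq(log(r_min), log(r_max), length.out = n))
}

#' Specification of one spheroid size distribution
#'
#' @param index Integer index of the distribution within the size ladder
#'   (1-based).
#' @param mean_radius_um Mean radius of the distribution, micrometres.
#' @param q2 Second-order moment coefficient: the radius variance is
#'   `q2 * mean_radius^2`, i.e. the radius coefficient of variation is
#'   `sqrt(q2)`. Default 0.01 (10% CV).
#' @param n_samples Number of spheroids to draw.
#' @param seed Integer seed for this distribution; if `NULL`, derived from a
#'   master seed at generation time.
#' @return An object of class `size_spec`.
#' @export
size_spec <- function(index, mean_radius_um, q2 = 0.01, n_samples,
                      seed = NULL) {
  stopifnot(length(index) == 1L, index >= 1,
            length(mean_radius_um) == 1L, mean_radius_um > 0,
            length(q2) == 1L, q2 >= 0,
            length(n_samples) == 1L, n_samples >= 1)
  if (q2 >= 1)
    stop("size_spec: q2 >= 1 implies a radius CV of 100% or more, outside ",
         "the valid log-normal parameterization", call. = FALSE)
  s <- list(index = as.integer(index), mean_radius_um = mean_radius_um,
            q2 = q2, n_samples = as.integer(n_samples),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(s) <- "size_spec"
  s
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (", x$kinetic_law, ")\n", sep = "")
  cat(sprintf("  sOCR: %.3g mol/s/cell (CV %.0f%%)\n",
              x$socr_mean, 100 * x$socr_sd_frac))
  cat(sprintf("  rho_c: %.3g cells/m^3, k_M: %.3g mol/m^3\n",
              x$rho_c, x$k_M))
  cat(sprintf("  D: %.3g m^2/s, c0: %.3g mol/m^3, C_crit: %.3g mol/m^3\n",
              x$D, x$c0, x$C_crit))
  cat(sprintf("  density omega: %.3g kg/m^3\n", x$omega))
  invisible(x)
}

#' @export
print.size_spec <- function(x, ...) {
  cat(sprintf(
    "Size distribution %d: <R> = %g um, q2 = %g, N = %d%s\n",
    x$index, x$mean_radius_um, x$q2, x$n_samples,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}
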