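# Meta-experiments: minimum sample size for a stable collapse, variability
# sweeps, and kinetic-parameter sensitivity.

#' Minimum-N analysis of a collapse functional
#'
#' For each N in a ladder, regenerates the window's populations with fresh
#' child seeds, solves them, optimizes the collapse, and records the
#' functional minimum. The plateau is the smallest N from which every
#' subsequent minimum (including the final one) stays within a relative
#' tolerance band of the final value.
#'
#' @param mean_radii_um Mean radii of the window members (micrometres).
#' @param params [kinetic_params()].
#' @param n_ladder Increasing vector of sample sizes (>= 3 values).
#' @param mode `"marginal"` or `"joint"`.
#' @param method Marginal collapse method, or `"both"` to track the
#'   residual- and distance-based minima simultaneously (plateau then
#'   requires both to be stable).
#' @param q2 Size variability coefficient.
#' @param seed Master seed; ladder step i uses child seed
#'   `child_seed(seed, 91, i)`.
#' @param plateau_tol Relative tolerance band (default 0.1).
#' @param lookup Optional prebuilt oxygen lookup table.
#' @param ... Passed to the collapse fitter.
#' @return An object of class `plateau_curve`: data frame of `n` and
#'   functional minima, plus attribute `plateau_n` (NA when no plateau).
#' @export
min_n_analysis <- function(mean_radii_um, params,
                           n_ladder = c(25, 50, 100, 200, 400, 1e3, 3e3,
                                        1e4, 3e4, 1e5),
                           mode = c("marginal", "joint"),
                           method = c("both", "distance", "residual"),
                           q2 = 0.01, seed = 1, plateau_tol = 0.1,
                           lookup = NULL, ...) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(length(n_ladder) >= 3, !is.unsorted(n_ladder))
  if (is.null(lookup)) {
    hi <- max(mean_radii_um * 1e-6)^2 * (1.6)^2 *
      params$socr_mean * (1 + 6 * params$socr_sd_frac) * params$rho_c /
      (params$D * params$c0)
    lookup <- build_oxygen_lookup(params, phi2_range = c(1e-6, hi * 2))
  }
  cols <- if (mode == "joint") "g"
          else if (method == "both") c("f_dis", "f_res") else method
  mins <- matrix(NA_real_, length(n_ladder), length(cols),
                 dimnames = list(NULL, cols))
  for (i in seq_along(n_ladder)) {
    pops <- build_populations(mean_radii_um, params,
                              n_samples = n_ladder[i], q2 = q2,
                              seed = child_seed(seed, 91, i))
    sols <- lapply(pops, solve_population, params = params,
                   lookup = lookup)
    if (mode == "joint") {
      mins[i, "g"] <- collapse_joint(sols, ...)$g_min
    } else {
      if (method %in% c("both", "distance"))
        mins[i, if (method == "both") "f_dis" else method] <-
          collapse_marginal(sols, method = "distance", ...)$f_min
      if (method %in% c("both", "residual"))
        mins[i, if (method == "both") "f_res" else method] <-
          collapse_marginal(sols, method = "residual", ...)$f_min
    }
  }
  plateau <- plateau_point(n_ladder, mins, tol = plateau_tol)
  out <- data.frame(n = n_ladder, mins)
  attr(out, "plateau_n") <- plateau
  attr(out, "mode") <- mode
  class(out) <- c("plateau_curve", "data.frame")
  out
}

# Smallest ladder N from which all subsequent minima (all tracked
# functionals) stay within +-tol relative of the final value.
plateau_point <- function(n_ladder, mins, tol = 0.1) {
  mins <- as.matrix(mins)
  final <- mins[nrow(mins), ]
  ok <- apply(mins, 1, function(row)
    all(abs(row / final - 1) <= tol, na.rm = TRUE))
  # onset of the terminal stable run (the final point trivially qualifies)
  if (!all(ok)) {
    last_bad <- max(which(!ok))
    n_ladder[min(last_bad + 1L, length(n_ladder))]
  } else n_ladder[1L]
}

#' @export
print.plateau_curve <- function(x, ...) {
  cat(sprintf("Functional minima vs N (%s mode); plateau at N = %s\n",
              attr(x, "mode"),
              ifelse(is.na(attr(x, "plateau_n")), "none",
                     attr(x, "plateau_n"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Variability sweep of the joint scaling exponents
#'
#' Reruns the joint pipeline on one window for several combinations of size
#' variability `q2` and sOCR variability, including the zero-variability
#' combination, which degenerates to the exact power-law solve through the
#' mean (m, B) points.
#'
#' @param mean_radii_um Window member mean radii (micrometres).
#' @param params Baseline [kinetic_params()].
#' @param combos Data frame with columns `q2` and `socr_sd_frac`; the
#'   default sweeps no, intermediate and reference variability.
#' @param n_samples Spheroids per distribution (default 1e4).
#' @param seed Master seed.
#' @param matched_seeds With `TRUE` (default) every combo uses the same
#'   child seed (common random numbers, for paired comparisons); otherwise
#'   combo i uses `child_seed(seed, 77, i)`.
#' @param lookup Optional oxygen lookup table.
#' @param ... Passed to [collapse_joint()].
#' @return Data frame of class `sweep_result`: one row per combo with the
#'   fitted exponents and 1%-variation intervals.
#' @export
variability_sweep <- function(mean_radii_um, params,
                              combos = data.frame(
                                q2 = c(0, 0.001, 0.01),
                                socr_sd_frac = c(0, 0.10, 0.20)),
                              n_samples = 1e4, seed = 1,
                              matched_seeds = TRUE, lookup = NULL, ...) {
  stopifnot(nrow(combos) >= 1,
            all(c("q2", "socr_sd_frac") %in% names(combos)))
  if (is.null(lookup)) {
    hi <- max(mean_radii_um * 1e-6)^2 * (1.6)^2 *
      params$socr_mean * (1 + 6 * max(combos$socr_sd_frac)) * params$rho_c /
      (params$D * params$c0)
    lookup <- build_oxygen_lookup(params, phi2_range = c(1e-6, hi * 2))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    p <- params
    p$socr_sd_frac <- combos$socr_sd_frac[i]
    s <- if (matched_seeds) child_seed(seed, 77) else child_seed(seed, 77, i)
    pops <- build_populations(mean_radii_um, p, n_samples = n_samples,
                              q2 = combos$q2[i], seed = s)
    sols <- lapply(pops, solve_population, params = p, lookup = lookup)
    fit <- collapse_joint(sols, ...)
    data.frame(q2 = combos$q2[i], socr_sd_frac = combos$socr_sd_frac[i],
               gamma_hat = fit$gamma_hat,
               gamma_lo = fit$gamma_interval[1],
               gamma_hi = fit$gamma_interval[2],
               delta_hat = fit$delta_hat,
               delta_lo = fit$delta_interval[1],
               delta_hi = fit$delta_interval[2],
               g_min = fit$g_min)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' One-at-a-time sensitivity of the marginal exponent to kinetic inputs
#'
#' Perturbs each kinetic parameter by +-`perturbation_frac`, reruns the
#' marginal collapse on a reference window with identical seeds, and reports
#' the exponent shifts.
#'
#' @param mean_radii_um Window member mean radii (micrometres).
#' @param params Baseline [kinetic_params()].
#' @param perturbation_frac Relative perturbation (default 0.05).
#' @param parameters Which fields to perturb.
#' @param n_samples Spheroids per distribution.
#' @param seed Master seed (same for every run: paired comparison).
#' @param method Marginal collapse method.
#' @param ... Passed to [collapse_marginal()].
#' @return Data frame: parameter, direction, perturbed delta, baseline
#'   delta, shift, and whether the shift stays inside the baseline
#'   1%-variation interval.
#' @export
sensitivity_analysis <- function(mean_radii_um, params,
                                 perturbation_frac = 0.05,
                                 parameters = c("socr_mean", "rho_c", "k_M",
                                                "D", "c0"),
                                 n_samples = 200, seed = 1,
                                 method = "distance", ...) {
  stopifnot(perturbation_frac >= 0)
  run_delta <- function(p) {
    pops <- build_populations(mean_radii_um, p, n_samples = n_samples,
                              seed = child_seed(seed, 55))
    sols <- solve_populations(pops, p)   # one shared lookup per param set
    collapse_marginal(sols, method = method, ...)
  }
  base <- run_delta(params)
  rows <- list()
  for (par in parameters) {
    for (dir in c(-1, 1)) {
      p <- params
      p[[par]] <- p[[par]] * (1 + dir * perturbation_frac)
      validate_kinetic_params(p)
      fit <- run_delta(p)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, direction = dir, delta_hat = fit$delta_hat,
        delta_base = base$delta_hat,
        shift = fit$delta_hat - base$delta_hat,
        within_interval = fit$delta_hat >= base$delta_interval[1] &&
          fit$delta_hat <= base$delta_interval[2])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- base
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
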