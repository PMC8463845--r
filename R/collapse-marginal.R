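# Finite-size scaling collapse of marginal metabolic-rate distributions.
#
# Under the scaling ansatz p(B | <m>, beta) = B^-beta F(B / <m>^delta) with
# beta = 1, the curves (log10 B/<m>^delta, log10 B p(B)) of different size
# distributions superimpose at the true delta. The exponent is estimated by
# minimizing either the Bhattacharjee-Seno residual functional (f_res) or
# the nearest-neighbour distance functional (f_dis) over delta.

# Internal: per-distribution marginal density summaries used by both
# functionals. `sols` is a list of spheroid_solutions (or anything with $B
# and a mean_mass attribute). Returns one curve set per bin-origin dither;
# the functionals average over dithers, which suppresses binning noise.
marginal_curves <- function(sols, bins = 30, dithers = 4) {
  shifts <- (seq_len(dithers) - 1) / dithers
  lapply(shifts, function(sh) {
    lapply(sols, function(s) {
      B <- s$B[is.finite(s$B)]
      dd <- log_density(B, bins = bins, origin_shift = sh)
      list(lp = dd$log_points, logm = log10(attr(s, "mean_mass")),
           B = B, n = length(B))
    })
  })
}

translate_curves <- function(curves, delta) {
  lapply(curves, function(cv) {
    lp <- cv$lp
    lp[, 1] <- lp[, 1] - delta * cv$logm
    lp
  })
}

#' Distance-based collapse functional for marginal distributions
#'
#' Sum over ordered pairs of distributions of the mean squared
#' nearest-neighbour Euclidean distance between their rescaled log-log
#' curves, with both axes standardized by the pooled range so the value is
#' unit free.
#'
#' @param delta Trial scaling exponent.
#' @param sols List of `spheroid_solutions` (>= 2), one per size
#'   distribution.
#' @param bins Number of log-spaced histogram bins.
#' @param dithers Number of bin-origin offsets averaged over.
#' @param curves Internal precomputed curves (overrides `sols`).
#' @return Nonnegative scalar, invariant to distribution relabeling.
#' @export
f_dis <- function(delta, sols = NULL, bins = 30, dithers = 4,
                  curves = NULL) {
  if (is.null(curves))
    curves <- marginal_curves(sols, bins = bins, dithers = dithers)
  mean(vapply(curves, function(cset) f_dis_one(delta, cset), numeric(1)))
}

f_dis_one <- function(delta, cset) {
  stopifnot(length(cset) >= 2)
  tc <- translate_curves(cset, delta)
  all_pts <- do.call(rbind, tc)
  rng_x <- diff(range(all_pts[, 1])); rng_y <- diff(range(all_pts[, 2]))
  if (rng_x == 0) rng_x <- 1
  if (rng_y == 0) rng_y <- 1
  tc <- lapply(tc, function(lp)
    cbind(lp[, 1] / rng_x, lp[, 2] / rng_y))
  total <- 0
  for (i in seq_along(tc)) for (j in seq_along(tc)) {
    if (i == j) next
    total <- total + mean_sq_nn(tc[[i]], tc[[j]])
  }
  total
}

#' Residual-based (Bhattacharjee-Seno) collapse functional
#'
#' For every ordered pair of rescaled log-log curves, linearly interpolates
#' one curve at the abscissae of the other over their overlap and
#' accumulates the mean squared ordinate residual. Pairs with no abscissa
#' overlap after rescaling are skipped with a warning.
#'
#' @inheritParams f_dis
#' @return Nonnegative scalar.
#' @export
f_res <- function(delta, sols = NULL, bins = 30, dithers = 4,
                  curves = NULL) {
  if (is.null(curves))
    curves <- marginal_curves(sols, bins = bins, dithers = dithers)
  mean(vapply(curves, function(cset) f_res_one(delta, cset), numeric(1)))
}

f_res_one <- function(delta, cset) {
  stopifnot(length(cset) >= 2)
  tc <- translate_curves(cset, delta)
  total <- 0
  n_skipped <- 0L
  for (i in seq_along(tc)) for (j in seq_along(tc)) {
    if (i == j) next
    xi <- tc[[i]][, 1]; yi <- tc[[i]][, 2]
    xj <- tc[[j]][, 1]; yj <- tc[[j]][, 2]
    lo <- max(min(xi), min(xj)); hi <- min(max(xi), max(xj))
    keep <- xi >= lo & xi <= hi
    if (!any(keep) || length(xj) < 2) { n_skipped <- n_skipped + 1L; next }
    yhat <- stats::approx(xj, yj, xout = xi[keep], ties = mean)$y
    total <- total + mean((yi[keep] - yhat)^2)
  }
  if (n_skipped > 0)
    warning(n_skipped, " curve pair(s) had no overlap after rescaling")
  total
}

#' Rescale a marginal metabolic-rate sample
#'
#' Computes `u = B / mean_mass^delta` and the collapsed log-log curve
#' `(u, B^beta p(B))`. With the default `beta = 1` the density of `u` itself
#' is independent of the conditioning mean mass under perfect scaling, so
#' the `u` samples feed the Anderson-Darling test directly.
#'
#' @param B Positive metabolic-rate samples.
#' @param mean_mass Conditioning mean mass (kg).
#' @param beta Normalization exponent (default 1).
#' @param delta Scaling exponent.
#' @param bins Histogram bins.
#' @return List with `u` (rescaled samples) and `curve` (two-column matrix
#'   of log10 rescaled abscissa and log10 `B^beta p(B)`).
#' @export
rescale_marginal <- function(B, mean_mass, beta = 1, delta, bins = 30) {
  stopifnot(all(B > 0), mean_mass > 0)
  dd <- log_density(B, bins = bins)
  lp <- dd$log_points
  # generic beta: ordinate log10(B^beta p(B)); log_points store beta = 1
  lp[, 2] <- lp[, 2] + (beta - 1) * lp[, 1]
  lp[, 1] <- lp[, 1] - delta * log10(mean_mass)
  list(u = B / mean_mass^delta, curve = lp)
}

#' Estimate the marginal scaling exponent by optimal data collapse
#'
#' Minimizes the chosen collapse functional over a grid of `delta` values
#' with local refinement, returning the optimum, its 1%-variation interval
#' `{delta : f(delta) <= 1.01 f(delta_hat)}`, and the k-sample
#' Anderson-Darling p-value of the rescaled samples at the optimum.
#'
#' Degenerate inputs in which every distribution has (numerically) zero
#' spread reduce to the exact power-law fit through the per-distribution
#' mean points.
#'
#' @param sols List of `spheroid_solutions` for >= 3 consecutive size
#'   distributions (two are accepted for exploratory use).
#' @param method `"distance"` (nearest-neighbour functional) or
#'   `"residual"` (Bhattacharjee-Seno).
#' @param grid Search grid for delta (default `seq(0.5, 1.3, by = 0.005)`).
#' @param bins Histogram bins per distribution.
#' @param dithers Bin-origin offsets averaged over (see [log_density()]).
#' @param members Optional integer labels of the member distributions
#'   (defaults to their `distribution_index`).
#' @return An object of class `collapse_fit`.
#' @export
#' @examples
#' params <- cell_type_params("stem")
#' pops <- build_populations(size_ladder()[9:11], params,
#'                           n_samples = 200, seed = 1)
#' sols <- solve_populations(pops, params)
#' fit <- collapse_marginal(sols, method = "distance")
#' coef(fit)
collapse_marginal <- function(sols, method = c("distance", "residual"),
                              grid = seq(0.5, 1.3, by = 0.005), bins = 30,
                              dithers = 4, members = NULL) {
  method <- match.arg(method)
  stopifnot(length(sols) >= 2)
  if (is.null(members))
    members <- vapply(sols, function(s) s$distribution_index[1], numeric(1))
  mean_masses <- vapply(sols, function(s) attr(s, "mean_mass"), numeric(1))
  B_sets <- lapply(sols, function(s) s$B[is.finite(s$B)])

  # degenerate (no-variability) inputs: exact log-log power-law fit
  spread <- vapply(B_sets, function(b) diff(range(b)) / max(b), numeric(1))
  if (all(spread < 1e-9)) {
    logB <- log10(vapply(B_sets, mean, numeric(1)))
    logm <- log10(mean_masses)
    delta_hat <- unname(coef(stats::lm(logB ~ logm))[2])
    out <- list(delta_hat = delta_hat,
                delta_interval = c(delta_hat, delta_hat),
                f_min = 0, method = method, member_indices = members,
                ad_pvalue = NA_real_, multimodal = FALSE, degenerate = TRUE,
                grid = NULL, f_grid = NULL, curves = NULL,
                mean_masses = mean_masses, beta = 1)
    class(out) <- "collapse_fit"
    return(out)
  }

  curves <- marginal_curves(sols, bins = bins, dithers = dithers)
  fun <- if (method == "distance") {
    function(d) f_dis(d, curves = curves)
  } else {
    function(d) suppressWarnings(f_res(d, curves = curves))
  }
  f_grid <- vapply(grid, fun, numeric(1))
  i_min <- which.min(f_grid)
  lo <- grid[max(1, i_min - 1)]; hi <- grid[min(length(grid), i_min + 1)]
  opt <- stats::optimize(fun, c(lo, hi), tol = 1e-5)
  delta_hat <- opt$minimum
  f_min <- opt$objective
  if (f_grid[i_min] < f_min) { delta_hat <- grid[i_min]; f_min <- f_grid[i_min] }

  ci <- sublevel_interval(grid, f_grid, delta_hat, f_min, fun)
  u_sets <- mapply(function(b, mm) b / mm^delta_hat, B_sets, mean_masses,
                   SIMPLIFY = FALSE)
  ad <- tryCatch(ad_ksample(u_sets), error = function(e) list(pvalue = NA))
  out <- list(delta_hat = delta_hat, delta_interval = ci$interval,
              f_min = f_min, method = method, member_indices = members,
              ad_pvalue = ad$pvalue, multimodal = ci$multimodal,
              degenerate = FALSE, grid = grid, f_grid = f_grid,
              curves = curves, mean_masses = mean_masses, beta = 1)
  class(out) <- "collapse_fit"
  out
}

# 1%-variation sublevel interval {x : f(x) <= 1.01 f_min} around the
# minimum, with edge refinement by root finding; flags multimodality when
# the grid sublevel set is not contiguous.
sublevel_interval <- function(grid, f_grid, x_hat, f_min, fun,
                              factor = 1.01) {
  thr <- factor * f_min
  below <- f_grid <= thr
  idx <- which(below)
  multimodal <- length(idx) > 0 && any(diff(idx) > 1)
  i_hat <- which.min(abs(grid - x_hat))
  # contiguous run containing the minimum
  run_lo <- i_hat; while (run_lo > 1 && below[run_lo - 1]) run_lo <- run_lo - 1
  run_hi <- i_hat
  while (run_hi < length(grid) && below[run_hi + 1]) run_hi <- run_hi + 1
  lo <- grid[run_lo]; hi <- grid[run_hi]
  refine <- function(a, b) {
    # f(a) <= thr < f(b): bisect for the crossing
    tryCatch(stats::uniroot(function(x) fun(x) - thr, c(a, b),
                            tol = 1e-5)$root,
             error = function(e) a)
  }
  if (run_lo > 1) lo <- refine(lo, grid[run_lo - 1])
  if (run_hi < length(grid)) hi <- refine(hi, grid[run_hi + 1])
  list(interval = c(min(lo, x_hat), max(hi, x_hat)), multimodal = multimodal)
}
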