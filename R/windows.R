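# Iterative identification of size windows with a common scaling exponent,
# and their classification as isometric / viable / physiologically relevant.

#' Viability of a window of size distributions
#'
#' A window is viable when, for every member distribution, the aggregate
#' nonviable volume fraction across its spheroids is below `threshold`
#' (default 10%). The aggregate is the mean by default; a quantile rule
#' (e.g. the 90th percentile spheroid) is available instead.
#'
#' @param sols List of `spheroid_solutions`, one per member.
#' @param threshold Viability threshold on the aggregate Phi, percent.
#' @param rule `"mean"` (default) or `"quantile"`.
#' @param q Quantile used when `rule = "quantile"`.
#' @return Logical scalar.
#' @export
classify_viability <- function(sols, threshold = 10, rule = c("mean",
                               "quantile"), q = 0.9) {
  rule <- match.arg(rule)
  agg <- vapply(sols, function(s) {
    phi <- s$phi[is.finite(s$phi)]
    if (rule == "mean") mean(phi) else unname(stats::quantile(phi, q))
  }, numeric(1))
  all(agg < threshold)
}

#' Iterative size-window identification
#'
#' Starting from the three smallest unassigned size distributions, collapses
#' the triplet; if the collapse is accepted (unimodal functional minimum and
#' validation p-value above its threshold), the next larger distribution is
#' added, and so on until acceptance fails. The window is then closed and
#' the search restarts from the next unassigned triplet, so every
#' distribution belongs to at most one window.
#'
#' Acceptance thresholds: Anderson-Darling p > `ad_alpha` (marginal mode) or
#' all Henze-Zirkler p >= `hz_alpha` and mean-vector p > `mv_alpha`
#' (joint mode). A window is *isometric* when its 1%-variation delta
#' interval contains 1, *viable* per [classify_viability()], and
#' *physiologically relevant* when nonisometric, viable, and statistically
#' validated.
#'
#' @param sols List of `spheroid_solutions` for the whole size ladder, in
#'   increasing order of mean radius.
#' @param mode `"marginal"` or `"joint"`.
#' @param method Collapse method passed to [collapse_marginal()] (marginal
#'   mode only).
#' @param ad_alpha,hz_alpha,mv_alpha Acceptance thresholds.
#' @param viability_threshold Percent Phi limit (see
#'   [classify_viability()]).
#' @param viability_rule,viability_q Aggregation rule for viability.
#' @param ... Further arguments passed to the collapse fitter.
#' @return An object of class `size_windows`: list of window reports, each
#'   with `member_indices`, `collapse` (fit object), `isometric`, `viable`,
#'   `validated`, `relevant`.
#' @export
find_windows <- function(sols, mode = c("marginal", "joint"),
                         method = "distance", ad_alpha = 0.05,
                         hz_alpha = 0.01, mv_alpha = 0.01,
                         viability_threshold = 10,
                         viability_rule = "mean", viability_q = 0.9, ...) {
  mode <- match.arg(mode)
  k <- length(sols)
  if (k < 3) stop("find_windows: need at least 3 size distributions",
                  call. = FALSE)
  idx <- vapply(sols, function(s) s$distribution_index[1], numeric(1))

  fit_members <- function(members) {
    sub <- sols[members]
    if (mode == "marginal") collapse_marginal(sub, method = method, ...)
    else collapse_joint(sub, ...)
  }
  accepted <- function(fit) {
    if (isTRUE(fit$degenerate)) return(TRUE)
    if (isTRUE(fit$multimodal)) return(FALSE)
    if (inherits(fit, "collapse_fit")) {
      is.finite(fit$ad_pvalue) && fit$ad_pvalue > ad_alpha
    } else {
      all(is.finite(fit$hz_pvalues)) && all(fit$hz_pvalues >= hz_alpha) &&
        is.finite(fit$meanvec_pvalue) && fit$meanvec_pvalue > mv_alpha
    }
  }

  windows <- list()
  start <- 1L
  while (start + 2L <= k) {
    members <- start:(start + 2L)
    fit <- fit_members(members)
    if (!accepted(fit)) {
      # this triplet does not collapse; advance one rung
      start <- start + 1L
      next
    }
    while (max(members) < k) {
      cand <- c(members, max(members) + 1L)
      fit_cand <- fit_members(cand)
      if (!accepted(fit_cand)) break
      members <- cand
      fit <- fit_cand
    }
    di <- fit$delta_interval
    isometric <- di[1] <= 1 && 1 <= di[2]
    viable <- classify_viability(sols[members],
                                 threshold = viability_threshold,
                                 rule = viability_rule, q = viability_q)
    windows[[length(windows) + 1L]] <- list(
      member_indices = idx[members], collapse = fit,
      isometric = isometric, viable = viable, validated = TRUE,
      relevant = !isometric && viable)
    start <- max(members) + 1L
  }
  structure(list(windows = windows, mode = mode,
                 ladder_indices = idx), class = "size_windows")
}

#' @export
print.size_windows <- function(x, ...) {
  cat(sprintf("Size windows (%s mode): %d window(s)\n", x$mode,
              length(x$windows)))
  for (w in x$windows) {
    fit <- w$collapse
    lab <- paste(range(w$member_indices), collapse = "-")
    if (inherits(fit, "collapse_fit")) {
      cat(sprintf(
        "  %s: delta = %.3f [%.3f, %.3f], AD p = %.3g | %s, %s%s\n",
        lab, fit$delta_hat, fit$delta_interval[1], fit$delta_interval[2],
        fit$ad_pvalue,
        if (w$isometric) "isometric" else "nonisometric",
        if (w$viable) "viable" else "nonviable",
        if (w$relevant) ", RELEVANT" else ""))
    } else {
      cat(sprintf(
        "  %s: gamma = %.3f, delta = %.3f [%.3f, %.3f], mv p = %.3g | %s, %s%s\n",
        lab, fit$gamma_hat, fit$delta_hat, fit$delta_interval[1],
        fit$delta_interval[2], fit$meanvec_pvalue,
        if (w$isometric) "isometric" else "nonisometric",
        if (w$viable) "viable" else "nonviable",
        if (w$relevant) ", RELEVANT" else ""))
    }
  }
  invisible(x)
}

#' Per-distribution classification table
#'
#' One row per size distribution: its window (if any), isometric, viable and
#' relevant labels — the tabular analogue of the phase-diagram figure.
#'
#' @param wins A `size_windows` object.
#' @param sols The solutions list used to build it.
#' @param viability_threshold Percent Phi limit.
#' @return A data frame.
#' @export
window_table <- function(wins, sols, viability_threshold = 10) {
  idx <- wins$ladder_indices
  rows <- data.frame(distribution_index = idx,
                     mean_phi = vapply(sols, function(s)
                       mean(s$phi[is.finite(s$phi)]), numeric(1)))
  rows$window <- NA_character_
  rows$isometric <- NA
  rows$relevant <- FALSE
  for (w in wins$windows) {
    sel <- rows$distribution_index %in% w$member_indices
    rows$window[sel] <- paste(range(w$member_indices), collapse = "-")
    rows$isometric[sel] <- w$isometric
    rows$relevant[sel] <- w$relevant
  }
  rows$viable <- rows$mean_phi < viability_threshold
  rows
}
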