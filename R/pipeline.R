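# Configuration, end-to-end pipeline and external-table import.

#' Default run configuration
#'
#' Returns the configuration list the pipeline runs on: the size ladder,
#' variability coefficients, per-cell-type kinetic parameters, sample sizes,
#' seeds, collapse settings and acceptance thresholds. Radii are in
#' micrometres at this interface (converted to SI internally); everything
#' else is strict SI.
#'
#' @param cell_type `"stem"` or `"hepatocyte"`.
#' @param n_samples Spheroids per size distribution.
#' @param seed Master seed.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(cell_type = "stem", n_samples = 200, seed = 1) {
  cfg <- list(
    cell_type = cell_type,
    mean_radii_um = size_ladder(),
    q2 = 0.01,
    n_samples = n_samples,
    seed = seed,
    params = unclass(cell_type_params(cell_type)),
    collapse = list(bins = 30, dithers = 4,
                    delta_grid = c(0.5, 1.3, 0.005),
                    gamma_grid = c(0.8, 1.2, 0.02),
                    joint_delta_grid = c(0.5, 1.3, 0.02),
                    method = "distance"),
    thresholds = list(ad_alpha = 0.05, hz_alpha = 0.01, mv_alpha = 0.01,
                      viability_percent = 10, plateau_tol = 0.1))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a validated `run_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- utils::modifyList(unclass(cfg), raw)
  cfg$params <- do.call(kinetic_params,
                        cfg$params[setdiff(names(cfg$params), NULL)])
  validate_kinetic_params(cfg$params)
  cfg$params <- unclass(cfg$params)
  stopifnot(all(cfg$mean_radii_um > 0), cfg$q2 >= 0, cfg$q2 < 1,
            cfg$n_samples >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_config
#' @param cfg A `run_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full in silico pipeline
#'
#' Generates the spheroid populations of the configured size ladder, solves
#' the oxygen model for every spheroid, identifies marginal and/or joint
#' size windows, and reports the physiological-relevance verdicts.
#'
#' @param cfg A `run_config` (see [default_config()], [read_config()]).
#' @param mode `"marginal"`, `"joint"`, or `"both"`.
#' @param out_dir Optional directory for stage artifacts (population and
#'   solution CSV, window report JSON-like RDS).
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report` with elements `populations`,
#'   `solutions`, `windows_marginal`, `windows_joint`, `tables` and
#'   `timings` (seconds per stage).
#' @export
run_pipeline <- function(cfg = default_config(), mode = c("both", "marginal",
                         "joint"), out_dir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message(sprintf(...))
  params <- do.call(kinetic_params, cfg$params)
  timings <- c()
  tic <- function() proc.time()[[3]]

  t0 <- tic()
  pops <- build_populations(cfg$mean_radii_um, params,
                            n_samples = cfg$n_samples, q2 = cfg$q2,
                            seed = cfg$seed)
  timings["generate"] <- tic() - t0
  say("generated %d populations (N = %d each) in %.1fs", length(pops),
      cfg$n_samples, timings["generate"])

  t0 <- tic()
  sols <- solve_populations(pops, params)
  timings["solve"] <- tic() - t0
  say("solved %d spheroids in %.1fs", sum(lengths(lapply(sols, `[[`, "B"))),
      timings["solve"])

  thr <- cfg$thresholds
  gr <- function(v) seq(v[1], v[2], by = v[3])
  wm <- wj <- NULL
  if (mode %in% c("both", "marginal")) {
    t0 <- tic()
    wm <- find_windows(sols, mode = "marginal",
                       method = cfg$collapse$method,
                       ad_alpha = thr$ad_alpha,
                       viability_threshold = thr$viability_percent,
                       grid = gr(cfg$collapse$delta_grid),
                       bins = cfg$collapse$bins,
                       dithers = cfg$collapse$dithers)
    timings["windows_marginal"] <- tic() - t0
  }
  if (mode %in% c("both", "joint")) {
    t0 <- tic()
    wj <- find_windows(sols, mode = "joint",
                       hz_alpha = thr$hz_alpha, mv_alpha = thr$mv_alpha,
                       viability_threshold = thr$viability_percent,
                       gamma_grid = gr(cfg$collapse$gamma_grid),
                       delta_grid = gr(cfg$collapse$joint_delta_grid),
                       bins = cfg$collapse$bins)
    timings["windows_joint"] <- tic() - t0
  }
  report <- list(config = cfg, populations = pops, solutions = sols,
                 windows_marginal = wm, windows_joint = wj,
                 tables = list(
                   marginal = if (!is.null(wm)) window_table(wm, sols,
                     thr$viability_percent),
                   joint = if (!is.null(wj)) window_table(wj, sols,
                     thr$viability_percent)),
                 timings = timings)
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_population_csv(population_table(pops, sols),
                         file.path(out_dir, "population_solutions.csv"))
    saveRDS(report, file.path(out_dir, "pipeline_report.rds"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %s cells, %d size distributions, N = %d\n",
              x$config$cell_type, length(x$populations),
              x$config$n_samples))
  if (!is.null(x$windows_marginal)) print(x$windows_marginal)
  if (!is.null(x$windows_joint)) print(x$windows_joint)
  invisible(x)
}

#' Load an external (mass, B) table for collapse-only use
#'
#' Reads a delimited text file with columns `group`, `mass_kg`,
#' `B_mol_per_s` (header required) and returns a list of
#' solution-like data frames, one per group, ready for [collapse_marginal()]
#' and [collapse_joint()]. Group mean masses default to the group sample
#' means; a named `mean_mass` vector overrides them.
#'
#' @param path File path (CSV or any `sep`-delimited text).
#' @param sep Field separator (default comma).
#' @param mean_mass Optional named numeric vector of conditioning mean
#'   masses (kg) per group label.
#' @return Named list of solution-like data frames (with `mean_mass`
#'   attributes).
#' @export
load_external_table <- function(path, sep = ",", mean_mass = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("group", "mass_kg", "B_mol_per_s")
  if (!all(need %in% names(tab)))
    stop("load_external_table: file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab$mass_kg)) || any(tab$mass_kg <= 0) ||
      any(!is.finite(tab$B_mol_per_s)) || any(tab$B_mol_per_s <= 0))
    stop("load_external_table: masses and metabolic rates must be positive",
         call. = FALSE)
  groups <- split(tab, tab$group)
  out <- lapply(names(groups), function(gname) {
    gg <- groups[[gname]]
    if (nrow(gg) < 20)
      warning("group '", gname, "' has fewer than 20 rows")
    s <- data.frame(distribution_index = match(gname, names(groups)),
                    mass = gg$mass_kg, B = gg$B_mol_per_s,
                    phi = NA_real_)
    attr(s, "mean_mass") <- if (!is.null(mean_mass) &&
                                gname %in% names(mean_mass))
      unname(mean_mass[gname]) else mean(gg$mass_kg)
    class(s) <- c("spheroid_solutions", "data.frame")
    s
  })
  names(out) <- names(groups)
  out
}
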