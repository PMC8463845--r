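# Statistical validation tests for collapsed distributions.

#' k-sample Anderson-Darling test
#'
#' Tests whether k independent samples are drawn from a common (unspecified)
#' continuous distribution, following Scholz and Stephens (1987). The
#' statistic is standardized by its exact null mean (k - 1) and variance and
#' converted to a p-value through the published critical-value surface
#' (quantile interpolation on the logistic scale), the same approximation
#' used in standard implementations.
#'
#' @param samples List of numeric vectors (at least two, each of length >= 2
#'   after removing non-finite values).
#' @return List with `A2` (the statistic), `T` (standardized statistic),
#'   `pvalue`, `k`, and `N` (pooled size).
#' @export
ad_ksample <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  samples <- lapply(samples, function(x) x[is.finite(x)])
  n <- lengths(samples)
  if (any(n < 2))
    stop("ad_ksample: each sample needs at least 2 values", call. = FALSE)
  k <- length(samples)
  pooled <- sort(unlist(samples, use.names = FALSE))
  N <- length(pooled)
  if (length(unique(pooled)) == 1L)
    stop("ad_ksample: pooled sample is degenerate (all ties)", call. = FALSE)
  # continuous-data version of the statistic; ties broken by midranks would
  # only matter for heavily discretized inputs
  z <- pooled[-N]
  j <- seq_len(N - 1)
  A2 <- 0
  for (i in seq_len(k)) {
    # M_ij: number of sample-i values <= j-th pooled order statistic
    M <- findInterval(z, sort(samples[[i]]))
    A2 <- A2 + (1 / n[i]) * sum((N * M - j * n[i])^2 / (j * (N - j)))
  }
  A2 <- A2 / N
  # exact null variance (Scholz & Stephens 1987)
  H <- sum(1 / n)
  h <- sum(1 / j)
  i_seq <- seq_len(N - 2)
  g <- sum(vapply(i_seq, function(i)
    sum(1 / ((N - i) * seq.int(i + 1, N - 1))), numeric(1)))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * h * k + (2 * g - 14 * h - 4) * H - 8 * h +
    4 * g - 6
  cc <- (6 * h + 2 * g - 2) * k^2 + (4 * h - 4 * g + 6) * k +
    (2 * h - 6) * H + 4 * h
  d <- (2 * h + 6) * k^2 - 4 * h * k
  var_A2 <- (a * N^3 + b * N^2 + cc * N + d) /
    ((N - 1) * (N - 2) * (N - 3))
  T_stat <- (A2 - (k - 1)) / sqrt(var_A2)
  list(A2 = A2, T = T_stat, pvalue = ad_pvalue(T_stat, k - 1), k = k, N = N)
}

# Interpolated p-value for the standardized k-sample AD statistic.
# Critical-value coefficients t_m(alpha) = b0 + b1/sqrt(m) + b2/m from
# Scholz & Stephens (1987), Table 1; quadratic interpolation of
# log(alpha/(1-alpha)) against t, extrapolated linearly outside.
ad_pvalue <- function(T_stat, m) {
  alpha <- c(0.25, 0.10, 0.05, 0.025, 0.01)
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396)
  tq <- b0 + b1 / sqrt(m) + b2 / m
  lal <- log(alpha / (1 - alpha))
  fit <- stats::lm(lal ~ poly(tq, 2, raw = TRUE))
  extrap <- function(t) {
    co <- coef(fit)
    co[1] + co[2] * t + co[3] * t^2
  }
  lp <- if (T_stat < min(tq)) {
    # linear continuation with the boundary slope keeps p monotone
    co <- coef(fit)
    sl <- co[2] + 2 * co[3] * min(tq)
    extrap(min(tq)) + sl * (T_stat - min(tq))
  } else if (T_stat > max(tq)) {
    co <- coef(fit)
    sl <- co[2] + 2 * co[3] * max(tq)
    extrap(max(tq)) + sl * (T_stat - max(tq))
  } else extrap(T_stat)
  1 / (1 + exp(-lp))
}

#' Henze-Zirkler test of multivariate normality
#'
#' Computes the Henze-Zirkler statistic with the standard data-driven
#' bandwidth and its lognormal asymptotic p-value.
#'
#' @param x Numeric matrix (rows = observations, columns = variables);
#'   at least 20 rows.
#' @return List with `HZ`, `pvalue`, `n`, `d`.
#' @export
hz_test_matrix <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 20) stop("hz_test_matrix: need at least 20 observations",
                   call. = FALSE)
  ctr <- scale(x, center = TRUE, scale = FALSE)
  S <- crossprod(ctr) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("hz_test_matrix: singular covariance matrix", call. = FALSE))
  y <- ctr %*% t(chol(Sinv))   # whitening: y y' = ctr S^-1 ctr'
  Dij <- as.matrix(stats::dist(y))^2
  Di <- rowSums(y^2)
  b <- (1 / sqrt(2)) * ((2 * d + 1) * n / 4)^(1 / (d + 4))
  hz <- n * (mean(exp(-b^2 / 2 * Dij)) -
             2 * (1 + b^2)^(-d / 2) * mean(exp(-b^2 * Di / (2 * (1 + b^2)))) +
             (1 + 2 * b^2)^(-d / 2))
  a <- 1 + 2 * b^2
  wb <- (1 + b^2) * (1 + 3 * b^2)
  mu <- 1 - a^(-d / 2) * (1 + d * b^2 / a + d * (d + 2) * b^4 / (2 * a^2))
  si2 <- 2 * (1 + 4 * b^2)^(-d / 2) +
    2 * a^(-d) * (1 + 2 * d * b^4 / a^2 + 3 * d * (d + 2) * b^8 / (4 * a^4)) -
    4 * wb^(-d / 2) * (1 + 3 * d * b^4 / (2 * wb) +
                       d * (d + 2) * b^8 / (2 * wb^2))
  pmu <- log(sqrt(mu^4 / (si2 + mu^2)))
  psi <- sqrt(log1p(si2 / mu^2))
  list(HZ = hz, pvalue = stats::plnorm(hz, pmu, psi, lower.tail = FALSE),
       n = n, d = d)
}

#' Henze-Zirkler normality check of one rescaled joint distribution
#'
#' Applies [hz_test_matrix()] to the log-transformed rescaled coordinates
#' `(log10(m / mean_mass^gamma), log10(B / mean_mass^delta))`. Because the
#' rescaling is a shift in log space and the test is affine invariant, the
#' p-value characterizes the log-bivariate shape of the distribution itself.
#'
#' @param m,B Positive sample vectors.
#' @param mean_mass Conditioning mean mass of the distribution (kg).
#' @param gamma,delta Scaling exponents.
#' @return List with `HZ`, `pvalue`, `n`, `d`.
#' @export
hz_test <- function(m, B, mean_mass = 1, gamma = 1, delta = 1) {
  stopifnot(all(m > 0), all(B > 0), length(m) == length(B))
  hz_test_matrix(cbind(log10(m) - gamma * log10(mean_mass),
                       log10(B) - delta * log10(mean_mass)))
}

#' Mean-vector equality across collapsed distributions
#'
#' Tests whether the bivariate mean vectors of the rescaled (collapsed)
#' distributions coincide: one-way MANOVA (Wilks' lambda) on the two
#' log-rescaled coordinates with the distribution index as factor, or,
#' alternatively, per-coordinate one-way ANOVAs with Bonferroni combination.
#'
#' @param coords List of two-column matrices, one per distribution
#'   (log-rescaled mass and metabolic-rate coordinates).
#' @param method `"manova"` (default) or `"anova"`.
#' @return List with `pvalue`, `method`, `statistic`.
#' @export
meanvec_test <- function(coords, method = c("manova", "anova")) {
  method <- match.arg(method)
  stopifnot(is.list(coords), length(coords) >= 2)
  y <- do.call(rbind, lapply(coords, as.matrix))
  grp <- factor(rep(seq_along(coords), vapply(coords, nrow, 1L)))
  if (method == "manova") {
    fit <- stats::manova(y ~ grp)
    sm <- summary(fit, test = "Wilks")$stats
    list(pvalue = sm[1, "Pr(>F)"], method = "manova",
         statistic = sm[1, "Wilks"])
  } else {
    p <- vapply(seq_len(ncol(y)), function(j)
      stats::anova(stats::lm(y[, j] ~ grp))[1, "Pr(>F)"], numeric(1))
    list(pvalue = min(1, min(p) * length(p)), method = "anova",
         statistic = NA_real_)
  }
}
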