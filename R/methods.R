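# S3 methods for the collapse fit objects.

#' @export
print.collapse_fit <- function(x, ...) {
  cat(sprintf("Marginal collapse (%s method), distributions %s\n",
              x$method, paste(x$member_indices, collapse = ", ")))
  cat(sprintf("  delta = %.4f  (1%%-variation interval [%.4f, %.4f])\n",
              x$delta_hat, x$delta_interval[1], x$delta_interval[2]))
  cat(sprintf("  f_min = %.4g, Anderson-Darling p = %.4g\n",
              x$f_min, x$ad_pvalue))
  if (isTRUE(x$multimodal))
    cat("  warning: functional is multimodal over the search grid\n")
  if (isTRUE(x$degenerate))
    cat("  (degenerate inputs: exact power-law fit through the means)\n")
  invisible(x)
}

#' @export
summary.collapse_fit <- function(object, ...) {
  iso <- object$delta_interval[1] <= 1 && 1 <= object$delta_interval[2]
  cat(sprintf(
    "Scaling exponent delta = %.4f [%.4f, %.4f] -> %s scaling\n",
    object$delta_hat, object$delta_interval[1], object$delta_interval[2],
    if (iso) "isometric" else "nonisometric"))
  cat(sprintf("Functional: %s, minimum %.4g%s\n", object$method,
              object$f_min,
              if (isTRUE(object$multimodal)) " (multimodal)" else ""))
  cat(sprintf("AD test of a common rescaled distribution: p = %.4g\n",
              object$ad_pvalue))
  invisible(object)
}

#' @export
coef.collapse_fit <- function(object, ...) c(delta = object$delta_hat)

#' @export
confint.collapse_fit <- function(object, parm, level, ...) {
  out <- matrix(object$delta_interval, nrow = 1,
                dimnames = list("delta", c("lower", "upper")))
  out
}

#' Plot a marginal collapse
#'
#' Draws the rescaled log-log curves of the member distributions at the
#' fitted exponent (or any other `delta`).
#'
#' @param x A `collapse_fit`.
#' @param delta Exponent at which to draw the curves.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.collapse_fit <- function(x, delta = x$delta_hat, ...) {
  if (is.null(x$curves)) {
    warning("degenerate fit has no curves to plot")
    return(invisible(x))
  }
  tc <- translate_curves(x$curves[[1]], delta)
  xy <- do.call(rbind, tc)
  graphics::plot(xy[, 1], xy[, 2], type = "n",
                 xlab = expression(log[10] * (B / "<m>"^delta)),
                 ylab = expression(log[10] * (B %.% p(B))), ...)
  for (i in seq_along(tc))
    graphics::points(tc[[i]][, 1], tc[[i]][, 2], col = i, pch = 16)
  graphics::legend("topright", legend = x$member_indices, col =
                   seq_along(tc), pch = 16, title = "distribution")
  invisible(x)
}

#' @export
print.joint_collapse_fit <- function(x, ...) {
  cat(sprintf("Joint collapse, distributions %s\n",
              paste(x$member_indices, collapse = ", ")))
  cat(sprintf("  gamma = %.4f [%.4f, %.4f]\n", x$gamma_hat,
              x$gamma_interval[1], x$gamma_interval[2]))
  cat(sprintf("  delta = %.4f [%.4f, %.4f]\n", x$delta_hat,
              x$delta_interval[1], x$delta_interval[2]))
  cat(sprintf("  g_min = %.4g\n", x$g_min))
  if (!is.null(x$hz_pvalues))
    cat("  Henze-Zirkler p per member:",
        paste(signif(x$hz_pvalues, 3), collapse = ", "), "\n")
  if (is.finite(x$meanvec_pvalue))
    cat(sprintf("  mean-vector equality p = %.4g\n", x$meanvec_pvalue))
  if (isTRUE(x$multimodal))
    cat("  warning: functional is multimodal over the search grid\n")
  if (isTRUE(x$degenerate))
    cat("  (degenerate inputs: exact power-law fit through the means)\n")
  invisible(x)
}

#' @export
coef.joint_collapse_fit <- function(object, ...)
  c(gamma = object$gamma_hat, delta = object$delta_hat)

#' @export
confint.joint_collapse_fit <- function(object, parm, level, ...) {
  rbind(gamma = object$gamma_interval, delta = object$delta_interval) |>
    `colnames<-`(c("lower", "upper"))
}

#' Plot the joint collapse functional surface
#'
#' Image of g over the evaluated (gamma, delta) grid with the optimum
#' marked.
#'
#' @param x A `joint_collapse_fit`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.joint_collapse_fit <- function(x, ...) {
  if (is.null(x$grid)) {
    warning("degenerate fit has no grid to plot")
    return(invisible(x))
  }
  graphics::image(x$grid$gamma, x$grid$delta, log10(x$grid$g),
                  xlab = expression(gamma), ylab = expression(delta), ...)
  graphics::points(x$gamma_hat, x$delta_hat, pch = 3, cex = 2)
  invisible(x)
}
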