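#' @export
print.horizon_fit <- function(x, digits = 4, ...) {
  cat("Exponential planning-horizon model: MT(w) = a*exp(-b*(w-1)) + c\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Effective horizon w* = %s items (criterion %.2g)\n",
              format(round(x$w_star, digits)), x$criterion))
  if (!x$valid) cat("NOTE: fit flagged invalid (degenerate or unconverged)\n")
  invisible(x)
}

#' @export
summary.horizon_fit <- function(object, ...) {
  n <- object$n_points
  rss <- object$sse
  out <- list(
    coefficients = object$coefficients,
    w_star = object$w_star, criterion = object$criterion,
    sse = rss, sigma = sqrt(rss / max(n - 3, 1)),
    n_points = n, converged = object$converged, valid = object$valid,
    call = object$call
  )
  class(out) <- "summary.horizon_fit"
  out
}

#' @export
print.summary.horizon_fit <- function(x, digits = 4, ...) {
  cat("Call: ")
  print(x$call)
  cat("\nCoefficients (MT(w) = a*exp(-b*(w-1)) + c):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nResidual SE: %.4g ms on %d points; SSE = %.6g\n",
              x$sigma, x$n_points, x$sse))
  cat(sprintf("Effective planning horizon w* = %s items (%.0f%% drop criterion)\n",
              format(round(x$w_star, digits)), 100 * (1 - x$criterion)))
  cat(sprintf("Converged: %s, valid: %s\n", x$converged, x$valid))
  invisible(x)
}

#' @export
coef.horizon_fit <- function(object, ...) object$coefficients

#' Predicted movement times from a horizon model
#'
#' @param object a `"horizon_fit"`.
#' @param newdata data frame with a `w` column, or a numeric vector of window
#'   sizes; defaults to the fitted window sizes.
#' @param ... unused.
#' @return predicted MT (ms).
#' @export
predict.horizon_fit <- function(object, newdata = NULL, ...) {
  w <- if (is.null(newdata)) object$w
  else if (is.numeric(newdata)) newdata
  else newdata$w
  cf <- object$coefficients
  cf["a"] * exp(-cf["b"] * (w - 1)) + cf["c"]
}

#' @export
fitted.horizon_fit <- function(object, ...) object$fitted.values

#' @export
residuals.horizon_fit <- function(object, ...) object$residuals

#' @export
plot.horizon_fit <- function(x, xlab = "viewing window size (w)",
                             ylab = "movement time (ms)", ...) {
  graphics::plot(x$w, x$mt, pch = 19, xlab = xlab, ylab = ylab, ...)
  ww <- seq(min(x$w), max(x$w), length.out = 200)
  graphics::lines(ww, predict(x, ww))
  cf <- x$coefficients
  graphics::abline(h = cf["c"], lty = 3)
  if (is.finite(x$w_star)) graphics::abline(v = x$w_star, lty = 2)
  invisible(x)
}

#' Simulate movement-time curves from a fitted horizon model
#'
#' Draws `nsim` replicate MT-vs-w curves from the fitted exponential plus
#' i.i.d. Gaussian noise with the residual standard deviation.
#'
#' @param object a `"horizon_fit"`.
#' @param nsim number of replicates.
#' @param seed optional seed, as for [stats::simulate()].
#' @param ... unused.
#' @return data frame of `nsim` columns, one row per fitted window size.
#' @export
simulate.horizon_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n_points - 3, 1))
  mu <- object$fitted.values
  out <- as.data.frame(
    matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sigma),
           ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "w") <- object$w
  out
}
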