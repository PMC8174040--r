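#' Fit the exponential movement-time saturation model
#'
#' Fits `MT = a * exp(-b * (w - 1)) + c` to mean movement time as a function
#' of viewing-window size by Levenberg-Marquardt nonlinear least squares
#' (via [minpack.lm::nls.lm()]). The decay rate is optimised on the log scale
#' so `b > 0` always holds and the effective planning horizon stays defined.
#' Starting values follow the data (`a0 = MT(min w) - MT(max w)`,
#' `c0 = MT(max w)`) with a multi-start over `b0 in {0.2, 0.5, 1, 2}`; the
#' best (lowest-SSE) converged fit is kept.
#'
#' @param w_values viewing-window sizes (>= 4 distinct values).
#' @param mt_means positive mean MTs (ms), one per element of `w_values`.
#'   Duplicated `w` values are averaged before fitting.
#' @param init optional named list/vector with starting values `a`, `b`, `c`.
#' @return a list with elements `a`, `b`, `c`, `sse`, `converged`, `valid`,
#'   `n_points`, `fitted`, `residuals`, `w`, `mt`. `valid` is `FALSE` for
#'   degenerate data (e.g. constant MT, where `b` is unidentifiable).
#' @seealso [horizon_fit()] for the user-facing modelling interface.
#' @export
fit_exponential <- function(w_values, mt_means, init = NULL) {
  keep <- is.finite(w_values) & is.finite(mt_means)
  w_values <- w_values[keep]
  mt_means <- mt_means[keep]
  if (anyDuplicated(w_values)) {
    mt_means <- as.numeric(tapply(mt_means, w_values, mean))
    w_values <- sort(unique(w_values))
  }
  o <- order(w_values)
  w <- w_values[o]
  mt <- mt_means[o]
  if (length(w) < 4L) stop("need >= 4 distinct window sizes", call. = FALSE)
  if (any(mt <= 0)) stop("'mt_means' must be positive", call. = FALSE)

  base <- list(a = max(mt[1] - mt[length(mt)], 1e-3), c = mt[length(mt)])
  b_starts <- c(0.5, 0.2, 1, 2)
  if (!is.null(init)) {
    init <- as.list(init)
    base$a <- max(init$a, 1e-6)
    base$c <- init$c
    b_starts <- unique(c(init$b, b_starts))
  }

  resid_fn <- function(par) {
    par["a"] * exp(-exp(par["logb"]) * (w - 1)) + par["c"] - mt
  }
  best <- NULL
  for (b0 in b_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a = base$a, logb = log(b0), c = base$c), fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && sse < best$sse)) {
      best <- list(par = fit$par, sse = sse, conv = conv)
    }
  }
  if (is.null(best)) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, sse = NA_real_,
                converged = FALSE, valid = FALSE, n_points = length(w),
                fitted = rep(NA_real_, length(w)),
                residuals = rep(NA_real_, length(w)), w = w, mt = mt))
  }
  a <- unname(best$par["a"])
  b <- unname(exp(best$par["logb"]))
  cc <- unname(best$par["c"])
  fitted <- a * exp(-b * (w - 1)) + cc
  valid <- best$conv && is.finite(a) && is.finite(b) && is.finite(cc) &&
    stats::sd(mt) > 0 && a > 1e-6 * mean(mt) && b < 1e3 && b > 1e-8
  list(a = a, b = b, c = cc, sse = best$sse, converged = best$conv,
       valid = valid, n_points = length(w), fitted = fitted,
       residuals = mt - fitted, w = w, mt = mt)
}

#' Exponential planning-horizon model for movement times
#'
#' The central estimator of the package. Movement time (MT) as a function of
#' viewing-window size `w` is modelled as an exponential saturation,
#' `MT(w) = a * exp(-b * (w - 1)) + c`, so that `MT(1) = a + c`, the
#' asymptote is `c` and the decay rate is `b`. The effective planning horizon
#' is the window size at which the predicted MT has dropped 99% of the way
#' from its `w = 1` value to the asymptote:
#' `w* = -log(criterion)/b + 1` with `criterion = 0.01`.
#'
#' The model is intended for *participant-level mean* MT per window size
#' (9 points in the canonical design); replicated `w` values in the input are
#' averaged first.
#'
#' @param x a formula such as `mt ~ w`, or a numeric vector of window sizes.
#' @param data data frame providing the formula variables.
#' @param mt mean movement times (default method).
#' @param criterion fraction of the drop above the asymptote that defines the
#'   horizon (default 0.01, i.e. a 99% drop).
#' @param init optional starting values, see [fit_exponential()].
#' @param ... passed between methods.
#' @return an object of class `"horizon_fit"` with components
#'   `coefficients` (named `a`, `b`, `c`), `w_star`, `criterion`, `sse`,
#'   `converged`, `valid`, `n_points`, `w`, `mt`, `fitted.values`,
#'   `residuals`, `call`.
#' @examples
#' w <- c(1:8, 14)
#' mt <- 2000 * exp(-1.0 * (w - 1)) + 3000
#' fit <- horizon_fit(mt ~ w, data.frame(w = w, mt = mt))
#' coef(fit)
#' fit$w_star
#' @export
horizon_fit <- function(x, ...) UseMethod("horizon_fit")

#' @rdname horizon_fit
#' @export
horizon_fit.formula <- function(x, data, criterion = 0.01, init = NULL, ...) {
  mf <- stats::model.frame(x, data)
  out <- horizon_fit.default(mf[[2L]], mf[[1L]], criterion = criterion,
                             init = init)
  out$call <- match.call()
  out
}

#' @rdname horizon_fit
#' @export
horizon_fit.default <- function(x, mt, criterion = 0.01, init = NULL, ...) {
  fit <- fit_exponential(x, mt, init = init)
  obj <- list(
    coefficients = c(a = fit$a, b = fit$b, c = fit$c),
    w_star = if (fit$valid) wstar_from_b(fit$b, criterion) else NA_real_,
    criterion = criterion, sse = fit$sse, converged = fit$converged,
    valid = fit$valid, n_points = fit$n_points, w = fit$w, mt = fit$mt,
    fitted.values = fit$fitted, residuals = fit$residuals,
    call = match.call()
  )
  class(obj) <- "horizon_fit"
  obj
}

#' Effective planning horizon from a fitted model or decay rate
#'
#' Solves `MT(w) = c + criterion * a` for `w`, giving
#' `w* = -log(criterion)/b + 1`. Changing the criterion rescales `w* - 1`
#' by a log ratio but never reorders participants.
#'
#' @param fit a `"horizon_fit"` object, a list with element `b`, or a
#'   numeric decay rate.
#' @param criterion fraction above the asymptote (default 0.01).
#' @return the horizon in window items; `NA` (with a warning) when `b <= 0`
#'   or the fit is invalid.
#' @examples
#' effective_horizon(4.60517) # 2.0
#' @export
effective_horizon <- function(fit, criterion = 0.01) {
  b <- if (is.numeric(fit)) fit else {
    if (!is.null(fit$valid) && !fit$valid) {
      warning("invalid fit: horizon undefined")
      return(NA_real_)
    }
    unname(if (inherits(fit, "horizon_fit")) coef(fit)["b"] else fit$b)
  }
  if (!is.finite(b) || b <= 0) {
    warning("horizon undefined for b <= 0")
    return(NA_real_)
  }
  wstar_from_b(b, criterion)
}
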