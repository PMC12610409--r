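check_fit_data <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_n)
    stop("at least ", min_n, " points are required for this fit")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fit data must be finite")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  invisible(TRUE)
}

#' Fit the three-parameter power surrogate
#'
#' Fits `delta_CI = A * X^B + C` by nonlinear least squares.  Because
#' power fits are sensitive to the starting exponent, a deterministic
#' multi-start is used: for each starting exponent `B` in
#' {-2, -1, -0.5, -0.25} the model is linear in `(A, C)` and solved in
#' closed form, then all three coefficients are refined by
#' Levenberg-Marquardt; the refinement with the smallest residual sum of
#' squares wins.  The coefficient of determination is
#' `R^2 = 1 - SSres / SStot` with the centred total sum of squares.
#'
#' @param x Strictly increasing positive predictor values (at least 4).
#' @param y Response values (change in cranial index, CI points).
#' @param starts Starting exponents for the multi-start.
#'
#' @return Object of class `power_fit` with coefficients `A`, `B`, `C`,
#'   their covariance matrix, `r_squared`, residuals and the data.
#'   Constant responses are handled as a degenerate fit (`A = 0`,
#'   `r_squared = 0`, flagged `degenerate`) rather than an error.
#' @export
fit_power <- function(x, y, starts = c(-2, -1, -0.5, -0.25)) {
  check_fit_data(x, y, 4L)
  if (any(x <= 0)) stop("power fit requires strictly positive x")
  sstot <- sum((y - mean(y))^2)
  if (sstot < 1e-20 * max(1, mean(y)^2)) {
    # constant data: the power model is rank deficient in (A, C)
    return(structure(list(A = 0, B = 1, C = mean(y),
                          vcov = NULL, r_squared = 0,
                          residuals = y - mean(y), x = x, y = y,
                          degenerate = TRUE), class = "power_fit"))
  }
  best <- NULL
  diagnostics <- character(0)
  for (B0 in starts) {
    xb <- x^B0
    lin <- stats::lm.fit(cbind(xb, 1), y)
    start <- list(A = lin$coefficients[[1]], B = B0,
                  C = lin$coefficients[[2]])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * x^B + C, data = data.frame(x = x, y = y),
                        start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics,
                       sprintf("B0 = %g: %s", B0, conditionMessage(fit)))
      next
    }
    ss <- sum(stats::resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best))
    stop("power fit failed to converge from all starting exponents:\n",
         paste(diagnostics, collapse = "\n"))
  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  structure(list(A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
                 vcov = vc, r_squared = 1 - best$ss / sstot,
                 residuals = as.numeric(stats::resid(best$fit)),
                 x = x, y = y, degenerate = FALSE),
            class = "power_fit")
}

#' Fit the linear surrogate
#'
#' Ordinary least squares for `delta_CI = P1 * X + P2` (used for the
#' osteotomy-size relationship).
#'
#' @param x Strictly increasing predictor values (at least 2 distinct).
#' @param y Response values.
#'
#' @return Object of class `linear_fit` with `P1` (slope), `P2`
#'   (intercept), covariance, `r_squared`, residuals and the data.
#' @export
fit_linear <- function(x, y) {
  check_fit_data(x, y, 2L)
  if (length(unique(x)) < 2L)
    stop("linear fit requires at least 2 distinct x values")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(stats::resid(fit)^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else 0
  # covariance in (P1, P2) order, computed directly so an exact fit
  # yields a zero matrix rather than a summary() warning
  Xm <- cbind(x, 1)
  sigma2 <- ssres / max(1L, length(x) - 2L)
  vc <- sigma2 * solve(crossprod(Xm))
  dimnames(vc) <- list(c("P1", "P2"), c("P1", "P2"))
  structure(list(P1 = cf[["x"]], P2 = cf[["(Intercept)"]],
                 vcov = vc, r_squared = r2,
                 residuals = as.numeric(stats::resid(fit)),
                 x = x, y = y), class = "linear_fit")
}

#' Construct a surrogate fit directly from known coefficients
#'
#' Builds `power_fit` / `linear_fit` objects from given coefficients
#' (for example the bundled reference coefficient table), so fitted and
#' fixture-based surrogates share one evaluation path.
#'
#' @param A,B,C Power-law coefficients (`delta_CI = A * X^B + C`).
#' @param P1,P2 Linear coefficients (`delta_CI = P1 * X + P2`).
#' @return A `power_fit` or `linear_fit` with no covariance attached.
#' @export
power_fit_from_coef <- function(A, B, C) {
  structure(list(A = A, B = B, C = C, vcov = NULL, r_squared = NA_real_,
                 residuals = NULL, x = NULL, y = NULL, degenerate = FALSE),
            class = "power_fit")
}

#' @rdname power_fit_from_coef
#' @export
linear_fit_from_coef <- function(P1, P2) {
  structure(list(P1 = P1, P2 = P2, vcov = NULL, r_squared = NA_real_,
                 residuals = NULL, x = NULL, y = NULL),
            class = "linear_fit")
}

#' Evaluate a fitted surrogate
#'
#' @param fit A `power_fit` or `linear_fit`.
#' @param x Values at which to evaluate.  Values outside the fitted
#'   range trigger a warning; non-positive values are an error for the
#'   power form.
#' @return Predicted `delta_CI` values.
#' @export
evaluate_fit <- function(fit, x) UseMethod("evaluate_fit")

warn_outside_domain <- function(fit, x) {
  if (!is.null(fit$x) && length(fit$x) &&
      (min(x) < min(fit$x) - 1e-9 || max(x) > max(fit$x) + 1e-9))
    warning("evaluating the surrogate outside its fitted range")
}

#' @export
evaluate_fit.power_fit <- function(fit, x) {
  if (any(x <= 0)) stop("power surrogate is defined for x > 0 only")
  warn_outside_domain(fit, x)
  fit$A * x^fit$B + fit$C
}

#' @export
evaluate_fit.linear_fit <- function(fit, x) {
  warn_outside_domain(fit, x)
  fit$P1 * x + fit$P2
}

#' Derivative of a fitted surrogate
#'
#' The change rate `d(delta_CI)/dX`: `A * B * X^(B-1)` for the power
#' form, the constant `P1` for the linear form.
#'
#' @inheritParams evaluate_fit
#' @return Derivative values.
#' @export
fit_derivative <- function(fit, x) UseMethod("fit_derivative")

#' @export
fit_derivative.power_fit <- function(fit, x) {
  if (any(x <= 0)) stop("power surrogate is defined for x > 0 only")
  fit$A * fit$B * x^(fit$B - 1)
}

#' @export
fit_derivative.linear_fit <- function(fit, x) {
  rep_len(fit$P1, length(x))
}

#' Delta-method confidence band for a fitted surrogate
#'
#' Pointwise band `fit +/- z * sqrt(g' Sigma g)` where `g` is the
#' gradient of the prediction with respect to the coefficients and
#' `Sigma` their covariance.
#'
#' @param fit A fitted surrogate carrying a covariance matrix.
#' @param x Evaluation grid.
#' @param level Coverage level (default 0.95).
#' @return Data frame with `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, x, level = 0.95) {
  if (is.null(fit$vcov))
    stop("fit carries no coefficient covariance; ",
         "confidence band is unavailable")
  yhat <- evaluate_fit(fit, x)
  g <- if (inherits(fit, "power_fit")) {
    cbind(x^fit$B, fit$A * x^fit$B * log(x), 1)
  } else {
    cbind(x, 1)
  }
  se <- sqrt(pmax(0, rowSums((g %*% fit$vcov) * g)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(x = x, fit = yhat, lower = yhat - z * se, upper = yhat + z * se)
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("power surrogate: delta_CI = %.6g * X^(%.6g) + %.6g   (R^2 = %.4f)\n",
              x$A, x$B, x$C, x$r_squared))
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear surrogate: delta_CI = %.6g * X + %.6g   (R^2 = %.4f)\n",
              x$P1, x$P2, x$r_squared))
  invisible(x)
}
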