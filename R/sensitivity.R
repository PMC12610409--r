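#' Study ranges of the four continuously varied parameters
#'
#' @return Named list of `c(min, max)` ranges: elastic modulus `E`
#'   (MPa), thickness `t` (mm), spring position `SP` (mm) and osteotomy
#'   size `OS` (mm).
#' @export
parameter_ranges <- function() {
  list(E = c(100, 3000), t = c(2, 4), SP = c(10, 40), OS = c(10, 20))
}

#' Sample a fitted surrogate on an equally spaced normalized grid
#'
#' Evaluates the surrogate at `n` equally spaced points spanning the
#' parameter range inclusive.  With the default `n = 30` the normalized
#' step between consecutive samples is 1/29 of the range (about 3.45%),
#' the grid used for the local sensitivity indices.
#'
#' @param fit A `power_fit` or `linear_fit`.
#' @param range Length-2 numeric range `c(min, max)`.
#' @param n Number of samples (default 30).
#' @param parameter Optional parameter label carried in the result.
#'
#' @return Object of class `sampled_curve`: list with `x`, `values`,
#'   `parameter` and the normalized step `dx_norm = 1/(n-1)`.
#' @export
sample_curve <- function(fit, range, n = 30L, parameter = NA_character_) {
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1])
    stop("range must be c(min, max) with min < max")
  x <- seq(range[1], range[2], length.out = n)
  structure(list(x = x, values = evaluate_fit(fit, x),
                 parameter = parameter, dx_norm = 1 / (n - 1)),
            class = "sampled_curve")
}

#' Per-step local sensitivity indices
#'
#' For samples on an equally spaced grid, the index of step `n` is the
#' difference of consecutive `delta_CI` values divided by the
#' normalized step `(X_{n+1} - X_n) / (X_max - X_1)`.  On a 30-point
#' grid every normalized step is 1/29, so each index is 29 times the
#' raw difference.
#'
#' @param curve A [sample_curve()] result, or a numeric vector of grid
#'   values when `values` is given.
#' @param values Sampled `delta_CI` values (when `curve` is the grid).
#'
#' @return Numeric vector of `n - 1` sensitivity indices, in step order.
#' @export
sensitivity_indices <- function(curve, values = NULL) {
  if (inherits(curve, "sampled_curve")) {
    x <- curve$x
    values <- curve$values
  } else {
    x <- curve
  }
  if (length(x) != length(values) || length(x) < 2L)
    stop("need matching grid and values with at least 2 points")
  steps <- diff(x)
  if (max(steps) - min(steps) > 1e-8 * (max(x) - min(x)))
    stop("sensitivity indices require an equally spaced grid")
  diff(values) * (length(x) - 1L)
}

#' Average sensitivity index
#'
#' Arithmetic mean of the per-step indices.  On an equally spaced grid
#' this telescopes to the total change of the curve over its range,
#' `delta_CI(X_max) - delta_CI(X_1)`; both computations are performed
#' and must agree to 1e-10, which guards the normalization.
#'
#' @param indices Per-step indices from [sensitivity_indices()], or a
#'   `sampled_curve` (indices are computed first).
#'
#' @return The average sensitivity (a scalar).
#' @export
average_sensitivity <- function(indices) {
  if (inherits(indices, "sampled_curve")) {
    total <- indices$values[length(indices$values)] - indices$values[1]
    indices <- sensitivity_indices(indices)
    avg <- mean(indices)
    if (abs(avg - total) > 1e-10 * max(1, abs(total)))
      stop("telescoping identity violated: mean index ", avg,
           " vs total change ", total)
    return(avg)
  }
  if (length(indices) == 0L) stop("no sensitivity indices supplied")
  mean(indices)
}

#' Pairwise absolute-difference curve
#'
#' Compares two parameters' effects on a shared normalized index: the
#' elementwise absolute difference of their sampled `delta_CI` curves.
#'
#' @param curve_x,curve_y Two [sample_curve()] results (or numeric
#'   vectors) sampled on grids of equal length.
#'
#' @return Data frame with `index`, `pair` label and `abs_diff`.
#' @export
pairwise_abs_difference <- function(curve_x, curve_y) {
  vx <- if (inherits(curve_x, "sampled_curve")) curve_x$values else curve_x
  vy <- if (inherits(curve_y, "sampled_curve")) curve_y$values else curve_y
  if (length(vx) != length(vy))
    stop("curves must be sampled on grids of equal length")
  lab <- paste0(
    if (inherits(curve_x, "sampled_curve")) curve_x$parameter else "x", "-",
    if (inherits(curve_y, "sampled_curve")) curve_y$parameter else "y")
  data.frame(index = seq_along(vx), pair = lab, abs_diff = abs(vx - vy))
}

#' Sensitivity summary table from fitted surrogates
#'
#' Samples each parameter's surrogate on its study range with `n`
#' equally spaced points and reports the average sensitivity index, for
#' each spring count.
#'
#' @param fits Nested list: `fits[[spring_count]][[parameter]]` with
#'   spring counts `"2"`/`"3"` and parameters among `E`, `t`, `SP`,
#'   `OS`.
#' @param n Samples per curve (default 30).
#'
#' @return Data frame of class `sensitivity_table` with columns
#'   `n_springs`, `parameter`, `average_sensitivity`.
#' @export
sensitivity_table <- function(fits, n = 30L) {
  ranges <- parameter_ranges()
  rows <- list()
  for (ns in names(fits)) {
    for (p in names(fits[[ns]])) {
      curve <- sample_curve(fits[[ns]][[p]], ranges[[p]], n = n,
                            parameter = p)
      rows[[length(rows) + 1L]] <-
        data.frame(n_springs = as.integer(ns), parameter = p,
                   average_sensitivity = average_sensitivity(curve))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' All pairwise absolute-difference curves
#'
#' Produces the six unordered parameter pairs of {E, t, SP, OS} for one
#' set of fitted surrogates.
#'
#' @param fits Named list of surrogates for parameters `E`, `t`, `SP`,
#'   `OS`.
#' @param n Samples per curve (default 30).
#' @return Data frame binding the six difference curves.
#' @export
difference_curves <- function(fits, n = 30L) {
  ranges <- parameter_ranges()
  pars <- intersect(c("E", "t", "SP", "OS"), names(fits))
  curves <- lapply(pars, function(p)
    sample_curve(fits[[p]], ranges[[p]], n = n, parameter = p))
  names(curves) <- pars
  out <- list()
  for (i in seq_along(pars)) {
    for (j in seq_along(pars)) {
      if (j <= i) next
      out[[length(out) + 1L]] <-
        pairwise_abs_difference(curves[[i]], curves[[j]])
    }
  }
  do.call(rbind, out)
}
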