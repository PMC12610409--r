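#' Reference surrogate coefficients
#'
#' The reference coefficient table for the surrogate laws relating the
#' change in cranial index to elastic modulus `E`, bone thickness `t`
#' and spring position `SP` (power form `A * X^B + C`) and to osteotomy
#' size `OS` (linear form `P1 * X + P2`), for two- and three-spring
#' corrections.  These coefficients are bundled as fixture inputs so the
#' analysis layer (sensitivity indices, difference curves) can be run in
#' seconds without the finite-element stage.
#'
#' @return Data frame with columns `parameter`, `n_springs`, `model`,
#'   `A`, `B`, `C`, `P1`, `P2`, `r_squared`.
#' @export
reference_fit_coefficients <- function() {
  data.frame(
    parameter = rep(c("E", "t", "SP", "OS"), each = 2),
    n_springs = rep(c(2L, 3L), 4),
    model = rep(c("power", "power", "power", "linear"), each = 2),
    A = c(40.16, 30.91, 3.754, 4.775, -3.145, -2.661, NA, NA),
    B = c(-0.5695, -0.4463, -1.632, -1.4, -0.3285, -0.552, NA, NA),
    C = c(-0.2011, -0.5485, -0.08946, -0.2461, 2.087, 1.923, NA, NA),
    P1 = c(NA, NA, NA, NA, NA, NA, -0.006143, -0.01157),
    P2 = c(NA, NA, NA, NA, NA, NA, 1.274, 1.819),
    r_squared = c(0.998, 0.9985, 0.9998, 0.9995, 0.9887, 0.9862,
                  0.564, 0.856))
}

#' Reference surrogates as fit objects
#'
#' Wraps [reference_fit_coefficients()] into evaluable fit objects,
#' nested as `fits[["2"]][[parameter]]` / `fits[["3"]][[parameter]]`
#' for use with [sensitivity_table()] and [difference_curves()].
#'
#' @return Nested list of `power_fit` / `linear_fit` objects.
#' @export
reference_fits <- function() {
  tab <- reference_fit_coefficients()
  out <- list(`2` = list(), `3` = list())
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    fit <- if (row$model == "power") {
      power_fit_from_coef(row$A, row$B, row$C)
    } else {
      linear_fit_from_coef(row$P1, row$P2)
    }
    out[[as.character(row$n_springs)]][[row$parameter]] <- fit
  }
  out
}
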