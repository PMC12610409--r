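#' Canonical one-at-a-time sweep grids
#'
#' The study grids: elastic modulus 100-3000 MPa in 100 MPa steps,
#' thickness 2-4 mm in 0.2 mm steps, spring position 10-40 mm in 3 mm
#' steps, osteotomy size 10-20 mm in 2 mm steps, the three catalogue
#' spring stiffnesses, and two or three springs.
#'
#' @param parameter One of `"E"`, `"t"`, `"SP"`, `"OS"`, `"k"`,
#'   `"n_springs"`.
#' @return Numeric grid for that parameter.
#' @export
canonical_grid <- function(parameter) {
  switch(match.arg(parameter, c("E", "t", "SP", "OS", "k", "n_springs")),
         E = seq(100, 3000, by = 100),
         t = seq(2, 4, by = 0.2),
         SP = seq(10, 40, by = 3),
         OS = seq(10, 20, by = 2),
         k = c(0.17, 0.39, 0.69),
         n_springs = c(2, 3))
}

# configuration field touched by each sweep parameter
sweep_field <- c(E = "E_MPa", t = "t_mm", SP = "SP_mm", OS = "OS_mm",
                 k = "k_Nmm", n_springs = "n_springs")

#' Plan a one-at-a-time parameter sweep
#'
#' One parameter is varied over its grid while all others are held at
#' the control configuration.
#'
#' @param parameter Parameter to vary (see [canonical_grid()]).
#' @param n_springs Number of springs held in the configuration (ignored
#'   when `parameter = "n_springs"`).
#' @param control Control configuration ([control_parameters()]).
#' @param grid Sweep grid; defaults to the canonical study grid.  A
#'   reduced grid may be supplied for scaled-down runs.
#'
#' @return Object of class `sweep_plan`.
#' @export
sweep_plan <- function(parameter, n_springs = 2L,
                       control = control_parameters(), grid = NULL) {
  parameter <- match.arg(parameter, names(sweep_field))
  if (is.null(grid)) grid <- canonical_grid(parameter)
  if (any(diff(grid) <= 0)) stop("sweep grid must be strictly increasing")
  control$n_springs <- as.integer(n_springs)
  structure(list(parameter = parameter, grid = grid, control = control),
            class = "sweep_plan")
}

#' Run a one-at-a-time sweep
#'
#' Runs one independent [simulate_case()] per grid point, in grid order.
#' Per-point failures are recorded as rows with status `"error"` and the
#' sweep continues.  When `out_csv` is given, completed rows found in an
#' existing file are reused, making long sweeps resumable; the file is
#' rewritten after each new row.
#'
#' @param plan A [sweep_plan()].
#' @param out_csv Optional path of the CSV result store.
#' @param quiet Suppress per-point progress messages.
#'
#' @return A data frame of class `sweep_result`: one row per grid point
#'   with the varied value, `n_springs`, `delta_CI`, the full
#'   configuration echo, mean spring opening, maximum displacement and a
#'   status column.  Attribute `partial_failure` flags failed points.
#' @export
run_oat_sweep <- function(plan, out_csv = NULL, quiet = TRUE) {
  stopifnot(inherits(plan, "sweep_plan"))
  field <- sweep_field[[plan$parameter]]
  prev <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv)
    if (!all(c("parameter", "value", "status") %in% names(prev)))
      stop("existing out_csv is not a sweep result store: ", out_csv)
    prev <- prev[prev$parameter == plan$parameter, , drop = FALSE]
  }
  rows <- vector("list", length(plan$grid))
  for (g in seq_along(plan$grid)) {
    val <- plan$grid[g]
    if (!is.null(prev)) {
      hit <- which(abs(prev$value - val) < 1e-9 & prev$status == "ok")
      if (length(hit)) {
        rows[[g]] <- prev[hit[1], , drop = FALSE]
        next
      }
    }
    cfg <- plan$control
    cfg[[field]] <- if (field == "n_springs") as.integer(val) else val
    row <- tryCatch({
      res <- simulate_case(cfg)
      data.frame(parameter = plan$parameter, value = val,
                 n_springs = cfg$n_springs, delta_CI = res$delta_CI,
                 E_MPa = cfg$E_MPa, nu = cfg$nu, t_mm = cfg$t_mm,
                 SP_mm = cfg$SP_mm, OS_mm = cfg$OS_mm, k_Nmm = cfg$k_Nmm,
                 free_length_mm = cfg$free_length_mm,
                 resolution = cfg$resolution,
                 mean_opening_mm = mean(res$spring_openings_mm),
                 max_displacement_mm = max(abs(res$displacement)),
                 status = "ok")
    }, error = function(e) {
      data.frame(parameter = plan$parameter, value = val,
                 n_springs = cfg$n_springs, delta_CI = NA_real_,
                 E_MPa = cfg$E_MPa, nu = cfg$nu, t_mm = cfg$t_mm,
                 SP_mm = cfg$SP_mm, OS_mm = cfg$OS_mm, k_Nmm = cfg$k_Nmm,
                 free_length_mm = cfg$free_length_mm,
                 resolution = cfg$resolution,
                 mean_opening_mm = NA_real_, max_displacement_mm = NA_real_,
                 status = paste0("error: ", conditionMessage(e)))
    })
    rows[[g]] <- row
    if (!quiet)
      message(sprintf("%s = %g (%d springs): delta_CI = %s",
                      plan$parameter, val, cfg$n_springs,
                      format(row$delta_CI)))
    if (!is.null(out_csv))
      utils::write.csv(do.call(rbind, rows[!vapply(rows, is.null,
                                                   logical(1))]),
                       out_csv, row.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "partial_failure") <- any(out$status != "ok")
  out
}

#' Mixed spring-diameter study
#'
#' Reproduces the spring-diameter comparison: one panel varies the
#' anterior spring over the three wire diameters with the posterior
#' fixed at 1.2 mm, the other varies the posterior with the anterior
#' fixed at 1.2 mm.  Both are run with two and three springs; the middle
#' spring of three-spring cases is always 1.2 mm.
#'
#' @param control Control configuration.
#' @param diameters Wire diameters to vary (default the catalogue set).
#'
#' @return Data frame with panel, anterior/posterior diameters, spring
#'   count and `delta_CI`.
#' @export
spring_variant_study <- function(control = control_parameters(),
                                 diameters = c(1.0, 1.2, 1.4)) {
  rows <- list()
  for (ns in c(2L, 3L)) {
    for (panel in c("vary_anterior", "vary_posterior")) {
      for (d in diameters) {
        d_ant <- if (panel == "vary_anterior") d else 1.2
        d_post <- if (panel == "vary_posterior") d else 1.2
        dias <- if (ns == 2L) c(d_ant, d_post) else c(d_ant, 1.2, d_post)
        cfg <- control
        cfg$n_springs <- ns
        cfg$spring_stiffness_Nmm <- spring_stiffness_from_diameter(dias)
        res <- simulate_case(cfg)
        rows[[length(rows) + 1L]] <-
          data.frame(panel = panel, anterior_mm = d_ant,
                     posterior_mm = d_post, n_springs = ns,
                     delta_CI = res$delta_CI)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
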