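#' Control values of the simulation parameters
#'
#' Returns the full configuration used as the control point of the
#' one-at-a-time study: calvarial bone elastic modulus `E` = 421 MPa and
#' Poisson ratio 0.22, shell thickness `t` = 2 mm, spring position
#' `SP` = 34 mm, osteotomy size `OS` = 20 mm, spring stiffness
#' `k` = 0.39 N/mm and two springs.  The spring free length (60 mm) and
#' mesh resolution are modelling choices recorded with every result.
#'
#' @param ... Named overrides of any configuration field.
#' @return Object of class `sac_config`.
#' @export
control_parameters <- function(...) {
  cfg <- list(E_MPa = 421, nu = 0.22, t_mm = 2, SP_mm = 34, OS_mm = 20,
              k_Nmm = 0.39, n_springs = 2L, free_length_mm = 60,
              resolution = 16L,
              E_fibrous_MPa = 16, nu_fibrous = 0.49,
              length_mm = 165, breadth_mm = 116, height_mm = 87,
              suture_width_mm = 2,
              spring_stiffness_Nmm = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$n_springs <- as.integer(cfg$n_springs)
  cfg$resolution <- as.integer(cfg$resolution)
  structure(cfg, class = "sac_config")
}

#' Validate a simulation configuration against the study ranges
#'
#' @param config A `sac_config` list.
#' @return The validated configuration, invisibly.
#' @export
validate_config <- function(config) {
  c_ <- config
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  chk(is.finite(c_$E_MPa) && c_$E_MPa >= 100 && c_$E_MPa <= 3000,
      "E_MPa must lie in [100, 3000] MPa")
  chk(c_$nu >= 0 && c_$nu < 0.5, "nu must lie in [0, 0.5)")
  chk(c_$t_mm >= 2 && c_$t_mm <= 4, "t_mm must lie in [2, 4] mm")
  chk(c_$SP_mm >= 10 && c_$SP_mm <= 40, "SP_mm must lie in [10, 40] mm")
  chk(c_$OS_mm >= 10 && c_$OS_mm <= 20, "OS_mm must lie in [10, 20] mm")
  chk(c_$k_Nmm > 0, "k_Nmm must be positive")
  chk(c_$n_springs %in% c(2L, 3L), "n_springs must be 2 or 3")
  chk(c_$free_length_mm > c_$OS_mm,
      "free_length_mm must exceed the osteotomy width")
  if (!isTRUE(any(abs(c_$k_Nmm - c(0.17, 0.39, 0.69)) < 1e-9)))
    warning("k_Nmm is not one of the catalogue stiffnesses ",
            "0.17, 0.39, 0.69 N/mm")
  invisible(config)
}

#' Simulate one spring-assisted cranioplasty case
#'
#' Orchestrates the full forward model for one parameter configuration:
#' generate the parametric skull, remove the midline osteotomy strip,
#' place the springs, assemble the finite-element system and solve for
#' equilibrium, then measure the change in cranial index.  `delta_CI` is
#' reported in CI points (100 x the change in breadth / length) relative
#' to the intact pre-operative skull.
#'
#' @param config A [control_parameters()] configuration; individual
#'   fields can also be overridden through `...`.
#' @param ... Named overrides applied on top of `config`.
#' @param validate Check parameters against the study ranges (default
#'   TRUE).
#'
#' @return A `simulation_result` (see [solve_with_springs()]) whose
#'   baseline dimensions are those of the intact skull, with the
#'   configuration attached as attribute `config`.
#' @export
simulate_case <- function(config = control_parameters(), ...,
                          validate = TRUE) {
  if (!inherits(config, "sac_config"))
    config <- do.call(control_parameters, as.list(config))
  dots <- list(...)
  if (length(dots)) config[names(dots)] <- dots
  if (validate) validate_config(config)

  params <- skull_geometry_params(
    length_mm = config$length_mm, breadth_mm = config$breadth_mm,
    height_mm = config$height_mm, thickness_mm = config$t_mm,
    suture_width_mm = config$suture_width_mm,
    osteotomy_mm = config$OS_mm, mesh_resolution = config$resolution)
  full <- generate_skull(params)
  baseline <- measure_cranial_dimensions(full)
  cut <- apply_osteotomy(full, config$OS_mm)
  sites <- locate_spring_sites(cut, config$SP_mm, config$n_springs)

  kvec <- config$spring_stiffness_Nmm
  if (is.null(kvec)) kvec <- rep(config$k_Nmm, config$n_springs)
  if (length(kvec) != length(sites))
    stop("spring_stiffness_Nmm must supply one stiffness per spring")

  mats <- material_map(E_bone = config$E_MPa, nu_bone = config$nu,
                       E_fibrous = config$E_fibrous_MPa,
                       nu_fibrous = config$nu_fibrous)
  system <- assemble_stiffness(cut, mats)
  res <- solve_with_springs(system, sites, stiffness_Nmm = kvec,
                            free_length_mm = config$free_length_mm)
  # delta CI is reported against the intact pre-operative skull
  res$baseline <- baseline
  res$delta_CI <- 100 * (res$deformed$cranial_index -
                           baseline$cranial_index)
  attr(res, "config") <- config
  res
}
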