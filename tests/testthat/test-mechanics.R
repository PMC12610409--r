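test_that("a unit cube element reproduces the closed-form bar stiffness", {
  cube <- make_block_mesh(1, 1, 1)
  sys <- assemble_stiffness(cube, material_map(E_bone = 1, nu_bone = 0))
  top <- which(cube$nodes[, 3] == 1)
  bot <- which(cube$nodes[, 3] == 0)
  fixed <- c(all_dofs(bot), 3L * top)
  vals <- c(rep(0, 3 * length(bot)), rep(1e-3, length(top)))
  u <- solve_linear_system(sys$K, numeric(sys$ndof), fixed, vals)
  # axial reaction = E * A / L * delta = 1 * 1 / 1 * 1e-3
  reac <- as.numeric(sys$K %*% u)
  expect_equal(sum(reac[3L * top]), 1e-3, tolerance = 1e-10)
})

test_that("assembled stiffness is symmetric with a rigid-body null space", {
  mesh <- generate_skull(skull_geometry_params(mesh_resolution = 12))
  sys <- assemble_stiffness(mesh, material_map())
  expect_identical(max(abs(sys$K - Matrix::t(sys$K))), 0)
  kscale <- max(abs(sys$K))
  # three translations
  for (dir in 1:3) {
    u <- rep(0, sys$ndof)
    u[seq(dir, sys$ndof, by = 3)] <- 1
    expect_lt(max(abs(sys$K %*% u)) / kscale, 1e-8)
  }
  # three linearised rotations u = omega x X
  X <- mesh$nodes
  rots <- list(cbind(0, -X[, 3], X[, 2]),
               cbind(X[, 3], 0, -X[, 1]),
               cbind(-X[, 2], X[, 1], 0))
  for (r in rots) {
    u <- as.vector(t(r))
    expect_lt(max(abs(sys$K %*% u)) / (kscale * max(abs(X))), 1e-8)
  }
})

test_that("the element formulation passes a linear patch test", {
  mesh <- make_block_mesh(2, 2, 2, jitter = 0.07)
  sys <- assemble_stiffness(mesh, material_map(E_bone = 421, nu_bone = 0.3))
  A <- matrix(c(1e-3, 2e-4, 0, 0, -5e-4, 1e-4, 3e-4, 0, 8e-4), 3, 3)
  u_exact <- mesh$nodes %*% t(A)
  onb <- which(mesh$nodes[, 1] %in% c(0, 1) | mesh$nodes[, 2] %in% c(0, 1) |
                 mesh$nodes[, 3] %in% c(0, 1))
  u <- solve_linear_system(sys$K, numeric(sys$ndof), all_dofs(onb),
                           as.vector(t(u_exact[onb, ])))
  expect_lt(max(abs(matrix(u, ncol = 3, byrow = TRUE) - u_exact)), 1e-10)
})

test_that("inverted elements are rejected at assembly", {
  mesh <- make_block_mesh(1, 1, 1)
  mesh$nodes[8, 3] <- -2  # fold the cube through itself
  expect_error(assemble_stiffness(mesh, material_map()),
               "non-positive Jacobian")
})

test_that("solver matches the two-block spring oracle to 1e-8", {
  # two bodies grounded through scalar stiffness k_s, joined by a spring
  # (k, pre-compression delta0): opening = k * delta0 / (k_s / 2 + k)
  ks <- 5; k <- 0.39; d <- 20; L0 <- 60
  K <- Matrix::sparseMatrix(i = 1:12, j = 1:12, x = rep(1, 12))
  K[2, 2] <- ks  # node 1, y
  K[5, 5] <- ks  # node 2, y
  fake <- structure(list(K = K, ndof = 12L,
                         mesh = list(nodes = rbind(c(0, -d / 2, 0),
                                                   c(0, d / 2, 0),
                                                   c(0, 0, -50),
                                                   c(0, 0, -60)),
                                     elements = matrix(integer(0), 0, 8))),
                    class = "fe_system")
  sites <- structure(list(list(
    arc_mm = 0,
    right = list(nodes = c(2L, 2L), weights = c(1, 0),
                 point = c(0, d / 2, 0)),
    left = list(nodes = c(1L, 1L), weights = c(1, 0),
                point = c(0, -d / 2, 0)))), class = "spring_sites")
  res <- solve_with_springs(fake, sites, stiffness_Nmm = k,
                            free_length_mm = L0, fixed_nodes = c(3L, 4L))
  expect_equal(res$spring_openings_mm, k * (L0 - d) / (ks / 2 + k),
               tolerance = 1e-8)
  expect_equal(res$residual_spring_forces_N,
               k * ((L0 - d) - res$spring_openings_mm), tolerance = 1e-10)
})

test_that("zero pre-compression yields zero displacement", {
  mesh <- apply_osteotomy(generate_skull(
    skull_geometry_params(mesh_resolution = 12)))
  sites <- locate_spring_sites(mesh, 34, 2)
  sep <- sqrt(sum((sites$anterior$right$point -
                     sites$anterior$left$point)^2))
  sys <- assemble_stiffness(mesh, material_map())
  res <- solve_with_springs(sys, sites, stiffness_Nmm = 0.39,
                            free_length_mm = sep)
  expect_lt(max(abs(res$displacement)), 1e-9)
})

test_that("displacements scale inversely with a uniform stiffness scaling", {
  mesh <- apply_osteotomy(generate_skull(
    skull_geometry_params(mesh_resolution = 12)))
  sys1 <- assemble_stiffness(mesh, material_map())
  sys2 <- assemble_stiffness(mesh, material_map(E_bone = 2 * 421,
                                                E_fibrous = 2 * 16))
  load_node <- mesh$grid$id[mesh$grid$st_par[2], mesh$grid$i_cut[2], 1]
  loads <- matrix(c(load_node, 0, 5, 0), 1)
  # pure force loading through a spring of negligible stiffness
  sites <- locate_spring_sites(mesh, 34, 2)
  sep <- sqrt(sum((sites$anterior$right$point -
                     sites$anterior$left$point)^2))
  u1 <- solve_with_springs(sys1, sites, stiffness_Nmm = 1e-12,
                           free_length_mm = sep,
                           point_loads = loads)$displacement
  u2 <- solve_with_springs(sys2, sites, stiffness_Nmm = 1e-12,
                           free_length_mm = sep,
                           point_loads = loads)$displacement
  expect_equal(u2, u1 / 2, tolerance = 1e-8)
})

test_that("springs load the skull as internal force pairs (zero net reaction)", {
  res <- simulate_case(control_parameters(resolution = 12))
  total_force <- sum(res$stiffness_Nmm * res$spring_precompression_mm)
  expect_lt(max(abs(res$net_base_reaction_N)), 1e-6 * total_force)
})

test_that("the control case expands the skull and known orderings hold", {
  ctl <- simulate_case(control_parameters(resolution = 12))
  expect_gt(ctl$delta_CI, 0)
  expect_true(all(ctl$spring_openings_mm > 0))
  expect_true(all(ctl$spring_openings_mm <= ctl$free_length_mm))
  expect_true(all(ctl$residual_spring_forces_N >= 0))
  soft <- simulate_case(control_parameters(E_MPa = 300, resolution = 12))
  expect_gt(soft$delta_CI, ctl$delta_CI)
  three <- simulate_case(control_parameters(n_springs = 3, resolution = 12))
  expect_gt(three$delta_CI, ctl$delta_CI)
})

test_that("swapping anterior and posterior wire diameters barely matters", {
  a <- simulate_case(control_parameters(
    resolution = 12,
    spring_stiffness_Nmm = spring_stiffness_from_diameter(c(1.4, 1.2))))
  b <- simulate_case(control_parameters(
    resolution = 12,
    spring_stiffness_Nmm = spring_stiffness_from_diameter(c(1.2, 1.4))))
  expect_lt(abs(a$delta_CI - b$delta_CI) / mean(c(a$delta_CI, b$delta_CI)),
            0.10)
})

test_that("configuration validation guards the study ranges", {
  expect_error(validate_config(control_parameters(E_MPa = -1)), "E_MPa")
  expect_error(validate_config(control_parameters(E_MPa = 5000)), "E_MPa")
  expect_error(validate_config(control_parameters(t_mm = 5)), "t_mm")
  expect_error(validate_config(control_parameters(n_springs = 4)),
               "n_springs")
  expect_error(validate_config(control_parameters(free_length_mm = 15)),
               "free_length")
  expect_warning(validate_config(control_parameters(k_Nmm = 0.5)),
                 "catalogue")
  expect_error(spring_stiffness_from_diameter(1.1), "must be one of")
  expect_identical(spring_stiffness_from_diameter(c(1, 1.2, 1.4)),
                   c(0.17, 0.39, 0.69))
})
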