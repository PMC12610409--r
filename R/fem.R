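#' Per-region elastic material map
#'
#' Isotropic linear-elastic properties per skull region.  Bone plates
#' (frontal, parietals, occipital) share one modulus/Poisson pair;
#' fibrous regions (sutures, fontanelle) share another.  Infant
#' calvarial bone is orders of magnitude stiffer than the fibrous
#' tissue, which is nearly incompressible.
#'
#' @param E_bone,nu_bone Elastic modulus (MPa) and Poisson ratio of the
#'   calvarial bone plates.
#' @param E_fibrous,nu_fibrous Properties of sutures and fontanelle.
#'
#' @return Object of class `material_map`: per-region `E` and `nu`.
#' @export
material_map <- function(E_bone = 421, nu_bone = 0.22,
                         E_fibrous = 16, nu_fibrous = 0.49) {
  if (E_bone <= 0 || E_fibrous <= 0)
    stop("elastic moduli must be strictly positive")
  if (any(c(nu_bone, nu_fibrous) < 0) || any(c(nu_bone, nu_fibrous) >= 0.5))
    stop("Poisson ratios must lie in [0, 0.5)")
  regs <- skull_regions()
  fib <- c("coronal_suture", "lambdoid_suture", "anterior_fontanelle")
  E <- ifelse(regs %in% fib, E_fibrous, E_bone)
  nu <- ifelse(regs %in% fib, nu_fibrous, nu_bone)
  names(E) <- names(nu) <- regs
  structure(list(E = E, nu = nu), class = "material_map")
}

# trilinear hexahedron: signs of the 8 corner nodes
.hex_signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                       -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                     ncol = 3, byrow = TRUE)

# shape-function derivatives wrt (xi, eta, zeta): 3 x 8
hex_dN <- function(xi, eta, zeta) {
  s <- .hex_signs
  rbind(s[, 1] * (1 + eta * s[, 2]) * (1 + zeta * s[, 3]),
        s[, 2] * (1 + xi * s[, 1]) * (1 + zeta * s[, 3]),
        s[, 3] * (1 + xi * s[, 1]) * (1 + eta * s[, 2])) / 8
}

# 2x2x2 Gauss points and precomputed parent-space derivatives
.hex_quad <- local({
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g),
                               zeta = c(-g, g)))
  list(pts = pts,
       dN = lapply(seq_len(8), function(k)
         hex_dN(pts[k, 1], pts[k, 2], pts[k, 3])))
})

# isotropic 6x6 elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx)
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement matrix (6 x 24) from nodal gradients G (3 x 8)
hex_B <- function(G) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- G[1, ]; B[2, ix + 1] <- G[2, ]; B[3, ix + 2] <- G[3, ]
  B[4, ix] <- G[2, ]; B[4, ix + 1] <- G[1, ]
  B[5, ix + 1] <- G[3, ]; B[5, ix + 2] <- G[2, ]
  B[6, ix] <- G[3, ]; B[6, ix + 2] <- G[1, ]
  B
}

# dilatational part of B from nodal gradients G (3 x 8)
hex_Bdil <- function(G) {
  row <- numeric(24)
  ix <- 3 * (1:8) - 2
  row[ix] <- G[1, ]; row[ix + 1] <- G[2, ]; row[ix + 2] <- G[3, ]
  B <- matrix(0, 6, 24)
  B[1, ] <- B[2, ] <- B[3, ] <- row / 3
  B
}

# element stiffness of one trilinear hex with mean-dilatation B-bar
# (selective reduced integration of the volumetric part, which controls
# locking in the thin, nearly incompressible regions)
hex_stiffness <- function(X, D) {
  q <- .hex_quad
  Gs <- vector("list", 8)
  detJs <- numeric(8)
  for (k in 1:8) {
    dN <- q$dN[[k]]
    J <- dN %*% X
    dJ <- det(J)
    if (!is.finite(dJ) || dJ <= 0) return(NULL)
    Gs[[k]] <- solve(J, dN)
    detJs[k] <- dJ
  }
  V <- sum(detJs)
  Gbar <- Reduce(`+`, Map(`*`, Gs, detJs)) / V
  Bdil_bar <- hex_Bdil(Gbar)
  K <- matrix(0, 24, 24)
  for (k in 1:8) {
    B <- hex_B(Gs[[k]]) - hex_Bdil(Gs[[k]]) + Bdil_bar
    K <- K + detJs[k] * crossprod(B, D %*% B)
  }
  K
}

#' Assemble the global linear-elastic stiffness matrix
#'
#' Assembles 8-node trilinear hexahedra with mean-dilatation selective
#' reduced integration over the labelled skull mesh.  The returned
#' matrix is symmetric and, before constraints, positive semi-definite
#' with exactly the six rigid-body null modes.
#'
#' @param mesh A `skull_mesh` (degenerate wedge hexahedra closing the
#'   poles are supported; truly inverted elements are rejected).
#' @param materials A [material_map()].
#'
#' @return Object of class `fe_system`: sparse symmetric stiffness `K`
#'   (3 dofs per node, interleaved x/y/z), the mesh and the materials.
#' @export
assemble_stiffness <- function(mesh, materials = material_map()) {
  stopifnot(inherits(mesh, "skull_mesh"), inherits(materials, "material_map"))
  M <- nrow(mesh$elements)
  Dcache <- lapply(skull_regions(), function(r)
    elastic_D(materials$E[[r]], materials$nu[[r]]))
  names(Dcache) <- skull_regions()
  reg <- as.character(mesh$region)

  ii <- integer(M * 576L); jj <- integer(M * 576L); xx <- numeric(M * 576L)
  pos <- 0L
  for (e in seq_len(M)) {
    en <- mesh$elements[e, ]
    Ke <- hex_stiffness(mesh$nodes[en, , drop = FALSE], Dcache[[reg[e]]])
    if (is.null(Ke))
      stop("degenerate or inverted element (non-positive Jacobian) at ",
           "element ", e)
    idx <- rep(3L * en, each = 3L) + c(-2L, -1L, 0L)
    ii[pos + 1:576] <- rep(idx, times = 24L)
    jj[pos + 1:576] <- rep(idx, each = 24L)
    xx[pos + 1:576] <- as.vector(Ke)
    pos <- pos + 576L
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, ndof = ndof, mesh = mesh, materials = materials),
            class = "fe_system")
}

#' Solve a constrained linear system with prescribed displacements
#'
#' Eliminates the fixed degrees of freedom and solves the remaining
#' sparse symmetric system by a direct factorisation (deterministic).
#'
#' @param K Sparse symmetric stiffness matrix.
#' @param f Load vector (length `nrow(K)`).
#' @param fixed_dofs Integer indices of constrained dofs.
#' @param fixed_values Prescribed values (recycled; default 0).
#'
#' @return Full displacement vector.
#' @export
solve_linear_system <- function(K, f, fixed_dofs, fixed_values = 0) {
  ndof <- nrow(K)
  fixed_dofs <- as.integer(fixed_dofs)
  if (length(fixed_dofs) == 0L)
    stop("singular system: no constraints supplied")
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- numeric(ndof)
  u[fixed_dofs] <- rep_len(fixed_values, length(fixed_dofs))
  rhs <- f[free] - as.numeric(K[free, fixed_dofs, drop = FALSE] %*%
                                u[fixed_dofs])
  sol <- tryCatch(
    Matrix::solve(K[free, free, drop = FALSE], rhs),
    error = function(e)
      stop("singular system: insufficient constraints (", conditionMessage(e),
           ")"))
  u[free] <- as.numeric(sol)
  u
}

#' Spring stiffness from wire diameter
#'
#' Distraction springs come in three wire diameters with catalogue
#' stiffnesses: 1.0 mm -> 0.17 N/mm, 1.2 mm -> 0.39 N/mm,
#' 1.4 mm -> 0.69 N/mm.
#'
#' @param diameter_mm Wire diameter, one of 1.0, 1.2, 1.4.
#' @return Spring stiffness in N/mm.
#' @export
spring_stiffness_from_diameter <- function(diameter_mm) {
  dia <- c(1.0, 1.2, 1.4)
  k <- c(0.17, 0.39, 0.69)
  out <- vapply(diameter_mm, function(d) {
    m <- which(abs(dia - d) < 1e-9)
    if (length(m) != 1L)
      stop("wire diameter must be one of 1.0, 1.2, 1.4 mm")
    k[m]
  }, numeric(1))
  out
}

#' Solve skull equilibrium under pre-compressed distraction springs
#'
#' Each spring joins one attachment point on each osteotomy face.  It
#' contributes (a) a rank-one axial stiffness `k` along its initial axis
#' and (b) an equal-and-opposite force pair of magnitude
#' `k * (free_length - initial separation)` pushing the attachments
#' apart (the spring is inserted compressed).  Springs are linearised
#' about the inserted state: the axis stays at its initial orientation
#' and a single linear solve yields equilibrium.  Attachment points that
#' are embedded on a cut edge distribute their force and stiffness to
#' the bracketing nodes by their interpolation weights.
#'
#' @param system An `fe_system` from [assemble_stiffness()].
#' @param sites A `spring_sites` object from [locate_spring_sites()].
#' @param stiffness_Nmm Spring stiffness, one value per spring (recycled)
#'   in the order of `sites` (anterior, middle if present, posterior).
#' @param free_length_mm Free (uncompressed) spring length; must exceed
#'   the initial attachment separation.
#' @param fixed_nodes Nodes fixed in all three directions; defaults to
#'   the mesh base nodes (the basal rim of the shell).
#' @param point_loads Optional external load matrix with columns
#'   `node`, `fx`, `fy`, `fz` (N), mainly for verification problems.
#'
#' @return Object of class `simulation_result` with the displacement
#'   field (N x 3, mm), baseline and deformed [cranial
#'   dimensions][measure_cranial_dimensions()], `delta_CI` (CI points,
#'   100 x change in cranial index), per-spring openings (mm) and
#'   residual forces (N), and the net base reaction (N).
#' @export
solve_with_springs <- function(system, sites, stiffness_Nmm,
                               free_length_mm = 60,
                               fixed_nodes = NULL, point_loads = NULL) {
  stopifnot(inherits(system, "fe_system"))
  mesh <- system$mesh
  if (is.null(fixed_nodes)) fixed_nodes <- mesh$base_nodes
  if (length(fixed_nodes) == 0L) stop("no fixed nodes supplied")
  n_spring <- length(sites)
  if (n_spring < 1L) stop("at least one spring is required")
  kvec <- rep_len(stiffness_Nmm, n_spring)
  Lvec <- rep_len(free_length_mm, n_spring)

  ndof <- system$ndof
  f <- numeric(ndof)
  gs <- vector("list", n_spring)
  delta0 <- numeric(n_spring)
  K <- system$K
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(n_spring)) {
    site <- sites[[s]]
    d_vec <- site$right$point - site$left$point
    sep <- sqrt(sum(d_vec^2))
    axis <- d_vec / sep
    if (Lvec[s] < sep - 1e-9)
      stop(sprintf("spring %d free length (%.1f mm) is below the initial
attachment separation (%.1f mm): spring must be inserted compressed",
                   s, Lvec[s], sep))
    delta0[s] <- max(0, Lvec[s] - sep)
    nodes <- c(site$right$nodes, site$left$nodes)
    wts <- c(site$right$weights, -site$left$weights)
    gdof <- as.vector(vapply(nodes, function(n) 3L * n + c(-2L, -1L, 0L),
                             integer(3)))
    gval <- as.vector(vapply(seq_along(nodes),
                             function(m) wts[m] * axis, numeric(3)))
    gs[[s]] <- list(dof = gdof, val = gval)
    # rank-one axial stiffness k * g g'
    ii <- c(ii, rep(gdof, times = length(gdof)))
    jj <- c(jj, rep(gdof, each = length(gdof)))
    xx <- c(xx, kvec[s] * as.vector(outer(gval, gval)))
    # pre-compression force pair pushing the attachments apart
    # (accumulate entry-wise: gdof may contain repeated dofs)
    for (q in seq_along(gdof))
      f[gdof[q]] <- f[gdof[q]] + kvec[s] * delta0[s] * gval[q]
  }
  Kadd <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Ktot <- Matrix::forceSymmetric(K + (Kadd + Matrix::t(Kadd)) / 2)

  if (!is.null(point_loads)) {
    pl <- as.matrix(point_loads)
    for (r in seq_len(nrow(pl))) {
      n <- as.integer(pl[r, 1])
      f[3L * n + (-2L:0L)] <- f[3L * n + (-2L:0L)] + pl[r, 2:4]
    }
  }

  fixed_dofs <- as.vector(vapply(as.integer(fixed_nodes),
                                 function(n) 3L * n + c(-2L, -1L, 0L),
                                 integer(3)))
  u <- solve_linear_system(Ktot, f, fixed_dofs)
  U <- matrix(u, ncol = 3, byrow = TRUE)

  openings <- vapply(gs, function(g) sum(g$val * u[g$dof]), numeric(1))
  residual <- kvec * (delta0 - openings)
  reac <- as.numeric(Ktot %*% u - f)
  net_reaction <- colSums(matrix(reac[fixed_dofs], ncol = 3, byrow = TRUE))

  # morphometry only for full skull meshes; bare verification systems
  # (e.g. the two-block spring oracle) carry no outer surface
  if (!is.null(mesh$outer_nodes) && nrow(mesh$elements) > 0L) {
    baseline <- measure_cranial_dimensions(mesh)
    deformed <- measure_cranial_dimensions(mesh, U)
    dci <- 100 * (deformed$cranial_index - baseline$cranial_index)
  } else {
    baseline <- deformed <- NULL
    dci <- NA_real_
  }
  structure(list(
    displacement = U,
    baseline = baseline, deformed = deformed,
    delta_CI = dci,
    spring_openings_mm = openings,
    spring_precompression_mm = delta0,
    residual_spring_forces_N = residual,
    net_base_reaction_N = net_reaction,
    stiffness_Nmm = kvec, free_length_mm = Lvec,
    mesh = mesh), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Spring-assisted cranioplasty simulation\n")
  cat(sprintf("  springs: %d (k = %s N/mm, free length %s mm)\n",
              length(x$spring_openings_mm),
              paste(format(x$stiffness_Nmm), collapse = "/"),
              paste(unique(format(x$free_length_mm)), collapse = "/")))
  cat(sprintf("  spring openings: %s mm\n",
              paste(sprintf("%.2f", x$spring_openings_mm), collapse = ", ")))
  if (!is.null(x$baseline))
    cat(sprintf("  baseline CI %.4f -> deformed CI %.4f (delta CI %+.3f points)\n",
                x$baseline$cranial_index, x$deformed$cranial_index,
                x$delta_CI))
  invisible(x)
}
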