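#' Region labels used on the skull mesh
#'
#' The calvarial shell is partitioned into four bone plates and three
#' fibrous regions (two suture bands and the anterior fontanelle).
#'
#' @return Character vector of the seven region labels.
#' @export
skull_regions <- function() {
  c("frontal", "parietal_left", "parietal_right", "occipital",
    "coronal_suture", "lambdoid_suture", "anterior_fontanelle")
}

#' Parameters of the parametric synostotic skull
#'
#' Defines the idealised scaphocephalic calvarium: an ellipsoid-like shell
#' of uniform thickness, truncated by the basal plane `z = 0`, with
#' transverse coronal and lambdoid suture bands, an anterior fontanelle
#' patch at bregma, and a fused (bony) sagittal midline.  The default
#' outer dimensions give a long, narrow head with cranial index near
#' 0.70, typical of sagittal synostosis around five months of age.
#'
#' The coordinate frame is right-handed, in millimetres: `x`
#' anterior-posterior (anterior positive), `y` lateral, `z`
#' inferior-superior with the basal cut plane at `z = 0` and the
#' mid-sagittal plane at `y = 0`.
#'
#' @param length_mm Outer anterior-posterior extent (mm).
#' @param breadth_mm Maximal outer lateral extent (mm).
#' @param height_mm Base-plane to vertex distance (mm).
#' @param thickness_mm Uniform calvarial shell thickness `t` (mm).
#' @param suture_width_mm Width of the coronal and lambdoid fibrous
#'   bands (mm).  Each band is meshed as exactly one element column, so
#'   any resolution resolves it.
#' @param osteotomy_mm Planned lateral width `OS` of the midline strip
#'   to be removed (mm).  The mesh is generated with element seams at
#'   `y = +/- OS/2` so the osteotomy cut is geometry-conforming.
#' @param mesh_resolution Elements along each parametric direction
#'   (minimum 8).  Controls both the number of rings around the
#'   anterior-posterior axis and the number of stations along it.
#' @param base_offset_mm Height of the ellipsoid equator above the basal
#'   cut plane.  A positive offset places the widest point of the skull
#'   above the (fixed) base, as in a real head.
#' @param fontanelle_radius_mm Radius of the anterior fontanelle patch
#'   centred at bregma (mm).
#' @param coronal_frac,lambdoid_frac Positions of the suture band
#'   centrelines along the anterior-posterior semi-axis, as signed
#'   fractions of `length_mm / 2`.
#' @param layers Number of element layers through the shell thickness.
#'
#' @return An object of class `skull_geometry_params`.
#' @export
skull_geometry_params <- function(length_mm = 165, breadth_mm = 116,
                                  height_mm = 87, thickness_mm = 2,
                                  suture_width_mm = 2, osteotomy_mm = 20,
                                  mesh_resolution = 24L,
                                  base_offset_mm = 15,
                                  fontanelle_radius_mm = 10,
                                  coronal_frac = 0.42,
                                  lambdoid_frac = -0.60,
                                  layers = 1L) {
  p <- list(length_mm = length_mm, breadth_mm = breadth_mm,
            height_mm = height_mm, thickness_mm = thickness_mm,
            suture_width_mm = suture_width_mm, osteotomy_mm = osteotomy_mm,
            mesh_resolution = as.integer(mesh_resolution),
            base_offset_mm = base_offset_mm,
            fontanelle_radius_mm = fontanelle_radius_mm,
            coronal_frac = coronal_frac, lambdoid_frac = lambdoid_frac,
            layers = as.integer(layers))
  lens <- c(p$length_mm, p$breadth_mm, p$height_mm, p$thickness_mm,
            p$suture_width_mm, p$osteotomy_mm)
  if (any(!is.finite(unlist(p[1:12]))) || any(lens <= 0))
    stop("all skull dimensions must be finite and strictly positive")
  if (p$thickness_mm >= p$breadth_mm / 10)
    stop("thickness_mm must be small compared to breadth_mm (thin shell)")
  if (p$osteotomy_mm >= p$breadth_mm / 2)
    stop("osteotomy_mm must be less than half the skull breadth")
  if (p$mesh_resolution < 8L)
    stop("mesh_resolution must be at least 8")
  if (p$layers < 1L)
    stop("layers must be at least 1")
  if (p$base_offset_mm <= 0 || p$base_offset_mm >= p$height_mm / 2)
    stop("base_offset_mm must lie in (0, height_mm / 2)")
  if (p$coronal_frac <= p$lambdoid_frac)
    stop("coronal suture must lie anterior to the lambdoid suture")
  if (abs(p$coronal_frac) >= 0.9 || abs(p$lambdoid_frac) >= 0.9)
    stop("suture positions must lie well inside the skull length")
  structure(p, class = "skull_geometry_params")
}

# Station (constant-x) cross-section of the outer ellipsoid:
# semi-axes of the (y, z) ellipse and the basal half-opening angle.
ring_geometry <- function(x, a, b, cc, zc) {
  s <- sqrt(max(0, 1 - (x / a)^2))
  b_x <- b * s
  c_x <- cc * s
  psi_b <- acos(max(-1, min(1, -zc / c_x)))
  list(b_x = b_x, c_x = c_x, psi_b = psi_b)
}

#' Generate the parametric synostotic skull mesh
#'
#' Builds a labelled hexahedral shell mesh of the calvarium.  The outer
#' surface is an ellipsoid with the requested length, breadth and height,
#' centred `base_offset_mm` above the basal cut plane; the inner surface
#' is offset inward along the outer normal by the shell thickness.  The
#' mesh is structured: rings around the anterior-posterior axis at a set
#' of stations, with degenerate (wedge) hexahedra closing the frontal and
#' occipital poles.  Ring node distributions place seams exactly at
#' `y = +/- osteotomy_mm / 2` in the parietal region so a later osteotomy
#' is geometry-conforming, and station spacing places each suture band in
#' exactly one element column.  Generation is fully deterministic.
#'
#' @param params A [skull_geometry_params()] object.
#'
#' @return An object of class `skull_mesh`: a list with node coordinates
#'   (`nodes`, N x 3, mm), hexahedral connectivity (`elements`, M x 8),
#'   per-element `region` factor, `base_nodes` (nodes with `z` < 2 mm),
#'   `outer_nodes` (outer-surface node indices), and structured-grid
#'   bookkeeping used by [apply_osteotomy()] and
#'   [locate_spring_sites()].
#' @export
generate_skull <- function(params = skull_geometry_params()) {
  stopifnot(inherits(params, "skull_geometry_params"))
  a  <- params$length_mm / 2
  b  <- params$breadth_mm / 2
  zc <- params$base_offset_mm
  cc <- params$height_mm - zc
  w  <- params$suture_width_mm
  os_half <- params$osteotomy_mm / 2
  res <- params$mesh_resolution
  L   <- params$layers
  thk <- params$thickness_mm

  x_cor <- params$coronal_frac * a
  x_lam <- params$lambdoid_frac * a
  x_base <- a * sqrt(1 - (zc / cc)^2)

  bnd <- c(-x_base, x_lam - w / 2, x_lam + w / 2,
           x_cor - w / 2, x_cor + w / 2, x_base)
  if (any(diff(bnd) <= 0))
    stop("suture bands do not fit inside the skull: ",
         "check suture_width_mm and suture positions")

  seg_len <- diff(bnd)[c(1, 3, 5)]  # occipital, parietal, frontal
  n_seg <- pmax(c(2L, 3L, 2L),
                as.integer(round(res * seg_len / sum(seg_len))))

  xs <- c(seq(bnd[1], bnd[2], length.out = n_seg[1] + 1),
          bnd[3],
          seq(bnd[3], bnd[4], length.out = n_seg[2] + 1)[-1],
          bnd[5],
          seq(bnd[5], bnd[6], length.out = n_seg[3] + 1)[-1])
  n_st <- length(xs)
  n_col <- n_st - 1L

  # Column region codes along x (1-based into skull_regions()).
  col_kind <- c(rep("occipital", n_seg[1]), "lambdoid_suture",
                rep("parietal", n_seg[2]), "coronal_suture",
                rep("frontal", n_seg[3]))
  par_cols <- which(col_kind == "parietal")
  # Stations bounding the parietal segment (cut-edge stations).
  st_par <- seq(min(par_cols), max(par_cols) + 1L)

  # Ring node distribution: symmetric in psi, with nodes exactly at
  # +/- psi_cut (the planned osteotomy seam) and +/- psi_b (base).
  n_in  <- max(4L, 2L * as.integer(round(res / 12)))
  n_out <- max(3L, as.integer(ceiling((res - n_in) / 2)))
  n_psi <- n_in + 2L * n_out

  psi_mat <- matrix(0, n_st, n_psi + 1L)
  ring_bx <- numeric(n_st)
  ring_cx <- numeric(n_st)
  for (j in seq_len(n_st)) {
    rg <- ring_geometry(xs[j], a, b, cc, zc)
    ring_bx[j] <- rg$b_x
    ring_cx[j] <- rg$c_x
    psi_cut <- min(asin(min(os_half / rg$b_x, 0.999)), 0.45 * rg$psi_b)
    half <- c(seq(0, psi_cut, length.out = n_in / 2 + 1),
              seq(psi_cut, rg$psi_b, length.out = n_out + 1)[-1])
    psi_mat[j, ] <- c(-rev(half[-1]), half)
  }
  i_cut_lo <- n_out + 1L              # node index of -psi_cut
  i_cut_hi <- n_out + n_in + 1L       # node index of +psi_cut
  i_mid <- n_out + n_in / 2L + 1L     # node index of psi = 0

  # ---- nodes ---------------------------------------------------------
  n_sheet <- L + 1L
  n_ring_nodes <- n_st * (n_psi + 1L) * n_sheet
  id <- array(seq_len(n_ring_nodes),
              dim = c(n_st, n_psi + 1L, n_sheet))
  nodes <- matrix(0, n_ring_nodes + 2L * n_sheet, 3)

  for (j in seq_len(n_st)) {
    psi <- psi_mat[j, ]
    px <- rep(xs[j], n_psi + 1L)
    py <- ring_bx[j] * sin(psi)
    pz <- zc + ring_cx[j] * cos(psi)
    # outward normal of the outer ellipsoid
    nx <- px / a^2; ny <- py / b^2; nz <- (pz - zc) / cc^2
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
    for (l in seq_len(n_sheet)) {
      d <- thk * (l - 1L) / L
      nodes[id[j, , l], ] <- cbind(px - d * nx, py - d * ny, pz - d * nz)
    }
  }
  # pole nodes: anterior (x = +a) and posterior (x = -a), per sheet
  pole_post <- n_ring_nodes + seq_len(n_sheet)
  pole_ant  <- n_ring_nodes + n_sheet + seq_len(n_sheet)
  for (l in seq_len(n_sheet)) {
    d <- thk * (l - 1L) / L
    nodes[pole_post[l], ] <- c(-(a - d), 0, zc)
    nodes[pole_ant[l], ]  <- c(a - d, 0, zc)
  }

  # ---- elements ------------------------------------------------------
  n_core <- n_col * n_psi * L
  n_cap  <- 2L * n_psi * L
  elements <- matrix(0L, n_core + n_cap, 8)
  einfo <- matrix(0L, n_core + n_cap, 3)  # column, psi band, cap flag
  colnames(einfo) <- c("col", "ipsi", "cap")

  e <- 0L
  for (cl in seq_len(n_col)) {
    for (i in seq_len(n_psi)) {
      for (l in seq_len(L)) {
        e <- e + 1L
        # nodes 1-4 on the deeper sheet (l + 1), 5-8 on the outer (l):
        # gives a right-handed map (x, +psi, outward).
        elements[e, ] <- c(id[cl, i, l + 1L], id[cl + 1L, i, l + 1L],
                           id[cl + 1L, i + 1L, l + 1L], id[cl, i + 1L, l + 1L],
                           id[cl, i, l], id[cl + 1L, i, l],
                           id[cl + 1L, i + 1L, l], id[cl, i + 1L, l])
        einfo[e, ] <- c(cl, i, 0L)
      }
    }
  }
  # posterior cap: fan from pole (x = -a) to the first ring
  for (i in seq_len(n_psi)) {
    for (l in seq_len(L)) {
      e <- e + 1L
      elements[e, ] <- c(pole_post[l + 1L], id[1L, i, l + 1L],
                         id[1L, i + 1L, l + 1L], pole_post[l + 1L],
                         pole_post[l], id[1L, i, l],
                         id[1L, i + 1L, l], pole_post[l])
      einfo[e, ] <- c(0L, i, -1L)
    }
  }
  # anterior cap: reversed ring order to keep the map right-handed
  for (i in seq_len(n_psi)) {
    for (l in seq_len(L)) {
      e <- e + 1L
      elements[e, ] <- c(pole_ant[l + 1L], id[n_st, i + 1L, l + 1L],
                         id[n_st, i, l + 1L], pole_ant[l + 1L],
                         pole_ant[l], id[n_st, i + 1L, l],
                         id[n_st, i, l], pole_ant[l])
      einfo[e, ] <- c(0L, i, 1L)
    }
  }

  # ---- region tags ---------------------------------------------------
  cx_el <- rowMeans(matrix(nodes[elements, 1], nrow(elements)))
  cy_el <- rowMeans(matrix(nodes[elements, 2], nrow(elements)))
  cz_el <- rowMeans(matrix(nodes[elements, 3], nrow(elements)))

  region <- character(nrow(elements))
  core <- einfo[, "cap"] == 0L
  kind <- col_kind[pmax(einfo[, "col"], 1L)]
  region[core & kind == "occipital"] <- "occipital"
  region[core & kind == "frontal"] <- "frontal"
  region[core & kind == "lambdoid_suture"] <- "lambdoid_suture"
  region[core & kind == "coronal_suture"] <- "coronal_suture"
  par <- core & kind == "parietal"
  region[par] <- ifelse(cy_el[par] < 0, "parietal_left", "parietal_right")
  region[einfo[, "cap"] == -1L] <- "occipital"
  region[einfo[, "cap"] == 1L] <- "frontal"

  # anterior fontanelle: patch at bregma, confined to the coronal band
  # so the fibrous patch never bridges the osteotomy strip
  bregma <- c(x_cor, 0, zc + cc * sqrt(1 - (x_cor / a)^2))
  d_bregma <- sqrt((cx_el - bregma[1])^2 + (cy_el - bregma[2])^2 +
                     (cz_el - bregma[3])^2)
  region[region == "coronal_suture" &
           d_bregma <= params$fontanelle_radius_mm] <- "anterior_fontanelle"
  region <- factor(region, levels = skull_regions())

  # basal rim: the node rows on the basal cut boundary (psi = +/- psi_b),
  # a structural set so the constrained boundary does not depend on the
  # parameter values being swept
  base_nodes <- sort(unique(c(as.vector(id[, 1L, ]),
                              as.vector(id[, n_psi + 1L, ]))))
  outer_nodes <- c(as.vector(id[, , 1L]), pole_post[1L], pole_ant[1L])

  structure(list(
    nodes = nodes, elements = elements, region = region,
    base_nodes = base_nodes, outer_nodes = outer_nodes,
    midline_cut_edges = NULL, osteotomy_applied = FALSE,
    grid = list(id = id, psi = psi_mat, xs = xs, col_kind = col_kind,
                st_par = st_par, i_cut = c(i_cut_lo, i_cut_hi),
                i_mid = i_mid, n_psi = n_psi, n_sheet = n_sheet,
                pole_post = pole_post, pole_ant = pole_ant,
                ring_bx = ring_bx, ring_cx = ring_cx),
    params = params), class = "skull_mesh")
}

#' @export
print.skull_mesh <- function(x, ...) {
  cat("Parametric skull mesh\n")
  cat(sprintf("  nodes: %d, hexahedral elements: %d\n",
              nrow(x$nodes), nrow(x$elements)))
  cat("  elements per region:\n")
  tb <- table(x$region)
  for (r in names(tb)) if (tb[[r]] > 0) cat(sprintf("    %-20s %d\n", r, tb[[r]]))
  if (x$osteotomy_applied)
    cat(sprintf("  osteotomy applied: %.1f mm strip\n",
                x$osteotomy_mm))
  d <- measure_cranial_dimensions(x)
  cat(sprintf("  length %.1f mm, breadth %.1f mm, height %.1f mm, CI %.3f\n",
              d$length_mm, d$breadth_mm, d$height_mm, d$cranial_index))
  invisible(x)
}

#' Remove the midline osteotomy strip
#'
#' Removes the parietal bone elements whose centroids lie within the
#' midline strip of lateral width `osteotomy_mm`, strictly between the
#' coronal and lambdoid suture bands, emulating the craniotomy performed
#' in spring-assisted cranioplasty.  Suture and fontanelle elements are
#' never removed.  Because [generate_skull()] places mesh seams at the
#' planned strip boundary, the cut faces are smooth surfaces at
#' `y = +/- osteotomy_mm / 2` when the strip width matches the planned
#' value.
#'
#' @param mesh A `skull_mesh` from [generate_skull()].
#' @param osteotomy_mm Lateral strip width (mm).  Defaults to the width
#'   the mesh was generated for.  Values outside the 10-20 mm surgical
#'   range are allowed with a warning.
#'
#' @return The mesh with strip elements removed, unused nodes dropped,
#'   and `midline_cut_edges` populated with the two mirrored node lists
#'   on the cut faces (ordered anterior to posterior).
#' @export
apply_osteotomy <- function(mesh, osteotomy_mm = mesh$params$osteotomy_mm) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (mesh$osteotomy_applied)
    stop("osteotomy has already been applied to this mesh")
  if (osteotomy_mm <= 0 || osteotomy_mm >= mesh$params$breadth_mm / 2)
    stop("osteotomy_mm must lie in (0, breadth/2)")
  if (osteotomy_mm < 10 || osteotomy_mm > 20)
    warning("osteotomy_mm outside the usual 10-20 mm surgical range")

  cy <- rowMeans(matrix(mesh$nodes[mesh$elements, 2], nrow(mesh$elements)))
  parietal <- mesh$region %in% c("parietal_left", "parietal_right")
  remove <- parietal & abs(cy) <= osteotomy_mm / 2 + 1e-9
  if (!any(remove))
    stop("osteotomy strip is narrower than the innermost element row; ",
         "nothing to remove")
  keep <- !remove
  if (!any(mesh$region[keep] == "parietal_left") ||
      !any(mesh$region[keep] == "parietal_right"))
    stop("osteotomy would empty a parietal region")

  elements <- mesh$elements[keep, , drop = FALSE]
  region <- mesh$region[keep]

  # connectivity check on the remaining elements (shared-node graph)
  comp <- mesh_components(elements, nrow(mesh$nodes))
  if (comp > 1L)
    stop("osteotomy disconnects the mesh into ", comp, " components")

  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  elements[] <- remap[elements]
  nodes <- mesh$nodes[used, , drop = FALSE]

  g <- mesh$grid
  id_new <- array(0L, dim = dim(g$id))
  id_new[] <- remap[g$id]          # 0 where the node was dropped
  g$id <- id_new
  g$pole_post <- remap[g$pole_post]
  g$pole_ant <- remap[g$pole_ant]

  # cut faces: node sheets at the +/- psi_cut seams over the parietal
  # stations; i_cut[1] is the y < 0 (left) face
  sheets <- seq_len(g$n_sheet)
  st <- g$st_par[order(g$xs[g$st_par], decreasing = TRUE)]  # ant -> post
  left  <- as.vector(t(id_new[st, g$i_cut[1], sheets]))
  right <- as.vector(t(id_new[st, g$i_cut[2], sheets]))
  if (length(left) != length(right) || any(left == 0L) || any(right == 0L))
    stop("internal error: inconsistent cut faces")

  mesh$nodes <- nodes
  mesh$elements <- elements
  mesh$region <- droplevels(region)
  mesh$region <- factor(as.character(mesh$region), levels = skull_regions())
  base_new <- remap[intersect(mesh$base_nodes, used)]
  mesh$base_nodes <- sort(base_new[base_new > 0L])
  mesh$outer_nodes <- sort(remap[intersect(mesh$outer_nodes, used)])
  mesh$midline_cut_edges <- list(left = left, right = right)
  mesh$grid <- g
  mesh$osteotomy_applied <- TRUE
  mesh$osteotomy_mm <- osteotomy_mm
  mesh
}

# number of connected components of the element adjacency (shared nodes)
mesh_components <- function(elements, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(elements))) {
    ns <- unique(elements[e, ])
    r <- find(ns[1])
    for (k in ns[-1]) {
      rk <- find(k)
      if (rk != r) parent[rk] <- r
    }
  }
  used <- sort(unique(as.vector(elements)))
  length(unique(vapply(used, find, integer(1))))
}

#' Locate distraction-spring attachment sites on the osteotomy edges
#'
#' Places the anterior spring at arc distance `spring_position_mm`
#' posterior to the coronal suture band along the outer cut edge, and the
#' posterior spring at the same arc distance anterior to the lambdoid
#' band.  With three springs the third is placed midway (in arc length)
#' between the other two.  Each attachment is a point on the cut-edge
#' polyline, expressed as a convex combination of the two bracketing
#' nodes; the contralateral attachment is its exact mirror image.  Using
#' an embedded (interpolated) attachment rather than snapping to the
#' nearest node keeps the simulated outcome a smooth function of the
#' spring position even on coarse meshes.
#'
#' @param mesh A `skull_mesh` after [apply_osteotomy()].
#' @param spring_position_mm Arc distance SP from the sutures (mm),
#'   in the 10-40 mm surgical range.
#' @param n_springs 2 or 3.
#'
#' @return An object of class `spring_sites`: a named list of sites
#'   (`anterior`, optionally `middle`, `posterior`), each holding the
#'   bracketing outer-edge node pairs, interpolation weights and
#'   attachment coordinates for the right (`y > 0`) and left faces.
#' @export
locate_spring_sites <- function(mesh, spring_position_mm, n_springs = 2L) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (!mesh$osteotomy_applied)
    stop("apply_osteotomy() must be called before locating spring sites")
  if (!n_springs %in% c(2L, 3L))
    stop("n_springs must be 2 or 3")
  if (spring_position_mm < 10 || spring_position_mm > 40)
    stop("spring_position_mm must lie in the 10-40 mm surgical range")

  g <- mesh$grid
  st <- g$st_par[order(g$xs[g$st_par], decreasing = TRUE)]  # ant -> post
  right_ids <- g$id[cbind(st, g$i_cut[2], 1L)]
  left_ids  <- g$id[cbind(st, g$i_cut[1], 1L)]
  pts <- mesh$nodes[right_ids, , drop = FALSE]
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]

  sp <- spring_position_mm
  if (sp >= total / 2)
    stop(sprintf(paste0("anterior and posterior spring sites would overlap ",
                        "or cross: SP = %.1f mm but the cut edge is only ",
                        "%.1f mm long"), sp, total))

  targets <- c(anterior = sp, posterior = total - sp)
  if (n_springs == 3L)
    targets <- c(targets[1], middle = total / 2, targets[2])

  site_at <- function(s) {
    k <- max(which(arc <= s + 1e-12))
    k <- min(k, length(arc) - 1L)
    alpha <- (s - arc[k]) / (arc[k + 1] - arc[k])
    wts <- c(1 - alpha, alpha)
    r_nodes <- right_ids[c(k, k + 1L)]
    l_nodes <- left_ids[c(k, k + 1L)]
    p_r <- wts[1] * mesh$nodes[r_nodes[1], ] + wts[2] * mesh$nodes[r_nodes[2], ]
    p_l <- wts[1] * mesh$nodes[l_nodes[1], ] + wts[2] * mesh$nodes[l_nodes[2], ]
    list(arc_mm = s,
         right = list(nodes = r_nodes, weights = wts, point = p_r),
         left = list(nodes = l_nodes, weights = wts, point = p_l))
  }
  sites <- lapply(targets, site_at)
  structure(sites, class = "spring_sites", arc_total_mm = total,
            spring_position_mm = sp)
}

#' Measure cranial dimensions of a (possibly deformed) skull mesh
#'
#' Length is the anterior-posterior extent, breadth the lateral extent
#' and height the maximum elevation above the basal plane, all taken
#' over outer-surface nodes.  The cranial index is breadth / length.
#' When a displacement field is supplied the measurements are taken on
#' the displaced coordinates.
#'
#' @param mesh A `skull_mesh`.
#' @param displacement Optional N x 3 matrix of nodal displacements (mm).
#'
#' @return An object of class `cranial_dimensions` with `length_mm`,
#'   `breadth_mm`, `height_mm` and `cranial_index`.
#' @export
measure_cranial_dimensions <- function(mesh, displacement = NULL) {
  stopifnot(inherits(mesh, "skull_mesh"))
  if (nrow(mesh$elements) == 0L) stop("mesh has no elements")
  xyz <- mesh$nodes
  if (!is.null(displacement)) {
    if (!is.matrix(displacement) || any(dim(displacement) != dim(xyz)))
      stop("displacement must be defined on all nodes (N x 3 matrix)")
    xyz <- xyz + displacement
  }
  xyz <- xyz[mesh$outer_nodes, , drop = FALSE]
  out <- list(length_mm = max(xyz[, 1]) - min(xyz[, 1]),
              breadth_mm = max(xyz[, 2]) - min(xyz[, 2]),
              height_mm = max(xyz[, 3]))
  out$cranial_index <- out$breadth_mm / out$length_mm
  structure(out, class = "cranial_dimensions")
}

#' @export
print.cranial_dimensions <- function(x, ...) {
  cat(sprintf("cranial dimensions: length %.1f mm, breadth %.1f mm, height %.1f mm, CI %.3f\n",
              x$length_mm, x$breadth_mm, x$height_mm, x$cranial_index))
  invisible(x)
}
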