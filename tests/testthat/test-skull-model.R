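test_that("default skull reproduces the target scaphocephalic anatomy", {
  mesh <- default_skull()
  d <- measure_cranial_dimensions(mesh)
  expect_equal(d$length_mm, 165, tolerance = 2 / 165)
  expect_equal(d$breadth_mm, 116, tolerance = 2 / 116)
  expect_equal(d$height_mm, 87, tolerance = 2 / 87)
  expect_gte(d$cranial_index, 0.69)
  expect_lte(d$cranial_index, 0.71)
})

test_that("generation is deterministic and mirror-symmetric", {
  p <- skull_geometry_params(mesh_resolution = 12)
  m1 <- generate_skull(p)
  m2 <- generate_skull(p)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$region, m2$region)

  # mirrored grid indices map to mirrored coordinates
  g <- m1$grid
  ids <- as.vector(g$id)
  mir <- as.vector(g$id[, rev(seq_len(ncol(g$psi))), , drop = FALSE])
  expect_lt(max(abs(m1$nodes[ids, 2] + m1$nodes[mir, 2])), 1e-6)
  expect_lt(max(abs(m1$nodes[ids, 1] - m1$nodes[mir, 1])), 1e-6)
  expect_lt(max(abs(m1$nodes[ids, 3] - m1$nodes[mir, 3])), 1e-6)
})

test_that("region tags partition the shell with both sutures resolved", {
  mesh <- default_skull()
  expect_false(any(is.na(mesh$region)))
  tb <- table(mesh$region)
  expect_identical(sum(tb), nrow(mesh$elements))
  for (r in c("frontal", "parietal_left", "parietal_right", "occipital",
              "coronal_suture", "lambdoid_suture", "anterior_fontanelle"))
    expect_gt(tb[[r]], 0)
  # symmetric bone plates
  expect_identical(tb[["parietal_left"]], tb[["parietal_right"]])
  expect_gt(length(mesh$base_nodes), 0)
})

test_that("an equal-axes skull measures cranial index 1 within mesh tolerance", {
  p <- skull_geometry_params(length_mm = 116, breadth_mm = 116,
                             mesh_resolution = 16)
  d <- measure_cranial_dimensions(generate_skull(p))
  expect_equal(d$cranial_index, 1, tolerance = 0.01)
})

test_that("measured dimensions converge under mesh refinement", {
  d1 <- measure_cranial_dimensions(
    generate_skull(skull_geometry_params(mesh_resolution = 16)))
  d2 <- measure_cranial_dimensions(
    generate_skull(skull_geometry_params(mesh_resolution = 32)))
  expect_lt(abs(d2$length_mm - d1$length_mm) / d1$length_mm, 0.01)
  expect_lt(abs(d2$breadth_mm - d1$breadth_mm) / d1$breadth_mm, 0.01)
  expect_lt(abs(d2$height_mm - d1$height_mm) / d1$height_mm, 0.01)
})

test_that("parameter validation rejects degenerate geometry", {
  expect_error(skull_geometry_params(length_mm = -1), "positive")
  expect_error(skull_geometry_params(mesh_resolution = 4), "at least 8")
  expect_error(skull_geometry_params(osteotomy_mm = 80), "half the skull")
  expect_error(skull_geometry_params(thickness_mm = 30), "thin shell")
  expect_error(skull_geometry_params(coronal_frac = -0.7), "anterior")
})

test_that("osteotomy removes exactly the midline parietal strip", {
  full <- default_skull()
  cut <- cut_skull()
  expect_lt(nrow(cut$elements), nrow(full$elements))

  # only parietal bone is removed: fibrous regions are untouched
  for (r in c("coronal_suture", "lambdoid_suture", "anterior_fontanelle",
              "frontal", "occipital"))
    expect_identical(sum(cut$region == r), sum(full$region == r))

  # all removed elements lay inside the strip |y| <= OS/2
  n_removed_by_region <- table(full$region) - table(cut$region)
  expect_identical(sum(n_removed_by_region),
                   nrow(full$elements) - nrow(cut$elements))
  cy <- rowMeans(matrix(cut$nodes[cut$elements, 2], nrow(cut$elements)))
  par <- cut$region %in% c("parietal_left", "parietal_right")
  expect_true(all(abs(cy[par]) > 20 / 2 - 1e-6))

  # a narrower osteotomy removes fewer elements
  cut10 <- apply_osteotomy(default_skull(), 10)
  expect_gt(nrow(cut10$elements), nrow(cut$elements))
})

test_that("osteotomy cut faces are equal-length mirrored node lists", {
  cut <- cut_skull()
  ce <- cut$midline_cut_edges
  expect_identical(length(ce$left), length(ce$right))
  expect_gt(length(ce$left), 0)
  pl <- cut$nodes[ce$left, , drop = FALSE]
  pr <- cut$nodes[ce$right, , drop = FALSE]
  expect_lt(max(abs(pl[, 2] + pr[, 2])), 1e-6)  # y mirrored
  expect_lt(max(abs(pl[, 1] - pr[, 1])), 1e-6)
  expect_lt(max(abs(pl[, 3] - pr[, 3])), 1e-6)
  # faces sit at the planned strip half-width
  expect_equal(max(abs(pr[, 2])), 10, tolerance = 1e-6)
})

test_that("osteotomy outside the surgical range warns", {
  expect_warning(apply_osteotomy(default_skull(), 25), "surgical range")
})

test_that("spring sites sit at the requested arc distances, mirrored", {
  cut <- cut_skull()
  s2 <- locate_spring_sites(cut, 34, 2)
  expect_named(s2, c("anterior", "posterior"))
  expect_equal(s2$anterior$arc_mm, 34)
  total <- attr(s2, "arc_total_mm")
  expect_equal(s2$posterior$arc_mm, total - 34)
  # mirrored attachment pair
  expect_equal(s2$anterior$right$point[2], -s2$anterior$left$point[2])
  expect_equal(s2$anterior$right$point[c(1, 3)],
               s2$anterior$left$point[c(1, 3)])
  # attachment separation equals the strip width at the cut edge
  expect_equal(sqrt(sum((s2$anterior$right$point -
                           s2$anterior$left$point)^2)),
               20, tolerance = 1e-6)

  s3 <- locate_spring_sites(cut, 34, 3)
  expect_named(s3, c("anterior", "middle", "posterior"))
  expect_equal(s3$middle$arc_mm - s3$anterior$arc_mm,
               s3$posterior$arc_mm - s3$middle$arc_mm)
})

test_that("infeasible spring placement is rejected", {
  # sutures close together -> short osteotomy arc
  short <- apply_osteotomy(generate_skull(skull_geometry_params(
    coronal_frac = 0.20, lambdoid_frac = -0.25, mesh_resolution = 16)))
  expect_error(locate_spring_sites(short, 40, 2), "overlap or cross")
  expect_error(locate_spring_sites(cut_skull(), 45, 2), "10-40")
  expect_error(locate_spring_sites(default_skull(), 34, 2),
               "apply_osteotomy")
})

test_that("measurement respects displacement fields", {
  mesh <- default_skull()
  d0 <- measure_cranial_dimensions(mesh)
  u0 <- matrix(0, nrow(mesh$nodes), 3)
  expect_identical(unclass(measure_cranial_dimensions(mesh, u0)),
                   unclass(d0))
  # rigid lateral separation of the two halves widens breadth by 2 mm
  u <- u0
  u[, 2] <- sign(mesh$nodes[, 2])
  d <- measure_cranial_dimensions(mesh, u)
  expect_equal(d$breadth_mm, d0$breadth_mm + 2)
  expect_equal(d$length_mm, d0$length_mm)
  expect_error(measure_cranial_dimensions(mesh, u[-1, ]), "all nodes")
})

test_that("mesh export writes well-formed VTK and STL files", {
  mesh <- generate_skull(skull_geometry_params(mesh_resolution = 12))
  vtk <- tempfile(fileext = ".vtk")
  stl <- tempfile(fileext = ".stl")
  write_vtk(mesh, vtk, displacement = matrix(0, nrow(mesh$nodes), 3))
  write_stl(mesh, stl)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_identical(sum(grepl("^POINTS", lines)), 1L)
  expect_match(lines[grepl("^CELLS", lines)][1],
               sprintf("^CELLS %d", nrow(mesh$elements)))
  expect_true(any(grepl("VECTORS displacement", lines)))
  stl_lines <- readLines(stl)
  expect_identical(stl_lines[1], "solid skull")
  expect_gt(sum(grepl("facet normal", stl_lines)), 100)

  # VTK round-trip: geometry, tags and field survive
  back <- read_vtk(vtk)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_identical(back$elements, mesh$elements)
  expect_identical(back$region, mesh$region)
  expect_identical(dim(attr(back, "displacement")), dim(mesh$nodes))
  d_back <- measure_cranial_dimensions(back)
  d_orig <- measure_cranial_dimensions(mesh)
  expect_equal(d_back$cranial_index, d_orig$cranial_index,
               tolerance = 1e-6)
  unlink(c(vtk, stl))
})
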