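# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_skull <- function() {
  cached("default_skull", generate_skull(skull_geometry_params()))
}

cut_skull <- function() {
  cached("cut_skull", apply_osteotomy(default_skull()))
}

# structured block mesh for element verification (patch test, bar test)
make_block_mesh <- function(nx, ny, nz, jitter = 0) {
  xs <- seq(0, 1, length.out = nx + 1)
  ys <- seq(0, 1, length.out = ny + 1)
  zs <- seq(0, 1, length.out = nz + 1)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- function(i, j, k)
    i + (j - 1) * (nx + 1) + (k - 1) * (nx + 1) * (ny + 1)
  els <- list()
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx)
    els[[length(els) + 1]] <-
      c(idx(i, j, k), idx(i + 1, j, k), idx(i + 1, j + 1, k), idx(i, j + 1, k),
        idx(i, j, k + 1), idx(i + 1, j, k + 1), idx(i + 1, j + 1, k + 1),
        idx(i, j + 1, k + 1))
  interior <- which(nodes[, 1] > 0 & nodes[, 1] < 1 &
                      nodes[, 2] > 0 & nodes[, 2] < 1 &
                      nodes[, 3] > 0 & nodes[, 3] < 1)
  if (jitter > 0 && length(interior))
    nodes[interior, ] <- nodes[interior, ] + jitter
  structure(list(nodes = nodes, elements = do.call(rbind, els),
                 region = factor(rep("frontal", length(els)),
                                 levels = skull_regions()),
                 base_nodes = integer(0), outer_nodes = NULL,
                 params = NULL),
            class = "skull_mesh")
}

all_dofs <- function(nodes) {
  as.vector(vapply(as.integer(nodes), function(n) 3L * n + c(-2L, -1L, 0L),
                   integer(3)))
}

# full one-at-a-time sweeps at the sweep resolution, shared between the
# trend and surrogate-quality acceptance checks
reference_sweeps <- function() {
  cached("reference_sweeps", {
    out <- list()
    for (ns in c(2L, 3L)) {
      for (p in c("E", "t", "SP", "OS", "k")) {
        out[[as.character(ns)]][[p]] <-
          run_oat_sweep(sweep_plan(p, n_springs = ns))
      }
    }
    out
  })
}

table2_laws <- function() {
  tab <- reference_fit_coefficients()
  split(tab, seq_len(nrow(tab)))
}
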