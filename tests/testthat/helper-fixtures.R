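# Shared fixtures: tiny analytic geometries and memoized meshes/systems.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# unit square, single (body) layer, fixed left+bottom
square_spec <- function(side = 1, plane = 2) {
  geometry_spec(
    outer = rbind(c(0, side), c(0, 0), c(side, 0), c(side, side)),
    layers = list(),
    contact_plane_x = plane, depth = 1, z_in = 0, z_out = side
  )
}

# trapezoid whose air-exposed chain is linear in z: x_r(z) = x0 + slope * z,
# giving an analytic wedge channel against the plane
wedge_spec <- function(x0 = 6, slope = 0.5, plane = 8, z_lo = -3.6, z_hi = 0) {
  geometry_spec(
    outer = rbind(c(0, z_hi), c(0, z_lo),
                  c(x0 + slope * z_lo, z_lo), c(x0 + slope * z_hi, z_hi)),
    layers = list(),
    contact_plane_x = plane, depth = 14, z_in = z_lo, z_out = z_hi
  )
}

coarse_mesh <- function() memo("coarse_mesh", build_m5_mesh(0.75))
fine_mesh <- function() memo("fine_mesh", build_m5_mesh(0.3))
nominal_mat <- function() material_params()

coarse_system <- function() memo("coarse_system",
                                 assemble(coarse_mesh(), nominal_mat()))

# single-triangle mesh for patch tests
one_tri_mesh <- function(p = rbind(c(0, 0), c(1, 0), c(0, 1)), depth = 1) {
  structure(list(
    nodes = p, triangles = matrix(c(1L, 2L, 3L), 1),
    layer = factor("body"), gamma_f = c(2L, 3L), gamma_fixed = integer(0),
    contact_plane_x = 10, depth = depth, z_in = 0, z_out = 1,
    resolution = 1, n_rows = 2L, n_cols = 2L
  ), class = "vf_mesh")
}

# synthetic single-dof system (mass m, stiffness k, damping c)
sdof_system <- function(m, k, c = 0) {
  one <- function(x) Matrix::sparseMatrix(i = 1, j = 1, x = x, dims = c(2, 2))
  structure(list(M = one(m), D = one(c), K = one(k),
                 free = 1L, fixed = 2L, mesh = NULL, mat = NULL),
            class = "vf_system")
}

sdof_state <- function(u = 0, v = 0, a = 0, t = 0) {
  structure(list(t = t, u = c(u, 0), v = c(v, 0), a = c(a, 0)),
            class = "vf_state")
}

# analytic test channels
uniform_channel <- function(gap = 1, n = 50, depth = 14) {
  channel_profile(seq(-3.6, 0, length.out = n), rep(gap, n), depth = depth)
}

converging_channel <- function(gap_in = 3, gap_out = 0.5, n = 101, depth = 14) {
  z <- seq(-3.6, 0, length.out = n)
  channel_profile(z, gap_in + (gap_out - gap_in) * (z - z[1]) / (z[n] - z[1]),
                  depth = depth)
}

# mean period (ms) from linearly interpolated upward zero crossings
measured_period <- function(t, x) {
  x <- x - mean(x)
  idx <- which(x[-length(x)] < 0 & x[-1] >= 0)
  tc <- t[idx] - x[idx] * (t[idx + 1] - t[idx]) / (x[idx + 1] - x[idx])
  mean(diff(tc))
}
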