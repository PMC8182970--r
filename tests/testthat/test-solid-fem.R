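test_that("rigid-body modes lie in the null space of the unconstrained stiffness", {
  sys <- coarse_system()
  n <- nrow(coarse_mesh()$nodes)
  tx <- rep(c(1, 0), n)
  tz <- rep(c(0, 1), n)
  rot <- as.vector(t(cbind(-coarse_mesh()$nodes[, 2], coarse_mesh()$nodes[, 1])))
  kscale <- max(abs(sys$K))
  for (v in list(tx, tz, rot)) {
    expect_lt(max(abs(sys$K %*% v)) / kscale, 1e-10)
  }
})

test_that("one-element patch reproduces the plane-strain stress (Lame oracle)", {
  E <- 11.8; nu <- 0.4995
  mesh <- one_tri_mesh()
  mat <- material_params(E_body = E, nu = nu)
  sys <- assemble(mesh, mat)

  eps <- c(3e-3, -1e-3, 2e-3)  # (du_x/dx, du_z/dz, du_z/dx + du_x/dz)
  # impose the uniform strain field u_x = e1*x + e3*z, u_z = e2*z
  u <- numeric(6)
  for (i in 1:3) {
    x <- mesh$nodes[i, 1]; z <- mesh$nodes[i, 2]
    u[2 * i - 1] <- eps[1] * x + eps[3] * z
    u[2 * i] <- eps[2] * z
  }
  # independent oracle: Lame constants, sigma = lambda tr(eps) I + 2 mu eps
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  sigma_oracle <- c(lam * (eps[1] + eps[2]) + 2 * mu * eps[1],
                    lam * (eps[1] + eps[2]) + 2 * mu * eps[2],
                    mu * eps[3])

  bb <- vfbayes:::tri_B(mesh$nodes)
  sigma <- as.vector(plane_strain_C(E, nu) %*% (bb$B %*% u))
  expect_equal(sigma, sigma_oracle, tolerance = 1e-8)

  # and the assembled stiffness produces the consistent nodal forces
  f <- as.vector(sys$K %*% u)
  f_oracle <- as.vector(bb$area * mesh$depth * t(bb$B) %*% sigma_oracle)
  expect_equal(f, f_oracle, tolerance = 1e-8)
})

test_that("the element shear modulus is E / (2 (1 + nu))", {
  expect_equal(shear_modulus(11.8, 0.4995), 11.8 / (2 * (1 + 0.4995)))
  expect_error(plane_strain_C(10, 0.5), "locking|singular")
  expect_error(material_params(nu = 0.51), "nu")
})

test_that("natural frequencies are real positive and scale as sqrt(stiffness)", {
  f1 <- natural_frequencies(coarse_system(), 4)
  expect_true(all(is.finite(f1) & f1 > 0))
  mat2 <- material_params(E_body = 2 * 11.8, E_slp = 2 * 0.6,
                          E_lig = 2 * 2.0, E_epi = 2 * 45.0)
  f2 <- natural_frequencies(assemble(coarse_mesh(), mat2), 4)
  expect_equal(f2 / f1, rep(sqrt(2), 4), tolerance = 1e-6)
})

test_that("precompression identities: m = 0 and no-contact m are pure shifts", {
  mesh <- coarse_mesh()
  pc0 <- precompress(mesh, nominal_mat(), 0)
  expect_equal(max(abs(pc0$state$u)), 0)
  expect_equal(pc0$mesh$nodes, mesh$nodes)

  # medial gap of the shipped geometry is 0.2 mm; m = 0.05 engages nothing
  pc <- precompress(mesh, nominal_mat(), 0.05)
  expect_equal(max(abs(pc$state$u)), 0, tolerance = 1e-8)
  expect_equal(pc$mesh$nodes[, 1], mesh$nodes[, 1] + 0.05)
  expect_length(pc$contact_nodes, 0)
})

test_that("m = 0.4 mm precompression respects the plane and touches it", {
  pc <- memo("coarse_precompress",
             precompress(coarse_mesh(), nominal_mat(), 0.4))
  def <- deformed_nodes(pc$mesh, pc$state)
  expect_true(all(def[, 1] <= pc$mesh$contact_plane_x + 1e-9))
  on_plane <- abs(def[pc$mesh$gamma_f, 1] - pc$mesh$contact_plane_x) < 1e-9
  expect_gt(sum(on_plane), 0)
  expect_lt(pc$residual, 1e-8)
  expect_equal(max(abs(pc$state$v)), 0)
})

test_that("the literal incremental precompression path reaches the same equilibrium", {
  pc1 <- memo("coarse_precompress",
              precompress(coarse_mesh(), nominal_mat(), 0.4))
  pc2 <- precompress(coarse_mesh(), nominal_mat(), 0.4,
                     method = "incremental", step = 0.01)
  expect_equal(pc2$state$u, pc1$state$u, tolerance = 1e-8)
})

test_that("Newmark keeps a constant-force equilibrium fixed", {
  sys <- coarse_system()
  set.seed(3)
  u0 <- numeric(nrow(sys$K))
  u0[sys$free] <- rnorm(length(sys$free), sd = 1e-3)
  f <- as.vector(sys$K %*% u0)
  st <- sim_state(coarse_mesh(), u = u0)
  st2 <- newmark_step(sys, st, f, dt = 0.01)
  expect_equal(st2$u, st$u, tolerance = 1e-10)
  expect_lt(max(abs(st2$v)), 1e-10)
})

test_that("single-dof Newmark matches the analytic oscillator to 0.1% in period", {
  m <- 2; k <- 5
  omega <- sqrt(k / m)
  period <- 2 * pi / omega
  dt <- period / 1000
  sys <- sdof_system(m, k)
  cache <- newmark_cache(sys, dt)
  st <- sdof_state(u = 1)
  n <- 5000
  us <- numeric(n); ts <- numeric(n)
  for (i in seq_len(n)) {
    st <- newmark_step(sys, st, c(0, 0), dt, cache = cache)
    us[i] <- st$u[1]; ts[i] <- st$t
  }
  expect_equal(measured_period(ts, us), period, tolerance = 1e-3)
})

test_that("with viscosity and no forcing the mechanical energy is non-increasing", {
  m <- 2; k <- 5; c <- 0.3
  sys <- sdof_system(m, k, c)
  dt <- 0.02
  cache <- newmark_cache(sys, dt)
  # consistent initial acceleration: m a0 = -c v0 - k u0
  st <- sdof_state(u = 1, v = 0.5, a = (-0.3 * 0.5 - 5 * 1) / 2)
  e_prev <- mechanical_energy(sys, st)
  for (i in 1:1000) {
    st <- newmark_step(sys, st, c(0, 0), dt, cache = cache)
    e <- mechanical_energy(sys, st)
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
  expect_lt(e_prev, 0.1 * mechanical_energy(sys, sdof_state(u = 1, v = 0.5)))
})

test_that("contact projection is exact, idempotent, and gap-safe", {
  mesh <- coarse_mesh()
  st <- sim_state(mesh)
  st2 <- enforce_contact(mesh, st)
  expect_identical(st2$u, st$u)  # nothing crossing -> unchanged

  xd <- 2 * mesh$gamma_f - 1
  set.seed(5)
  st$u[xd] <- runif(length(xd), -0.1, 0.3)
  st$v[xd] <- rnorm(length(xd))
  proj <- enforce_contact(mesh, st)
  def <- deformed_nodes(mesh, proj)
  expect_true(all(def[, 1] <= mesh$contact_plane_x + 1e-12))
  crossing <- which(mesh$nodes[, 1] + st$u[2 * seq_len(nrow(mesh$nodes)) - 1] >
                      mesh$contact_plane_x)
  expect_equal(def[crossing, 1],
               rep(mesh$contact_plane_x, length(crossing)))
  expect_true(all(proj$v[2 * crossing - 1] == 0))
  expect_identical(enforce_contact(mesh, proj), proj)

  # projection only moves penetrating nodes back to the plane: station gaps
  # change by at most the deepest penetration and never go negative
  pen <- max(0, max(mesh$nodes[, 1] + st$u[2 * seq_len(nrow(mesh$nodes)) - 1] -
                      mesh$contact_plane_x))
  g0 <- extract_channel(mesh, st)$gap      # clamped gaps
  g1 <- extract_channel(mesh, proj)$gap
  expect_true(all(abs(g1 - g0) <= pen + 1e-12))
  expect_true(all(g1 >= 0))
})
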