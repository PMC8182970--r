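test_that("surface pressure maps to consistent nodal loads", {
  # uniform pressure on the straight right face of a unit square:
  # total x-force = -p * L * depth, no z-force
  mesh <- build_m5_mesh(0.5, square_spec())
  ch <- channel_profile(seq(0, 1, length.out = 11), rep(1, 11), depth = 1)
  p <- rep(0.8, 11)
  f <- pressure_to_forces(ch, p, mesh)
  idx <- seq_len(nrow(mesh$nodes))
  expect_equal(sum(f[2 * idx - 1]), -0.8 * 1 * 1, tolerance = 1e-12)
  expect_equal(sum(f[2 * idx]), 0, tolerance = 1e-12)
  expect_equal(pressure_to_forces(ch, rep(0, 11), mesh), numeric(2 * nrow(mesh$nodes)))
})

test_that("a linearly varying pressure splits with the 1/3-1/6 weights", {
  mesh <- one_tri_mesh(rbind(c(0, 0), c(1, 0), c(1, 1)), depth = 2)
  mesh$gamma_f <- c(2L, 3L)      # single vertical edge x = 1, length 1
  ch <- channel_profile(c(0, 1), c(1, 1), depth = 2)
  p <- c(0.6, 1.2)               # linear along the edge
  f <- pressure_to_forces(ch, p, mesh)
  L <- 1; d <- 2
  expect_equal(f[2 * 2 - 1], -L * d * (0.6 / 3 + 1.2 / 6))  # node a
  expect_equal(f[2 * 3 - 1], -L * d * (0.6 / 6 + 1.2 / 3))  # node b
  expect_equal(f[2 * 2], 0)
  expect_equal(f[2 * 3], 0)
})

test_that("zero driving pressure leaves the precompressed state at rest", {
  cfg <- sim_config("bernoulli_fixed", p_sub = 0, p_sup = 0, duration = 5,
                    transient_discard = 0, output_dt = 0.05)
  obs <- run_forward(cfg, coarse_mesh(), nominal_mat())
  expect_equal(obs$width_mm, rep(obs$width_mm[1], nrow(obs)), tolerance = 1e-9)
  expect_equal(obs$width_mm[1], 0)   # m = 0.4 mm keeps the glottis shut
})

test_that("free vibration tracks the first eigenfrequency within 2%", {
  mesh <- coarse_mesh()
  mat <- material_params(eta = 0)
  sys <- assemble(mesh, mat)
  eig <- natural_frequencies(sys, 1, return_modes = TRUE)
  mode <- eig$modes[, 1]
  mode <- mode * (0.02 / max(abs(mode)))      # small kick, no contact
  cfg <- sim_config("none", m = 0, duration = 400, transient_discard = 0,
                    output_dt = 0.25)
  pc <- precompress(mesh, mat, 0)
  obs <- run_forward(cfg, mesh, mat, precomp = pc,
                     init_state = sim_state(mesh, u = mode))
  f_sim <- 1000 / measured_period(obs$time_ms, obs$width_mm)
  expect_equal(f_sim, eig$freq_hz[1], tolerance = 0.02)
})

test_that("the C++ time loop agrees with the R reference stepper", {
  mesh <- coarse_mesh()
  mat <- nominal_mat()
  pc <- memo("coarse_precompress", precompress(mesh, mat, 0.4))
  p_sub <- 1.092; r_sep <- 1.4
  dt <- 0.01; nstep <- 25

  cfg <- sim_config("bernoulli_fixed", p_sub = p_sub, r_sep = r_sep,
                    duration = nstep * dt, transient_discard = 0,
                    output_dt = dt)
  cpp_obs <- run_forward(cfg, mesh, mat, precomp = pc, keep_state = TRUE)
  cpp_state <- attr(cpp_obs, "final_state")

  # R reference: the same loop out of exported pieces
  sys <- pc$system
  smesh <- pc$mesh
  st <- pc$state
  forces <- function(state) {
    ch <- extract_channel(smesh, state, n_stations = 50)
    p <- bernoulli_pressure(ch, bernoulli_params(p_sub, 0, r_sep))
    pressure_to_forces(ch, as.numeric(p), smesh, state,
                       p_below = p_sub, p_above = 0)
  }
  f0 <- forces(st)
  fr <- sys$free
  a0 <- numeric(length(st$u))
  a0[fr] <- as.vector(Matrix::solve(sys$M[fr, fr],
                                    f0[fr] - sys$D[fr, fr] %*% st$v[fr] -
                                      sys$K[fr, fr] %*% st$u[fr]))
  st$a <- a0
  cache <- newmark_cache(sys, dt)
  for (i in seq_len(nstep)) {
    st <- newmark_step(sys, st, forces(st), dt, cache = cache)
    st <- enforce_contact(smesh, st)
  }
  expect_equal(cpp_state$u, st$u, tolerance = 1e-8)
  expect_equal(cpp_state$v, st$v, tolerance = 1e-8)
})

test_that("nominal driving sustains periodic oscillation with an energy balance", {
  mesh <- coarse_mesh()
  cfg <- sim_config("bernoulli_fixed", p_sub = 0.910, duration = 400,
                    transient_discard = 50, output_dt = 0.25)
  obs <- run_forward(cfg, mesh, nominal_mat(), keep_state = TRUE)
  w <- obs$width_mm
  expect_gt(max(w), 0.1)                      # open phase
  expect_equal(min(w), 0)                     # collision phase
  # periodicity: normalized autocorrelation peak at the fundamental lag
  x <- w - mean(w)
  ac <- stats::acf(x, lag.max = 80, plot = FALSE)$acf[, 1, 1]
  fundamental <- which.max(ac[20:80]) + 19    # search beyond 5 ms
  expect_gt(ac[fundamental], 0.95)
  # energy audit: fluid work balances dissipation + contact loss + stored
  en <- attr(obs, "energy")
  residual <- en$work_fluid - en$dissipation - en$contact_loss -
    (en$e_end - en$e_start)
  expect_lt(abs(residual) / max(en$work_fluid, en$dissipation), 0.05)
})

test_that("halving the time step changes the cycle-averaged width by < 1%", {
  mesh <- coarse_mesh()
  mean_width <- function(dt) {
    cfg <- sim_config("bernoulli_fixed", dt = dt, duration = 120,
                      transient_discard = 40, output_dt = 0.25)
    mean(run_forward(cfg, mesh, nominal_mat())$width_mm)
  }
  w1 <- mean_width(0.01)
  w2 <- mean_width(0.005)
  expect_lt(abs(w1 - w2) / w1, 0.01)
})

test_that("observation CSV round-trips including metadata", {
  obs <- observation_series(seq(0, 1, by = 0.25), c(0, 0.1, 0.3, 0.2, 0),
                            depth = 14, noise_sd = 1 / 14,
                            meta = list(flow_model = "viscous", p_sub = 1.001))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observation(obs, path)
  back <- read_observation(path)
  expect_equal(back$time_ms, obs$time_ms)
  expect_equal(back$width_mm, obs$width_mm)
  expect_equal(attr(back, "depth"), 14)
  expect_equal(attr(back, "meta")$p_sub, 1.001)
})

test_that("registration finds the true integer lag", {
  t_long <- seq(0, 60, by = 0.25)
  sig <- function(t) 0.3 + 0.25 * sin(2 * pi * t / 7.3)
  sim <- observation_series(t_long, pmax(0, sig(t_long)))
  lag_true <- 9
  t_obs <- seq(0, 40, by = 0.25)
  obs <- observation_series(t_obs, pmax(0, sig(t_obs + lag_true * 0.25)))
  reg <- register_series(sim, obs, max_lag = 30)
  expect_equal(reg$lag, lag_true)
  expect_lt(max(abs(reg$residuals)), 1e-10)
})
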