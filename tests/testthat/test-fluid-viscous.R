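test_that("the vena-contracta correction takes its printed values", {
  vp <- viscous_params()  # z_in = -3.6, z_out = 0
  expect_equal(alpha_correction(0, vp), 0.75)
  expect_equal(alpha_correction(-3.6, vp), 1.00)
  expect_equal(alpha_correction(-1.8, vp), 0.8125)
  # clamped outside the channel
  expect_equal(alpha_correction(1.0, vp), 0.75)
  expect_equal(alpha_correction(-5.0, vp), 1.00)
})

test_that("the recovery profile switches from 1 to chi_min after the minimum", {
  ch <- converging_channel(n = 10)            # minimum at the outlet
  expect_equal(chi_profile(ch, 0.2), rep(1, 10))
  z <- seq(-3.6, 0, length.out = 10)
  gap <- c(3, 2.5, 2, 1.5, 1, 0.5, 0.8, 1.2, 1.5, 2)
  ch2 <- channel_profile(z, gap)
  k <- which.min(gap)
  expect_equal(chi_profile(ch2, 0.2), c(rep(1, k), rep(0.2, 10 - k)))
  expect_equal(chi_profile(ch2, 1), rep(1, 10))  # chi = 1: no separation loss
})

test_that("zero driving pressure gives zero flow and uniform pressure", {
  fl <- solve_viscous_flow(converging_channel(), 0.7, 0.7)
  expect_equal(attr(fl, "q"), 0)
  expect_equal(fl$w, rep(0, nrow(fl)))
  expect_equal(fl$p, rep(0.7, nrow(fl)), tolerance = 1e-12)
})

test_that("the inviscid limit reproduces the analytic Bernoulli profile", {
  vp <- viscous_params(mu_f = 0, chi_min = 1, alpha_coef = c(1, 0))
  ch <- converging_channel(gap_in = 3, gap_out = 0.5, n = 101)
  p_sub <- 1.0; p_sup <- 0.2
  fl <- solve_viscous_flow(ch, p_sub, p_sup, vp)
  A <- ch$area
  n <- length(A)
  # analytic: q from energy conservation between inlet and outlet
  q_star <- sqrt(2 * (p_sub - p_sup) / (1.14e-3 * (1 / A[n]^2 - 1 / A[1]^2)))
  p_star <- p_sub - 0.5 * 1.14e-3 * q_star^2 * (1 / A^2 - 1 / A[1]^2)
  expect_equal(attr(fl, "q"), q_star, tolerance = 1e-6)
  expect_lt(max(abs(fl$p - p_star)) / p_sub, 1e-6)
  # minimum-area station (the outlet here) matches the Bernoulli value
  expect_equal(fl$p[min_area_station(ch)],
               p_star[min_area_station(ch)], tolerance = 1e-6)
})

test_that("a constant-area channel recovers the closed-form friction drop", {
  vp <- viscous_params(alpha_coef = c(1, 0))  # no vena contracta
  gap <- 1; depth <- 14; L <- 3.6
  ch <- uniform_channel(gap = gap, n = 181, depth = depth)
  p_sub <- 1.0; p_sup <- 0.9
  fl <- solve_viscous_flow(ch, p_sub, p_sup, vp)
  A <- gap * depth; S <- 2 * depth
  # advection vanishes (w constant), so dp/dz = -2 mu (S/A)^2 w exactly
  q_star <- (p_sub - p_sup) * A^3 / (2 * 1.9e-5 * S^2 * L)
  expect_equal(attr(fl, "q"), q_star, tolerance = 1e-8)
  # linear pressure profile
  expect_equal(fl$p, p_sub - (p_sub - p_sup) * (ch$z - ch$z[1]) / L,
               tolerance = 1e-8)
})

test_that("mass conservation and bounds hold on an irregular channel", {
  z <- seq(-3.6, 0, length.out = 60)
  gap <- 1 + 0.6 * sin(3 * z) + 0.3 * cos(7 * z)
  ch <- channel_profile(z, gap - min(gap) + 0.3)
  fl <- solve_viscous_flow(ch, 1.2, 0.1)
  q <- attr(fl, "q")
  expect_equal(fl$w * fl$A, rep(q, 60), tolerance = 1e-10)
  expect_equal(fl$p[60], 0.1, tolerance = 1e-6)
  expect_lte(fl$p[min_area_station(ch)], 1.2)
})

test_that("the shooting result is independent of the initial bracket", {
  ch <- converging_channel()
  f1 <- solve_viscous_flow(ch, 1.0, 0, q_bracket = 0.5)
  f2 <- solve_viscous_flow(ch, 1.0, 0, q_bracket = 4000)
  expect_equal(attr(f1, "q"), attr(f2, "q"), tolerance = 1e-9)
})

test_that("without separation loss the interior constriction fully recovers", {
  vp <- viscous_params(mu_f = 0, chi_min = 1, alpha_coef = c(1, 0))
  z <- seq(-3.6, 0, length.out = 81)
  gap <- 2 - 1.5 * exp(-((z + 1.8) / 0.7)^2)   # deep interior constriction
  gap[81] <- 1.8                                # mildly smaller outlet
  ch <- channel_profile(z, gap)
  p_sub <- 1.0; p_sup <- 0.2
  fl <- solve_viscous_flow(ch, p_sub, p_sup, vp)
  # with full recovery (chi = 1) the flow rate depends only on the end areas
  A <- ch$area
  q_star <- sqrt(2 * (p_sub - p_sup) / (1.14e-3 * (1 / A[81]^2 - 1 / A[1]^2)))
  expect_equal(attr(fl, "q"), q_star, tolerance = 1e-6)
  # the pressure dips at the throat and comes back up to the outlet value
  expect_lt(min(fl$p), 0)
  expect_equal(fl$p[81], p_sup, tolerance = 1e-6)
})

test_that("the closed glottis falls back to the hydrostatic assignment", {
  z <- seq(-3.6, 0, length.out = 6)
  ch <- channel_profile(z, c(2, 1, 0, 0.5, 1, 2))
  fl <- solve_viscous_flow(ch, 1.0, 0)
  expect_true(attr(fl, "closed"))
  expect_equal(attr(fl, "q"), 0)
  expect_equal(fl$p, c(1, 1, 0, 0, 0, 0))
})

test_that("the C++ per-step viscous solver agrees with the R implementation", {
  z <- seq(-3.6, 0, length.out = 50)
  gap <- 0.8 + 0.5 * sin(2 * z + 1)
  ch <- channel_profile(z, gap)
  vp <- viscous_params()
  flR <- solve_viscous_flow(ch, 1.092, 0, vp)
  cpp <- vfbayes:::cpp_viscous_profile(ch$z, ch$area, ch$perimeter, 1.092, 0,
                                       list(rho_f = vp$rho_f, mu_f = vp$mu_f,
                                            chi_min = vp$chi_min,
                                            alpha_coef = vp$alpha_coef))
  expect_equal(cpp$q, attr(flR, "q"), tolerance = 1e-6)
  expect_equal(as.numeric(cpp$p), flR$p, tolerance = 1e-6)
})

test_that("the optional unsteady term vanishes at a self-consistent velocity", {
  ch <- converging_channel()
  steady <- solve_viscous_flow(ch, 1.0, 0)
  again <- solve_viscous_flow(ch, 1.0, 0, w_prev = steady$w, dt = 0.01)
  expect_equal(attr(again, "q"), attr(steady, "q"), tolerance = 1e-9)
  # a previous velocity above the steady one decelerates the flow: the
  # backward-difference term adds pressure, so the root moves up
  slower <- solve_viscous_flow(ch, 1.0, 0, w_prev = 2 * steady$w, dt = 0.05)
  expect_gt(attr(slower, "q"), attr(steady, "q"))
})
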