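#' Viscous flow model parameters
#'
#' One-dimensional viscous glottal flow in the collapsible-tube tradition:
#' steady continuity and momentum with a fully developed friction shear
#' stress, a separation-loss shear stress parameterized by the pressure
#' recovery constant `chi_min`, and a quadratic vena-contracta correction
#' of the cross-sectional area.
#'
#' @param rho_f Fluid density in kg/m^3 (air at body temperature).
#' @param mu_f Dynamic viscosity in kg/(m s).
#' @param chi_min Pressure-recovery constant downstream of the minimum area
#'   (1 = no separation loss, 0 = no recovery).
#' @param z_in,z_out Glottal channel inlet/outlet in mm.
#' @param alpha_coef The two coefficients of the quadratic vena-contracta
#'   correction (value at the outlet and the quadratic weight).
#' @return An object of class `vf_viscous`.
#' @export
viscous_params <- function(rho_f = 1.14, mu_f = 1.9e-5, chi_min = 0.2,
                           z_in = -3.6, z_out = 0,
                           alpha_coef = c(0.75, 0.25)) {
  stopifnot(rho_f > 0, mu_f >= 0, chi_min >= 0, chi_min <= 1, z_in < z_out)
  structure(list(rho_f = rho_f, mu_f = mu_f, chi_min = chi_min,
                 z_in = z_in, z_out = z_out, alpha_coef = alpha_coef),
            class = "vf_viscous")
}

#' Vena-contracta area correction
#'
#' Quadratic correction coefficient `alpha(z) = 0.75 + 0.25 (z - z_out)^2 /
#' (z_in - z_out)^2` on the glottal channel, clamped to its boundary values
#' outside `[z_in, z_out]`.  The effective flow area is
#' `A(z) = alpha(z) A0(z)`.
#'
#' @param z Station coordinate(s) in mm.
#' @param params A `vf_viscous`.
#' @return Correction coefficient(s), dimensionless.
#' @export
alpha_correction <- function(z, params = viscous_params()) {
  zc <- pmin(pmax(z, params$z_in), params$z_out)
  params$alpha_coef[1] + params$alpha_coef[2] *
    (zc - params$z_out)^2 / (params$z_in - params$z_out)^2
}

#' Pressure-recovery profile
#'
#' chi = 1 at and upstream of the minimum-area station, `chi_min` strictly
#' downstream of it.
#'
#' @param channel A `vf_channel`.
#' @param chi_min Recovery constant in `[0, 1]`.
#' @return Numeric vector of chi at each station.
#' @export
chi_profile <- function(channel, chi_min = 0.2) {
  kmin <- min_area_station(channel)
  n <- nrow(channel)
  chi <- rep(1, n)
  if (kmin < n) chi[(kmin + 1L):n] <- chi_min
  chi
}

#' Solve the one-dimensional viscous glottal flow
#'
#' Quasi-steady solve of the collapsible-tube momentum balance on the
#' channel stations.  With the separation-loss closure the advection term
#' carries the factor chi, and friction enters as `-2 mu (S/A)^2 w`, so
#' the pressure gradient is `dp/dz = -chi rho_f w dw/dz - 2 mu (S/A)^2 w`
#' with `w = q / A` and `A = alpha(z) A0(z)`.  The pressure profile is
#' integrated from the inlet (where `p = p_sub`) with the chi switch located
#' exactly at the minimum-area station, and the flow rate `q` is found by
#' shooting: a bracketed Brent root solve of `p(z_out; q) = p_sup`, the
#' bracket grown geometrically from the inviscid-orifice estimate.
#'
#' @param channel A `vf_channel` (open; for a fully closed glottis the
#'   hydrostatic closed-glottis assignment is returned, flagged).
#' @param p_sub,p_sup Boundary pressures in kPa.
#' @param params A `vf_viscous`.
#' @param w_prev,dt Optional previous-step station velocities (mm/ms) and
#'   time step (ms); when supplied, the local acceleration term
#'   `rho_f (w - w_prev)/dt` is retained via backward difference.
#' @param tol Shooting tolerance on the outlet pressure in kPa.
#' @param q_bracket Optional initial upper bracket for the flow-rate root
#'   (mm^3/ms); grown geometrically if it does not contain the root.  The
#'   solution does not depend on this choice.
#' @return An object of class `vf_flow`: a tibble with stations `z`,
#'   velocity `w` (mm/ms = m/s), pressure `p` (kPa), effective area `A`
#'   (mm^2), and attributes `q` (flow rate, mm^3/ms), `closed`, `chi`.
#' @export
solve_viscous_flow <- function(channel, p_sub, p_sup, params = viscous_params(),
                               w_prev = NULL, dt = NULL, tol = 1e-8,
                               q_bracket = NULL) {
  stopifnot(is.finite(p_sub), is.finite(p_sup), p_sub >= p_sup)
  z <- channel$z
  A0 <- channel$area
  S <- channel$perimeter
  kmin <- min_area_station(channel)
  if (A0[kmin] <= 0) {
    p <- closed_glottis_pressure(A0, p_sub, p_sup)
    out <- tibble::tibble(z = z, w = 0, p = as.numeric(p), A = A0)
    return(structure(out, class = c("vf_flow", class(out)),
                     q = 0, closed = TRUE, chi = chi_profile(channel, params$chi_min)))
  }

  rho <- params$rho_f * KG_M3_TO_INTERNAL     # mg/mm^3
  mu <- params$mu_f * PA_S_TO_INTERNAL        # kPa*ms
  alpha <- alpha_correction(z, params)
  A <- alpha * A0
  chi <- chi_profile(channel, params$chi_min)
  n <- length(z)
  fric <- 2 * mu * (S / A)^2 / A              # * q = friction pressure gradient
  dz <- diff(z)

  unsteady <- !is.null(w_prev) && !is.null(dt)
  if (unsteady) stopifnot(length(w_prev) == n, dt > 0)

  outlet_pressure <- function(q) {
    w <- q / A
    # chi on the downstream side of each interval governs its advection
    chi_iv <- chi[-1]
    dp_kin <- -chi_iv * rho * (w[-1]^2 - w[-n]^2) / 2
    dp_fric <- -q * (fric[-1] + fric[-n]) / 2 * dz
    dp <- dp_kin + dp_fric
    if (unsteady) {
      acc <- rho * (w - w_prev) / dt
      dp <- dp - (acc[-1] + acc[-n]) / 2 * dz
    }
    p_sub + sum(dp)
  }
  pressure_profile <- function(q) {
    w <- q / A
    chi_iv <- chi[-1]
    dp <- -chi_iv * rho * (w[-1]^2 - w[-n]^2) / 2 -
      q * (fric[-1] + fric[-n]) / 2 * dz
    if (unsteady) {
      acc <- rho * (w - w_prev) / dt
      dp <- dp - (acc[-1] + acc[-n]) / 2 * dz
    }
    cumsum(c(p_sub, dp))
  }

  dP <- p_sub - p_sup
  if (dP <= tol) {
    q <- 0
  } else {
    # inviscid-orifice estimate for the bracket
    a_kin <- (1 - params$chi_min) / A[kmin]^2 + params$chi_min / A[n]^2 -
      1 / A[1]^2
    a_kin <- max(a_kin, 1e-12)
    q_est <- sqrt(2 * dP / (rho * a_kin))
    hi <- q_bracket %||% q_est
    f_hi <- outlet_pressure(hi) - p_sup
    grow <- 0L
    while (f_hi > 0 && grow < 60L) {
      hi <- hi * 2
      f_hi <- outlet_pressure(hi) - p_sup
      grow <- grow + 1L
    }
    if (f_hi > 0) {
      stop("shooting failure: no root for q in bracket [0, ", format(hi),
           "]; outlet residual ", format(f_hi), " kPa", call. = FALSE)
    }
    q <- stats::uniroot(function(qq) outlet_pressure(qq) - p_sup,
                        lower = 0, upper = hi, tol = tol / max(1, dP))$root
    # polish on the outlet pressure itself
    it <- 0L
    while (abs(outlet_pressure(q) - p_sup) > tol && it < 10L) {
      q <- stats::uniroot(function(qq) outlet_pressure(qq) - p_sup,
                          lower = 0, upper = hi,
                          tol = .Machine$double.eps^0.75)$root
      it <- it + 1L
    }
  }
  p <- pressure_profile(q)
  out <- tibble::tibble(z = z, w = q / A, p = p, A = A)
  structure(out, class = c("vf_flow", class(out)),
            q = q, closed = FALSE, chi = chi)
}
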