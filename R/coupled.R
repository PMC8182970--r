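#' Simulation configuration
#'
#' @param flow_model One of `"bernoulli_fixed"`, `"bernoulli_estimated"`,
#'   `"viscous"`, or `"none"` (structural dynamics only).  The two Bernoulli
#'   settings run the same forward physics; they differ in whether the
#'   separation ratio is a fixed or an estimated parameter during inference.
#' @param p_sub,p_sup Subglottal and supraglottal pressure in kPa.
#' @param r_sep Separation ratio for the Bernoulli model.
#' @param m Medial compression in mm.
#' @param dt Structural time step in ms.
#' @param duration Simulated time in ms.
#' @param transient_discard Initial transient to drop from the output, ms.
#' @param output_dt Output sampling interval in ms (waveform rate).
#' @param n_stations Channel stations for the flow models.
#' @param resolution Mesh resolution in mm (used when a helper builds the
#'   mesh for you).
#' @param viscous A `vf_viscous` parameter set.
#' @param perturb Optional list(`amplitude`, `seed`) adding a random initial
#'   velocity kick; by default simulations start from the precompressed
#'   equilibrium with the pressure loading switched on at t = 0, which is
#'   not a flow equilibrium, so oscillation onset occurs naturally.
#' @param blowup_limit Displacement magnitude (mm) treated as divergence.
#' @return A list of class `vf_config`.
#' @export
sim_config <- function(flow_model = c("bernoulli_fixed", "bernoulli_estimated",
                                      "viscous", "none"),
                       p_sub = 1.092, p_sup = 0, r_sep = 1.4, m = 0.4,
                       dt = 0.01, duration = 200, transient_discard = 50,
                       output_dt = 0.25, n_stations = 50, resolution = 0.3,
                       viscous = viscous_params(), perturb = NULL,
                       blowup_limit = 50) {
  flow_model <- match.arg(flow_model)
  stopifnot(dt > 0, duration > transient_discard, transient_discard >= 0,
            output_dt >= dt)
  structure(list(flow_model = flow_model, p_sub = p_sub, p_sup = p_sup,
                 r_sep = r_sep, m = m, dt = dt, duration = duration,
                 transient_discard = transient_discard, output_dt = output_dt,
                 n_stations = n_stations, resolution = resolution,
                 viscous = viscous, perturb = perturb,
                 blowup_limit = blowup_limit),
            class = "vf_config")
}

flow_code <- function(flow_model) {
  switch(flow_model, none = 0L, bernoulli_fixed = 1L,
         bernoulli_estimated = 1L, viscous = 2L,
         stop("unknown flow model: ", flow_model, call. = FALSE))
}

#' Observation series
#'
#' A uniformly sampled time series of length-averaged glottal width, the
#' observable the inference operates on.
#'
#' @param time_ms Time stamps in ms (uniform grid).
#' @param width_mm Length-averaged glottal width in mm (>= 0).
#' @param depth Anterior-posterior depth used for width-area conversion, mm.
#' @param noise_sd Noise standard deviation in width units (mm); 0 for
#'   noise-free model output.
#' @param meta Optional named list of provenance metadata.
#' @return A tibble of class `vf_obs`.
#' @export
observation_series <- function(time_ms, width_mm, depth = 14, noise_sd = 0,
                               meta = list()) {
  stopifnot(length(time_ms) == length(width_mm), all(width_mm >= 0))
  if (length(time_ms) > 2) {
    stopifnot(diff(range(diff(time_ms))) < 1e-8 * max(diff(time_ms)))
  }
  structure(tibble::tibble(time_ms = time_ms, width_mm = width_mm),
            class = c("vf_obs", class(tibble::tibble())),
            depth = depth, noise_sd = noise_sd, meta = meta)
}

obs_dt <- function(obs) if (nrow(obs) > 1) obs$time_ms[2] - obs$time_ms[1] else NA_real_

#' Trim an observation to a time window
#'
#' Keeps samples with `t_min <= time_ms <= t_max`, preserving the series
#' metadata (depth, noise level, provenance).  Typical use: restricting the
#' likelihood to a fit window while the simulation keeps an overhang for
#' lag registration.
#'
#' @param obs A `vf_obs`.
#' @param t_max,t_min Window bounds in ms.
#' @return A `vf_obs`.
#' @export
obs_window <- function(obs, t_max, t_min = 0) {
  sel <- obs$time_ms >= t_min & obs$time_ms <= t_max
  observation_series(obs$time_ms[sel], obs$width_mm[sel],
                     depth = attr(obs, "depth"),
                     noise_sd = attr(obs, "noise_sd"),
                     meta = attr(obs, "meta"))
}

#' Run the coupled forward model
#'
#' Advances the fluid-structure loop: per structural step the glottal
#' channel is extracted from the deformed surface, the chosen flow model
#' gives the station pressures, pressures are applied as consistent
#' inward-normal surface loads on the fluid-loaded boundary (subglottal
#' pressure below the channel inlet, supraglottal above the outlet), one
#' implicit Newmark step advances the solid, and contact with the
#' hemilaryngeal plane is enforced by projection.  The output is the
#' minimum-gap width waveform (the length-averaged glottal width) after
#' discarding the start-up transient; output times are re-zeroed at the end
#' of the discard window.
#'
#' @param config A `vf_config`.
#' @param mesh A `vf_mesh` (un-precompressed reference geometry).
#' @param mat A `vf_material`.
#' @param init_state Optional `vf_state` overriding the precompressed start.
#' @param precomp Optional `vf_precompress` (skips recomputing it).
#' @param keep_state If `TRUE`, attach the final state and energy audit.
#' @return A `vf_obs` (noise-free widths).
#' @export
run_forward <- function(config, mesh, mat, init_state = NULL, precomp = NULL,
                        keep_state = FALSE) {
  stopifnot(inherits(config, "vf_config"), inherits(mesh, "vf_mesh"),
            inherits(mat, "vf_material"))
  if (is.null(precomp)) precomp <- precompress(mesh, mat, config$m)
  smesh <- precomp$mesh
  sys <- precomp$system
  state0 <- init_state %||% precomp$state

  if (!is.null(config$perturb)) {
    set.seed(config$perturb$seed %||% 1L)
    amp <- config$perturb$amplitude %||% 0.01
    kick <- numeric(length(state0$v))
    kick[sys$free] <- rnorm(length(sys$free), sd = amp)
    state0$v <- state0$v + kick
  }

  flow <- list(model = flow_code(config$flow_model),
               p_sub = config$p_sub, p_sup = config$p_sup,
               r_sep = config$r_sep,
               rho_f = config$viscous$rho_f, mu_f = config$viscous$mu_f,
               chi_min = config$viscous$chi_min,
               alpha_coef = config$viscous$alpha_coef)

  n_steps <- round(config$duration / config$dt)
  stride <- max(1L, round(config$output_dt / config$dt))
  fr <- sys$free
  res <- cpp_simulate(sys$K[fr, fr], sys$D[fr, fr], sys$M[fr, fr],
                      fr, smesh$nodes, smesh$gamma_f,
                      smesh$contact_plane_x, smesh$depth,
                      smesh$z_in, smesh$z_out, config$n_stations,
                      flow, config$dt, n_steps, stride,
                      state0$u, state0$v, numeric(length(state0$u)),
                      config$blowup_limit)
  if (res$status != 0) {
    stop(structure(class = c("vf_sim_error", "error", "condition"),
                   list(message = res$message, call = sys.call())))
  }
  keep <- seq_len(res$n_recorded)
  times <- res$times[keep]
  width <- res$width[keep]
  sel <- times >= config$transient_discard - 1e-9
  obs <- observation_series(times[sel] - config$transient_discard,
                            pmax(0, width[sel]),
                            depth = smesh$depth, noise_sd = 0,
                            meta = list(flow_model = config$flow_model,
                                        p_sub = config$p_sub,
                                        r_sep = config$r_sep, m = config$m))
  if (keep_state) {
    attr(obs, "final_state") <- sim_state(smesh, u = res$u, v = res$v,
                                          a = res$a,
                                          t = n_steps * config$dt)
    attr(obs, "energy") <- res$energy
    attr(obs, "precompress") <- precomp
  }
  obs
}

#' Consistent nodal forces from a surface pressure
#'
#' Maps a station pressure distribution to nodal forces on the fluid-loaded
#' surface: the pressure is interpolated linearly to the surface nodes
#' (constant extension outside the station range unless `p_below` /
#' `p_above` are given), applied as inward-normal traction on each surface
#' edge, and integrated against the linear surface basis, so a linearly
#' varying pressure on an edge splits with the consistent 1/3-1/6 weights.
#' Forces carry the anterior-posterior depth (units mN).
#'
#' @param channel A `vf_channel` giving the station grid.
#' @param p Station pressures in kPa.
#' @param mesh A `vf_mesh`.
#' @param state Optional `vf_state` (forces follow the deformed surface).
#' @param p_below,p_above Pressure applied to surface nodes below/above the
#'   station range (defaults: the end-station values).
#' @return Full-dof nodal force vector in mN.
#' @export
pressure_to_forces <- function(channel, p, mesh, state = NULL,
                               p_below = NULL, p_above = NULL) {
  stopifnot(length(p) == nrow(channel))
  pos <- deformed_nodes(mesh, state)[mesh$gamma_f, , drop = FALSE]
  zn <- pos[, 2]
  pn <- approx(channel$z, p, xout = zn, rule = 2)$y
  if (!is.null(p_below)) pn[zn < channel$z[1]] <- p_below
  if (!is.null(p_above)) pn[zn > channel$z[nrow(channel)]] <- p_above

  f <- numeric(2L * nrow(mesh$nodes))
  ng <- length(mesh$gamma_f)
  for (e in seq_len(ng - 1L)) {
    dvec <- pos[e + 1L, ] - pos[e, ]
    len <- sqrt(sum(dvec^2))
    if (len == 0) next
    nrm <- c(dvec[2], -dvec[1]) / len   # outward normal of the solid
    wa <- len * mesh$depth * (pn[e] / 3 + pn[e + 1L] / 6)
    wb <- len * mesh$depth * (pn[e] / 6 + pn[e + 1L] / 3)
    na <- mesh$gamma_f[e]; nb <- mesh$gamma_f[e + 1L]
    f[2L * na - 1L] <- f[2L * na - 1L] - wa * nrm[1]
    f[2L * na]      <- f[2L * na]      - wa * nrm[2]
    f[2L * nb - 1L] <- f[2L * nb - 1L] - wb * nrm[1]
    f[2L * nb]      <- f[2L * nb]      - wb * nrm[2]
  }
  f
}

#' Register a simulated series against an observation
#'
#' Finds the non-negative integer lag (in observation samples) minimizing
#' the sum of squared residuals between the observation and the simulated
#' series sampled at the lagged observation times, then returns the aligned
#' residuals.  Periodic waveforms make a one-sided search sufficient
#' provided the maximum lag covers at least one period.
#'
#' @param sim,obs `vf_obs` series; the simulation must span the observation
#'   window plus the maximum lag.
#' @param max_lag Maximum lag in samples (default: a quarter of the
#'   observation, capped by the available simulated overhang).
#' @return List with `lag` (samples), `residuals` (mm), `sim_aligned`.
#' @export
register_series <- function(sim, obs, max_lag = NULL) {
  dt <- obs_dt(obs)
  interp <- function(tt) {
    if (nrow(sim) < 2) {
      out <- ifelse(abs(tt - sim$time_ms[1]) < 1e-9, sim$width_mm[1], NA_real_)
      return(out)
    }
    approx(sim$time_ms, sim$width_mm, xout = tt, rule = 1)$y
  }
  if (nrow(obs) < 2) {
    sim_w <- interp(obs$time_ms)
    if (anyNA(sim_w)) stop("alignment error: simulation does not cover the observation window",
                           call. = FALSE)
    return(list(lag = 0L, residuals = obs$width_mm - sim_w, sim_aligned = sim_w))
  }
  overhang <- max(sim$time_ms) - max(obs$time_ms)
  avail <- max(0L, floor(overhang / dt))
  max_lag <- min(max_lag %||% floor(nrow(obs) / 4), avail)
  best <- NULL
  for (lag in 0:max_lag) {
    tt <- obs$time_ms + lag * dt
    sw <- interp(tt)
    if (anyNA(sw)) next
    sse <- sum((obs$width_mm - sw)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(lag = lag, sse = sse, sim_aligned = sw)
    }
  }
  if (is.null(best)) {
    stop("alignment error: simulation does not cover the observation window",
         call. = FALSE)
  }
  list(lag = best$lag, residuals = obs$width_mm - best$sim_aligned,
       sim_aligned = best$sim_aligned)
}

#' Write / read an observation series as CSV
#'
#' Columns `time_ms`, `width_mm`; `#`-prefixed header comments carry the
#' depth, noise level, and provenance metadata as JSON.
#'
#' @param obs A `vf_obs`.
#' @param path File path.
#' @export
write_observation <- function(obs, path) {
  hdr <- c(
    sprintf("# depth_mm: %.10g", attr(obs, "depth")),
    sprintf("# noise_sd_mm: %.10g", attr(obs, "noise_sd")),
    sprintf("# meta: %s", jsonlite::toJSON(attr(obs, "meta"), auto_unbox = TRUE,
                                           digits = NA))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(obs)[, c("time_ms", "width_mm")], con,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_observation
#' @export
read_observation <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("^# ", key, ": "), "", hdr[startsWith(hdr, paste0("# ", key))])
  depth <- as.numeric(get("depth_mm"))
  noise <- as.numeric(get("noise_sd_mm"))
  meta <- jsonlite::fromJSON(get("meta"))
  df <- read.csv(text = lines[!startsWith(lines, "#")])
  observation_series(df$time_ms, df$width_mm, depth = depth,
                     noise_sd = noise, meta = as.list(meta))
}
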