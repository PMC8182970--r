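#' Simulation state
#'
#' Displacement coefficients and their first two time derivatives on the
#' nodal degrees of freedom.  Dof ordering is interleaved: dof `2i-1` is the
#' x-displacement of node `i`, dof `2i` its z-displacement.  Units: mm,
#' mm/ms, mm/ms^2.
#'
#' @param mesh A `vf_mesh`.
#' @param u,v,a Optional displacement/velocity/acceleration vectors
#'   (default zero).
#' @param t Time in ms.
#' @return An object of class `vf_state`.
#' @export
sim_state <- function(mesh, u = NULL, v = NULL, a = NULL, t = 0) {
  n <- 2L * nrow(mesh$nodes)
  z <- numeric(n)
  st <- list(t = t, u = u %||% z, v = v %||% z, a = a %||% z)
  stopifnot(length(st$u) == n, length(st$v) == n, length(st$a) == n)
  class(st) <- "vf_state"
  st
}

#' Deformed node positions
#'
#' @param mesh A `vf_mesh`.
#' @param state A `vf_state` (default: undeformed).
#' @return n x 2 matrix of deformed (x, z) positions in mm.
#' @export
deformed_nodes <- function(mesh, state = NULL) {
  if (is.null(state)) return(mesh$nodes)
  mesh$nodes + matrix(state$u, ncol = 2, byrow = TRUE)
}

#' Extract the glottal channel profile
#'
#' Discretizes the glottal channel between `z_in` and `z_out` into stations.
#' At each station the gap is the distance from the (deformed) fluid-loaded
#' surface to the contact plane, clamped at zero; the actual cross-sectional
#' area is gap x depth, and the wetted perimeter uses the high-aspect-ratio
#' rectangular duct convention S = 2 x depth (the two wide faces).  The
#' minimum-area station is recorded, ties broken toward the most superior
#' station.
#'
#' @param mesh A `vf_mesh`.
#' @param state A `vf_state` giving the deformation (default undeformed).
#' @param z_in,z_out Channel ends in mm (defaults from the mesh spec).
#' @param n_stations Number of uniformly spaced stations (default 50).
#' @return A tibble of class `vf_channel` with columns `z` (mm), `gap` (mm),
#'   `area` (mm^2), `perimeter` (mm), and attributes `min_station`, `depth`,
#'   `contact_plane_x`.
#' @export
extract_channel <- function(mesh, state = NULL, z_in = mesh$z_in,
                            z_out = mesh$z_out, n_stations = 50) {
  stopifnot(z_in < z_out, n_stations >= 2)
  pos <- deformed_nodes(mesh, state)[mesh$gamma_f, , drop = FALSE]

  zsurf <- pos[, 2]
  in_window <- which(zsurf >= z_in - 1e-9 & zsurf <= z_out + 1e-9)
  # contiguous span (plus one node beyond each end), so a node folded out of
  # the window is still caught by the single-valuedness check
  idx <- if (length(in_window) > 0) {
    seq(max(1L, min(in_window) - 1L), min(nrow(pos), max(in_window) + 1L))
  } else {
    seq_len(nrow(pos))
  }
  zw <- zsurf[idx]
  if (any(diff(zw) <= 0)) {
    stop("channel-extraction error: fluid surface is not single-valued in z ",
         "within [", z_in, ", ", z_out, "] (mesh fold-over?)", call. = FALSE)
  }

  z <- seq(z_in, z_out, length.out = n_stations)
  xs <- approx(zw, pos[idx, 1], xout = z, rule = 2)$y
  gap <- pmax(0, mesh$contact_plane_x - xs)
  channel_profile(z, gap, depth = mesh$depth,
                  contact_plane_x = mesh$contact_plane_x)
}

#' Construct a channel profile directly
#'
#' Useful for analytic test channels and for driving the flow solvers
#' without a mesh.
#'
#' @param z Station coordinates in mm (strictly increasing).
#' @param gap Gap widths in mm (>= 0).
#' @param depth Anterior-posterior depth in mm.
#' @param contact_plane_x Contact plane location (metadata only).
#' @return A tibble of class `vf_channel`.
#' @export
channel_profile <- function(z, gap, depth = 14, contact_plane_x = NA_real_) {
  stopifnot(length(z) == length(gap), all(diff(z) > 0), all(gap >= 0))
  area <- gap * depth
  ch <- tibble::tibble(z = z, gap = gap, area = area,
                       perimeter = rep(2 * depth, length(z)))
  # minimum-area station, ties toward the most superior station
  min_station <- length(area) + 1L - which.min(rev(area))
  structure(ch, class = c("vf_channel", class(ch)),
            min_station = as.integer(min_station), depth = depth,
            contact_plane_x = contact_plane_x)
}

#' @rdname channel_profile
#' @param channel A `vf_channel`.
#' @export
min_area_station <- function(channel) attr(channel, "min_station")
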