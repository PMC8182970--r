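#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_polygon
#'   geom_hline geom_col labs facet_wrap theme_minimal scale_fill_brewer
NULL

#' Plot an observation waveform
#'
#' @param object A `vf_obs`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vf_obs <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ms, y = .data$width_mm)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "length-averaged glottal width (mm)") +
    theme_minimal()
}

#' Plot a mesh colored by layer
#'
#' @param object A `vf_mesh`.
#' @param ... Unused.
#' @export
autoplot.vf_mesh <- function(object, ...) {
  tri <- object$triangles
  df <- tibble::tibble(
    x = object$nodes[t(tri), 1],
    z = object$nodes[t(tri), 2],
    id = rep(seq_len(nrow(tri)), each = 3),
    layer = rep(as.character(object$layer), each = 3)
  )
  ggplot(df, aes(x = .data$x, y = .data$z, group = .data$id,
                 fill = .data$layer)) +
    geom_polygon(colour = "grey30", linewidth = 0.05) +
    ggplot2::geom_vline(xintercept = object$contact_plane_x,
                        linetype = 2, colour = "red") +
    ggplot2::coord_equal() +
    scale_fill_brewer(palette = "Pastel1") +
    labs(x = "x (mm, medial-lateral)", y = "z (mm, inferior-superior)") +
    theme_minimal()
}

#' Plot posterior marginals
#'
#' Weighted histograms of the resampled ensemble per parameter, with the
#' posterior mean (solid) and, if known, the truth (dashed).
#'
#' @param object A `vf_posterior`.
#' @param ... Unused.
#' @export
autoplot.vf_posterior <- function(object, ...) {
  rs <- object$samples[object$resample_idx, , drop = FALSE]
  long <- tidyr::pivot_longer(rs, dplyr::everything(),
                              names_to = "parameter", values_to = "value")
  sm <- object$summary
  p <- ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = NA) +
    facet_wrap(~parameter, scales = "free") +
    ggplot2::geom_vline(data = sm, aes(xintercept = .data$estimate)) +
    labs(x = NULL, y = "resampled count") +
    theme_minimal()
  if ("truth" %in% names(sm)) {
    p <- p + ggplot2::geom_vline(data = sm, aes(xintercept = .data$truth),
                                 linetype = 2)
  }
  p
}

#' Plot a study result table
#'
#' Normalized estimates (estimate / truth) per parameter against the
#' permutation, one panel per parameter, the analogue of the flow-model
#' sensitivity figures.
#'
#' @param object A `vf_study`.
#' @param parameters Which parameters to show (default the three moduli and
#'   the subglottal pressure).
#' @param ... Unused.
#' @export
autoplot.vf_study <- function(object,
                              parameters = c("E_body", "E_slp", "E_lig", "p_sub"),
                              ...) {
  stopifnot("normalized_estimate" %in% names(object))
  df <- dplyr::filter(object, .data$parameter %in% parameters,
                      !is.na(.data$estimate))
  ggplot(df, aes(x = .data$permutation, y = .data$normalized_estimate,
                 colour = .data$observation, group = .data$observation)) +
    geom_point() + geom_line(linewidth = 0.3) +
    geom_hline(yintercept = 1, linetype = 2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = NULL, y = "estimate / truth") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cycle-resolved closure statistics of a width waveform
#'
#' Splits the waveform into cycles at upward crossings of half the 95th
#' percentile and reports each cycle's minimum and peak.  `closure_tol` is
#' the observational closure threshold: gaps below it are unresolvable by
#' the emulated video segmentation (and lie far below the 1 mm^2 area-noise
#' floor), so such cycles count as fully closed.
#'
#' @param obs A `vf_obs`.
#' @param closure_tol Closure threshold in mm (default 0.02).
#' @return A tibble with one row per cycle: `t_start`, `period_ms`,
#'   `min_width`, `peak_width`, `closed` (min below `closure_tol`),
#'   `contact` (exact zero width, i.e. node-on-plane contact).
#' @export
cycle_stats <- function(obs, closure_tol = 0.02) {
  w <- obs$width_mm
  t <- obs$time_ms
  th <- 0.5 * stats::quantile(w, 0.95)
  up <- which(diff(w > th) == 1)
  if (length(up) < 2) {
    return(tibble::tibble(t_start = numeric(0), period_ms = numeric(0),
                          min_width = numeric(0), peak_width = numeric(0),
                          closed = logical(0), contact = logical(0)))
  }
  purrr::map_dfr(seq_len(length(up) - 1), function(i) {
    seg <- w[up[i]:up[i + 1]]
    tibble::tibble(t_start = t[up[i]],
                   period_ms = t[up[i + 1]] - t[up[i]],
                   min_width = min(seg), peak_width = max(seg),
                   closed = min(seg) <= closure_tol,
                   contact = min(seg) <= 0)
  })
}
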