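#' Bernoulli flow model parameters
#'
#' @param p_sub Subglottal pressure in kPa.
#' @param p_sup Supraglottal pressure in kPa (default 0, fixed).
#' @param r_sep Flow separation ratio (>= 1): the flow detaches at the first
#'   station downstream of the minimum glottal area where the area reaches
#'   `r_sep` times the minimum area.
#' @return An object of class `vf_bernoulli`.
#' @export
bernoulli_params <- function(p_sub, p_sup = 0, r_sep = 1.4) {
  stopifnot(r_sep >= 1, p_sub >= p_sup)
  structure(list(p_sub = p_sub, p_sup = p_sup, r_sep = r_sep),
            class = "vf_bernoulli")
}

#' Intraglottal pressure from the Bernoulli model
#'
#' Upstream of the separation point the pressure follows the Bernoulli
#' relation `p = p_sub - (p_sub - p_sup) (A_sep / A)^2` with
#' `A_sep = r_sep * A_min`; at and downstream of the separation point the
#' pressure is `p_sup`.  The separation point is the first station
#' downstream of the minimum-area station whose area reaches `A_sep`;
#' stations upstream of the minimum always use the Bernoulli branch.  The
#' two branches agree where `A = A_sep`, so the distribution is continuous.
#'
#' For a fully closed glottis (minimum area zero) the flow stops and the
#' pressure is assigned hydrostatically: `p_sub` upstream of the first
#' closed station, zero over the contact zone, and `p_sup` downstream of the
#' last closed station; the result carries attribute `closed = TRUE`.
#'
#' @param channel A `vf_channel`.
#' @param params A `vf_bernoulli`.
#' @return Numeric vector of station pressures in kPa, with attribute
#'   `closed`.
#' @export
bernoulli_pressure <- function(channel, params) {
  A <- channel$area
  stopifnot(all(A >= 0))
  n <- length(A)
  kmin <- min_area_station(channel)
  if (A[kmin] <= 0) {
    return(closed_glottis_pressure(A, params$p_sub, params$p_sup))
  }
  A_sep <- params$r_sep * A[kmin]
  down <- if (kmin < n) (kmin + 1L):n else integer(0)
  sep_candidates <- down[A[down] >= A_sep]
  k_sep <- if (length(sep_candidates)) sep_candidates[1] else n + 1L
  p <- params$p_sub - (params$p_sub - params$p_sup) * (A_sep / A)^2
  if (k_sep <= n) p[k_sep:n] <- params$p_sup
  structure(p, closed = FALSE)
}

closed_glottis_pressure <- function(A, p_sub, p_sup) {
  closed <- which(A <= 0)
  p <- numeric(length(A))
  first <- closed[1]; last <- closed[length(closed)]
  if (first > 1) p[1:(first - 1L)] <- p_sub
  p[closed] <- 0
  if (last < length(A)) p[(last + 1L):length(A)] <- p_sup
  # open pockets inside the contact zone are stagnant: keep 0 there
  structure(p, closed = TRUE)
}
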