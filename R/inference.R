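#' Prior specification
#'
#' A named list of independent per-parameter distribution descriptors.
#' Supported families: `uniform(min, max)`, `normal(mean, sd)`, and
#' `point(value)`.
#'
#' @param ... Named descriptors, e.g. `E_body = prior_uniform(6, 18)`.
#' @return A list of class `vf_prior`.
#' @export
prior_spec <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && is.null(specs[[1]]$dist)) {
    specs <- specs[[1]]
  }
  if (is.null(names(specs)) || any(names(specs) == "")) {
    stop("configuration error: every prior component must be named", call. = FALSE)
  }
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (!is.list(s) || is.null(s$dist) ||
        !s$dist %in% c("uniform", "normal", "point")) {
      stop("configuration error: invalid prior descriptor for '", nm, "'",
           call. = FALSE)
    }
    if (s$dist == "uniform" && !(is.finite(s$min) && is.finite(s$max) && s$min <= s$max)) {
      stop("configuration error: bad uniform bounds for '", nm, "'", call. = FALSE)
    }
  }
  structure(specs, class = "vf_prior")
}

#' @rdname prior_spec
#' @param min,max Uniform bounds.
#' @export
prior_uniform <- function(min, max) list(dist = "uniform", min = min, max = max)

#' @rdname prior_spec
#' @param mean,sd Normal hyper-parameters.
#' @export
prior_normal <- function(mean, sd) list(dist = "normal", mean = mean, sd = sd)

#' @rdname prior_spec
#' @param value Point-mass location.
#' @export
prior_point <- function(value) list(dist = "point", value = value)

#' Default priors for the estimation study
#'
#' Independent uniforms around the nominal values: moduli within +/-50% of
#' nominal, subglottal pressure within +/-20%, density 900-1200 kg/m^3,
#' viscosity 0-10 Pa*s, medial compression 0.2-0.6 mm, and (for the
#' estimated-separation permutation) r_sep in 1.0-1.6.  `scale` shrinks the
#' half-widths of the bounded components toward the nominal, for scaled-down
#' studies.
#'
#' @param p_sub Nominal subglottal pressure in kPa.
#' @param mat Nominal `vf_material` supplying the moduli.
#' @param estimate_r_sep Include an r_sep component.
#' @param scale Multiplier on the half-width of each uniform (default 1).
#' @param eta_max Upper bound of the viscosity prior in Pa*s.
#' @return A `vf_prior`.
#' @export
default_prior <- function(p_sub = 1.092, mat = material_params(),
                          estimate_r_sep = FALSE, scale = 1, eta_max = 10) {
  u <- function(lo, hi, centre = (lo + hi) / 2) {
    half <- (hi - lo) / 2 * scale
    prior_uniform(centre - half, centre + half)
  }
  pr <- list(
    E_body = u(0.5 * mat$E_body, 1.5 * mat$E_body, mat$E_body),
    E_slp  = u(0.5 * mat$E_slp, 1.5 * mat$E_slp, mat$E_slp),
    E_lig  = u(0.5 * mat$E_lig, 1.5 * mat$E_lig, mat$E_lig),
    p_sub  = u(0.8 * p_sub, 1.2 * p_sub, p_sub),
    rho_b  = u(900, 1200, mat$rho_b),
    eta    = prior_uniform(0, eta_max * scale),
    m      = u(0.2, 0.6, 0.4)
  )
  if (estimate_r_sep) pr$r_sep <- prior_uniform(1.0, 1.6)
  prior_spec(pr)
}

#' Draw a parameter sample set from the prior
#'
#' @param prior A `vf_prior`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; same seed gives a bitwise-identical sample set.
#' @return A tibble with one column per parameter and `n` rows.
#' @export
sample_prior <- function(prior, n, seed = 1L) {
  stopifnot(inherits(prior, "vf_prior"), n >= 1)
  set.seed(seed)
  cols <- lapply(prior, function(s) {
    switch(s$dist,
           uniform = runif(n, s$min, s$max),
           normal = rnorm(n, s$mean, s$sd),
           point = rep(s$value, n))
  })
  tibble::as_tibble(cols)
}

#' Gaussian log-likelihood of an observation given a simulation
#'
#' Independent Gaussian errors over time points with an area-equivalent
#' standard deviation: the width standard deviation is
#' `sigma_area / depth`.  The simulated series is registered to the
#' observation grid by an integer-lag cross-correlation search before the
#' residuals are formed.  The additive normalization constant is omitted
#' (it cancels in normalized importance weights).
#'
#' @param sim Simulated `vf_obs` (noise-free model output).
#' @param obs Observed `vf_obs`.
#' @param sigma_area Noise standard deviation in area units (mm^2).
#' @param max_lag Optional registration lag cap (samples).
#' @return Log-density value (<= 0), with attribute `lag`.
#' @export
log_likelihood <- function(sim, obs, sigma_area = 1, max_lag = NULL) {
  depth <- attr(obs, "depth") %||% 14
  sigma_w <- sigma_area / depth
  reg <- register_series(sim, obs, max_lag = max_lag)
  ll <- -0.5 * sum((reg$residuals / sigma_w)^2)
  attr(ll, "lag") <- reg$lag
  ll
}

#' Importance-sampling posterior estimate
#'
#' Prior-as-proposal importance sampling: `n` draws from the prior are
#' pushed through the forward operator, weighted by the Gaussian likelihood
#' of the observation (so the prior density cancels), and multinomially
#' resampled.  Forward-run failures (e.g. blow-ups at extreme draws) receive
#' weight zero and are counted.  Posterior means and standard deviations are
#' computed from the normalized weights; the resampled index multiset is
#' retained.  The effective sample size `n_eff = 1 / sum(w^2)` is reported.
#'
#' @param prior A `vf_prior`.
#' @param obs Observed `vf_obs`.
#' @param forward Function mapping a named parameter vector (one prior draw)
#'   to a simulated `vf_obs`.
#' @param n Ensemble size.
#' @param seed Seed for the prior draws.
#' @param sigma_area Likelihood noise scale in mm^2.
#' @param resample_seed Seed of the decoupled resampling stream
#'   (default `seed + 10^6`).
#' @param max_lag Registration lag cap passed to [log_likelihood()].
#' @param progress Print a progress line every `progress` samples (0 = quiet).
#' @return An object of class `vf_posterior`.
#' @export
importance_estimate <- function(prior, obs, forward, n, seed = 1L,
                                sigma_area = 1, resample_seed = seed + 1000000L,
                                max_lag = NULL, progress = 0) {
  samples <- sample_prior(prior, n, seed = seed)
  ll <- rep(NA_real_, n)
  lag <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    theta <- unlist(samples[i, ])
    simi <- tryCatch(forward(theta), vf_sim_error = function(e) NULL,
                     error = function(e) NULL)
    if (!is.null(simi)) {
      l <- log_likelihood(simi, obs, sigma_area = sigma_area, max_lag = max_lag)
      ll[i] <- as.numeric(l)
      lag[i] <- attr(l, "lag")
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("  sample %d/%d (failures so far: %d)",
                      i, n, sum(is.na(ll[seq_len(i)]))))
    }
  }
  new_posterior(samples, ll, lag, resample_seed, sigma_area,
                truth = attr(obs, "meta")$truth)
}

#' Normalized importance weights from log-likelihoods
#'
#' Stabilized exponentiation (the maximum is subtracted first, so adding any
#' constant to all log-likelihoods leaves the weights unchanged); `NA`
#' entries (failed forward runs) receive weight zero.
#'
#' @param log_lik Vector of log-likelihood values, `NA` for failures.
#' @return Normalized weight vector summing to 1.
#' @export
importance_weights <- function(log_lik) {
  ok <- is.finite(log_lik)
  if (!any(ok)) {
    stop("degenerate-posterior error: all importance weights are zero; ",
         "widen the priors or increase sigma_area", call. = FALSE)
  }
  w <- numeric(length(log_lik))
  w[ok] <- exp(log_lik[ok] - max(log_lik[ok]))
  w / sum(w)
}

#' Posterior ensemble from precomputed samples and log-likelihoods
#'
#' Constructor used by [importance_estimate()] and available for custom
#' forward loops: weights, multinomial resampling, and weighted summaries
#' from an existing (samples, log-likelihood) ensemble.
#'
#' @param samples Data frame of prior draws (one column per parameter).
#' @param log_lik Log-likelihood per draw (`NA` = failed forward run).
#' @param resample_seed Seed of the resampling stream.
#' @param sigma_area Noise scale the log-likelihoods were computed with.
#' @param truth Optional named truth values for normalized estimates.
#' @return A `vf_posterior`.
#' @export
posterior_from_ensemble <- function(samples, log_lik, resample_seed = 1L,
                                    sigma_area = 1, truth = NULL) {
  new_posterior(tibble::as_tibble(samples), log_lik,
                rep(NA_integer_, length(log_lik)), resample_seed, sigma_area,
                truth = truth)
}

new_posterior <- function(samples, ll, lag, resample_seed, sigma_area,
                          truth = NULL) {
  n <- nrow(samples)
  ok <- is.finite(ll)
  w <- importance_weights(ll)
  n_eff <- 1 / sum(w^2)
  set.seed(resample_seed)
  resample_idx <- sample.int(n, n, replace = TRUE, prob = w)
  est <- vapply(samples, function(x) sum(w * x), numeric(1))
  std <- sqrt(pmax(0, vapply(seq_along(samples), function(j) {
    sum(w * (samples[[j]] - est[j])^2)
  }, numeric(1))))
  summary <- tibble::tibble(
    parameter = names(samples),
    estimate = unname(est),
    std = unname(std),
    relative_uncertainty_pct = 100 * unname(std) / unname(est)
  )
  if (!is.null(truth)) {
    tr <- unlist(truth)[summary$parameter]
    summary$truth <- unname(tr)
    summary$normalized_estimate <- summary$estimate / summary$truth
  }
  structure(list(samples = samples, log_lik = ll, lag = lag, weights = w,
                 resample_idx = resample_idx, summary = summary,
                 n_eff = n_eff, n_failures = sum(!ok),
                 sigma_area = sigma_area),
            class = "vf_posterior")
}

#' @export
print.vf_posterior <- function(x, ...) {
  cat("<vf_posterior> n =", length(x$weights), " n_eff =",
      signif(x$n_eff, 4), " failures =", x$n_failures, "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a posterior ensemble
#'
#' @param x A `vf_posterior`.
#' @param ... Unused.
#' @return The per-parameter summary tibble: estimate, posterior standard
#'   deviation, relative uncertainty (std as % of the estimate), and, when
#'   the observation carried a truth manifest, the truth and the normalized
#'   estimate (estimate / truth).
#' @export
tidy.vf_posterior <- function(x, ...) x$summary

#' @rdname tidy.vf_posterior
#' @export
glance.vf_posterior <- function(x, ...) {
  tibble::tibble(n = length(x$weights), n_eff = x$n_eff,
                 failures = x$n_failures,
                 max_log_lik = max(x$log_lik, na.rm = TRUE))
}

#' Forward operator bound to a mesh and configuration
#'
#' Returns a function mapping a named parameter vector (fields `E_body`,
#' `E_slp`, `E_lig`, `p_sub`, `rho_b`, `eta`, `m`, optionally `r_sep`) to a
#' simulated observation series, suitable for [importance_estimate()].
#' Fixed quantities (epithelium modulus, Poisson ratio, supraglottal
#' pressure) come from `mat_fixed` and `config`.
#'
#' @param mesh A `vf_mesh`.
#' @param config A `vf_config` (flow model, durations, fixed r_sep, ...).
#' @param mat_fixed A `vf_material` supplying E_epi and nu.
#' @return `function(theta) -> vf_obs`.
#' @export
forward_operator <- function(mesh, config, mat_fixed = material_params()) {
  force(mesh); force(config); force(mat_fixed)
  function(theta) {
    theta <- as.list(theta)
    mat <- material_params(
      E_body = theta$E_body %||% mat_fixed$E_body,
      E_slp = theta$E_slp %||% mat_fixed$E_slp,
      E_lig = theta$E_lig %||% mat_fixed$E_lig,
      E_epi = mat_fixed$E_epi, nu = mat_fixed$nu,
      rho_b = theta$rho_b %||% mat_fixed$rho_b,
      eta = theta$eta %||% mat_fixed$eta
    )
    cfg <- config
    cfg$p_sub <- theta$p_sub %||% config$p_sub
    cfg$m <- theta$m %||% config$m
    if (!is.null(theta$r_sep)) cfg$r_sep <- theta$r_sep
    run_forward(cfg, mesh, mat)
  }
}
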