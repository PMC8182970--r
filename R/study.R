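#' Flow-model permutations
#'
#' Builds the permutation table of the estimation study: Bernoulli with
#' fixed separation ratio swept over a range, optionally the
#' estimated-separation Bernoulli permutation, and the single viscous
#' permutation.
#'
#' @param r_sep_fixed Fixed separation ratios (default 1.0 to 1.6 by 0.1).
#' @param include_estimated Include the estimated-r_sep Bernoulli
#'   permutation.
#' @param include_viscous Include the viscous permutation.
#' @return A tibble with columns `permutation`, `flow_model`, `r_sep`.
#' @export
study_permutations <- function(r_sep_fixed = seq(1.0, 1.6, by = 0.1),
                               include_estimated = TRUE,
                               include_viscous = TRUE) {
  rows <- lapply(r_sep_fixed, function(r) {
    tibble::tibble(permutation = sprintf("bernoulli_rsep_%.1f", r),
                   flow_model = "bernoulli_fixed", r_sep = r)
  })
  if (include_estimated) {
    rows <- c(rows, list(tibble::tibble(permutation = "bernoulli_estimated",
                                        flow_model = "bernoulli_estimated",
                                        r_sep = NA_real_)))
  }
  if (include_viscous) {
    rows <- c(rows, list(tibble::tibble(permutation = "viscous",
                                        flow_model = "viscous",
                                        r_sep = NA_real_)))
  }
  dplyr::bind_rows(rows)
}

#' Parse a permutation range string
#'
#' Accepts `"bernoulli:1.0..1.6:0.1"` (fixed-ratio sweep),
#' `"bernoulli:estimated"`, `"viscous"`, or a comma-separated combination.
#'
#' @param text Permutation specification string.
#' @return A permutation tibble as from [study_permutations()].
#' @export
parse_permutations <- function(text) {
  parts <- trimws(strsplit(text, ",")[[1]])
  out <- list()
  for (p in parts) {
    if (p == "viscous") {
      out <- c(out, list(study_permutations(numeric(0), FALSE, TRUE)))
    } else if (p == "bernoulli:estimated") {
      out <- c(out, list(study_permutations(numeric(0), TRUE, FALSE)))
    } else if (grepl("^bernoulli:[0-9.]+\\.\\.[0-9.]+:[0-9.]+$", p)) {
      m <- regmatches(p, regexec("^bernoulli:([0-9.]+)\\.\\.([0-9.]+):([0-9.]+)$", p))[[1]]
      lo <- as.numeric(m[2]); hi <- as.numeric(m[3]); by <- as.numeric(m[4])
      out <- c(out, list(study_permutations(seq(lo, hi, by = by), FALSE, FALSE)))
    } else if (grepl("^bernoulli:[0-9.]+$", p)) {
      r <- as.numeric(sub("^bernoulli:", "", p))
      out <- c(out, list(study_permutations(r, FALSE, FALSE)))
    } else {
      stop("usage error: cannot parse permutation '", p, "'", call. = FALSE)
    }
  }
  dplyr::bind_rows(out)
}

#' Run the flow-model sensitivity study
#'
#' For each (observation, permutation) pair, runs an importance-sampling
#' estimate and collects the per-parameter summaries: estimate, posterior
#' standard deviation, relative uncertainty, and (for synthetic twins with a
#' truth manifest) the normalized estimate.  Failures in one cell are
#' recorded and do not stop the study.
#'
#' @param obs_set A `vf_obs` or list of them (one per subglottal pressure).
#' @param permutations Permutation tibble from [study_permutations()] /
#'   [parse_permutations()].
#' @param mesh A `vf_mesh` shared by all forward runs.
#' @param config `vf_config` template (durations, mesh resolution etc.).
#' @param prior Base `vf_prior` WITHOUT r_sep; the estimated-separation
#'   permutation adds `r_sep ~ U(1.0, 1.6)` automatically.
#' @param n Ensemble size per cell.
#' @param seed Base seed; cell (i, j) derives its own seed.
#' @param sigma_area Likelihood noise scale (mm^2).
#' @param max_lag Registration cap, passed through.
#' @param progress Progress reporting interval (0 = quiet).
#' @return A tibble of class `vf_study`: one row per observation,
#'   permutation, and parameter, with `n_eff`, `failures`, and `error`
#'   columns; the posterior objects are attached as attribute `posteriors`.
#' @export
run_study <- function(obs_set, permutations, mesh, config, prior, n,
                      seed = 1L, sigma_area = 1, max_lag = NULL,
                      progress = 0) {
  stopifnot(nrow(permutations) >= 1)
  if (inherits(obs_set, "vf_obs")) obs_set <- list(obs_set)
  if (is.null(names(obs_set))) {
    names(obs_set) <- vapply(seq_along(obs_set), function(i) {
      ps <- attr(obs_set[[i]], "meta")$p_sub %||%
        attr(obs_set[[i]], "meta")$truth$p_sub
      if (is.null(ps)) sprintf("obs%d", i) else sprintf("psub_%.3f", ps)
    }, character(1))
  }
  rows <- list()
  posteriors <- list()
  cell <- 0L
  for (i in seq_along(obs_set)) {
    for (j in seq_len(nrow(permutations))) {
      cell <- cell + 1L
      perm <- permutations[j, ]
      cfg <- config
      cfg$flow_model <- perm$flow_model
      if (!is.na(perm$r_sep)) cfg$r_sep <- perm$r_sep
      pr <- prior
      if (perm$flow_model == "bernoulli_estimated" && is.null(pr$r_sep)) {
        pr <- prior_spec(c(unclass(pr), list(r_sep = prior_uniform(1.0, 1.6))))
      }
      fwd <- forward_operator(mesh, cfg)
      if (progress > 0) {
        message(sprintf("study cell %d: obs %s, permutation %s",
                        cell, names(obs_set)[i], perm$permutation))
      }
      post <- tryCatch(
        importance_estimate(pr, obs_set[[i]], fwd, n,
                            seed = seed + 7919L * cell,
                            sigma_area = sigma_area, max_lag = max_lag,
                            progress = progress),
        error = function(e) e)
      if (inherits(post, "error")) {
        rows[[cell]] <- tibble::tibble(
          observation = names(obs_set)[i],
          permutation = perm$permutation, parameter = NA_character_,
          estimate = NA_real_, std = NA_real_,
          relative_uncertainty_pct = NA_real_, n_eff = NA_real_,
          failures = NA_integer_, error = conditionMessage(post))
        next
      }
      posteriors[[paste(names(obs_set)[i], perm$permutation, sep = "|")]] <- post
      sm <- tidy(post)
      sm$observation <- names(obs_set)[i]
      sm$permutation <- perm$permutation
      sm$n_eff <- post$n_eff
      sm$failures <- post$n_failures
      sm$error <- NA_character_
      rows[[cell]] <- sm
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "observation", "permutation")
  structure(out, class = c("vf_study", class(out)), posteriors = posteriors)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
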