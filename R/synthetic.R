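#' Generate a synthetic ground-truth observation
#'
#' Runs the forward model at known "true" parameters and adds unbiased
#' Gaussian noise with area-equivalent standard deviation
#' `noise_sigma_area` (the width-equivalent standard deviation is
#' `noise_sigma_area / depth`).  Negative noisy widths are clipped at zero
#' and the clip count recorded; the truth and seed are stored in the
#' metadata so the observation is exactly reproducible.
#'
#' @param truth Named list/vector: `E_body`, `E_slp`, `E_lig`, `p_sub`,
#'   `rho_b`, `eta`, `m`, and `r_sep` for the Bernoulli generator.
#' @param flow_model Generator flow model (`"bernoulli_fixed"` or
#'   `"viscous"`).
#' @param noise_sigma_area Noise standard deviation in mm^2 (default 1).
#' @param seed Noise seed.
#' @param mesh Optional `vf_mesh` (default: built at `config$resolution`).
#' @param config Optional `vf_config` template (durations etc.).
#' @param mat_fixed `vf_material` supplying the fixed E_epi and nu.
#' @return A `vf_obs` with truth metadata.
#' @export
make_observation <- function(truth, flow_model = "viscous",
                             noise_sigma_area = 1, seed = 1L, mesh = NULL,
                             config = NULL, mat_fixed = material_params()) {
  config <- config %||% sim_config(flow_model)
  config$flow_model <- flow_model
  mesh <- mesh %||% build_m5_mesh(config$resolution)
  truth <- as.list(truth)
  clean <- forward_operator(mesh, config, mat_fixed)(unlist(truth))
  depth <- attr(clean, "depth")
  sigma_w <- noise_sigma_area / depth
  set.seed(seed)
  noisy <- clean$width_mm + rnorm(nrow(clean), 0, sigma_w)
  clipped <- sum(noisy < 0)
  observation_series(clean$time_ms, pmax(0, noisy), depth = depth,
                     noise_sd = sigma_w,
                     meta = list(truth = truth, seed = seed,
                                 flow_model = flow_model,
                                 noise_sigma_area = noise_sigma_area,
                                 clipped = clipped))
}

#' Default truth parameters of the synthetic study
#'
#' The silicone analogue's measured moduli with the package's nominal
#' density, viscosity, medial compression, and separation ratio.
#'
#' @param p_sub Subglottal pressure in kPa.
#' @param mat A `vf_material` supplying the material nominals.
#' @param r_sep Separation ratio recorded for Bernoulli generators.
#' @export
default_truth <- function(p_sub = 1.092, mat = material_params(),
                          r_sep = 1.4) {
  list(E_body = mat$E_body, E_slp = mat$E_slp, E_lig = mat$E_lig,
       p_sub = p_sub, rho_b = mat$rho_b, eta = mat$eta, m = 0.4,
       r_sep = r_sep)
}

#' Generate the full synthetic observation suite
#'
#' One observation per experimental subglottal pressure (0.910, 1.001,
#' 1.092, 1.183 kPa by default), written as CSV files plus a JSON manifest
#' of truths and seeds.  Regenerating from the manifest reproduces the CSVs
#' bitwise.  An existing manifest is never overwritten unless
#' `overwrite = TRUE`.
#'
#' @param dir Output directory.
#' @param p_subs Subglottal pressures in kPa.
#' @param flow_model Generator flow model.
#' @param noise_sigma_area Noise level in mm^2.
#' @param seed Base seed; observation i uses `seed + i - 1`.
#' @param config Optional `vf_config` template.
#' @param mesh Optional prebuilt `vf_mesh`.
#' @param overwrite Allow overwriting an existing manifest.
#' @return Invisibly, a list with the observation paths and the manifest.
#' @export
make_suite <- function(dir, p_subs = c(0.910, 1.001, 1.092, 1.183),
                       flow_model = "viscous", noise_sigma_area = 1,
                       seed = 1L, config = NULL, mesh = NULL,
                       overwrite = FALSE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("make_suite will not mutate an existing suite: ", manifest_path,
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- config %||% sim_config(flow_model)
  mesh <- mesh %||% build_m5_mesh(config$resolution)
  entries <- list()
  paths <- character(0)
  for (i in seq_along(p_subs)) {
    truth <- default_truth(p_sub = p_subs[i])
    obs <- make_observation(truth, flow_model = flow_model,
                            noise_sigma_area = noise_sigma_area,
                            seed = seed + i - 1L, mesh = mesh,
                            config = config)
    fn <- sprintf("obs_psub_%0.3f.csv", p_subs[i])
    write_observation(obs, file.path(dir, fn))
    paths <- c(paths, file.path(dir, fn))
    entries[[i]] <- list(file = fn, p_sub = p_subs[i], truth = truth,
                         seed = seed + i - 1L,
                         clipped = attr(obs, "meta")$clipped)
  }
  manifest <- list(flow_model = flow_model,
                   noise_sigma_area = noise_sigma_area,
                   resolution = config$resolution,
                   duration = config$duration,
                   transient_discard = config$transient_discard,
                   output_dt = config$output_dt,
                   observations = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest,
                 manifest_path = manifest_path))
}
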