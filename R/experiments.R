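#' Configuration of a simulation study
#'
#' Bundles every parameter of the scripted Shepp-Logan studies: geometry,
#' phantom variant, dense-view prior protocol, noise and reconstruction
#' settings. Defaults reproduce the reference few-view experiment:
#' 256 x 256 high-contrast Shepp-Logan, 60 views over 360 degrees at
#' 500/1000 mm source/detector radii on a 512 x 1 mm panel, prior from a
#' 360-view FBP, 50 main iterations, `alpha = 0.85`.
#'
#' @param image_n image side, pixels.
#' @param n_det detector elements.
#' @param n_views few-view count.
#' @param dense_views prior-scan view count.
#' @param det_pitch detector pitch, mm.
#' @param pixel_size image pixel size, mm.
#' @param sod,sdd source-to-axis / source-to-detector distances, mm.
#' @param variant Shepp-Logan variant, see [shepp_logan_spec()].
#' @param noise additive white-noise fraction on the few-view sinogram.
#' @param seed top-level seed; all randomness (noise, optional ray
#'   shuffles) flows from it.
#' @param profile_row row for line profiles (1-based from the top).
#' @param params a [recon_params()].
#' @param fbp_filter filter for the prior FBP.
#' @param prior_simulation how the dense-view prior scan is simulated,
#'   see [make_prior()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(image_n = 256L, n_det = 512L, n_views = 60L,
                         dense_views = 360L, det_pitch = 1.0,
                         pixel_size = 1.0, sod = 500, sdd = 1000,
                         variant = "high_contrast", noise = 0,
                         seed = 1L, profile_row = 128L,
                         params = recon_params(),
                         fbp_filter = "ram-lak",
                         prior_simulation = "analytic") {
  stopifnot(inherits(params, "recon_params"), noise >= 0)
  structure(list(image_n = as.integer(image_n), n_det = as.integer(n_det),
                 n_views = as.integer(n_views),
                 dense_views = as.integer(dense_views),
                 det_pitch = det_pitch, pixel_size = pixel_size,
                 sod = sod, sdd = sdd, variant = variant, noise = noise,
                 seed = as.integer(seed),
                 profile_row = as.integer(profile_row), params = params,
                 fbp_filter = fbp_filter,
                 prior_simulation = prior_simulation),
            class = "study_config")
}

config_geometry <- function(config, n_views = config$n_views) {
  scan_geometry(sod = config$sod, sdd = config$sdd, n_views = n_views,
                n_det = config$n_det, det_pitch = config$det_pitch,
                image_n = config$image_n, pixel_size = config$pixel_size)
}

#' Simulate a few-view sinogram from a phantom
#'
#' Rasterizes the phantom on the reconstruction grid, forward-projects it
#' with the study geometry and optionally adds white noise.
#'
#' @param config a [study_config()].
#' @return A list with `truth` ([image_grid()]), `sino` ([sinogram()])
#'   and `geom`.
#' @export
simulate_sinogram <- function(config) {
  stopifnot(inherits(config, "study_config"))
  geom <- config_geometry(config)
  truth <- rasterize(shepp_logan_spec(config$variant), geom$image_n,
                     pixel_size = geom$pixel_size)
  sino <- forward_project(truth, geom)
  if (config$noise > 0)
    sino <- add_white_noise(sino, config$noise, seed = config$seed)
  list(truth = truth, sino = sino, geom = geom)
}

run_study <- function(config, algorithms, outdir = NULL) {
  sim <- simulate_sinogram(config)
  spec <- shepp_logan_spec(config$variant)
  prior <- make_prior(spec, sim$geom, dense_views = config$dense_views,
                      filter = config$fbp_filter,
                      simulation = config$prior_simulation)
  params <- config$params
  params$seed <- if (is.null(params$seed)) NULL else params$seed
  arms <- list()
  for (alg in algorithms) {
    arms[[alg]] <- switch(alg,
      "art" = art_reconstruct(sim$sino, sim$geom, params = params,
                              truth = sim$truth),
      "asd-pocs" = asd_pocs_reconstruct(sim$sino, sim$geom, params = params,
                                        truth = sim$truth),
      "api-tv" = api_tv_reconstruct(sim$sino, sim$geom, prior = prior,
                                    params = params, truth = sim$truth),
      stop("unknown algorithm: ", alg, call. = FALSE))
  }
  row <- config$profile_row
  bundle <- list(
    config = config,
    truth = sim$truth,
    sino = sim$sino,
    prior = prior,
    results = arms,
    final_errors = vapply(arms, function(r)
      r$error_history[r$iterations_run], numeric(1)),
    profiles = c(list(truth = extract_profile(sim$truth, row)),
                 lapply(arms, function(r) extract_profile(r$image, row))),
    curves = lapply(arms, convergence_curve))
  if (!is.null(outdir)) write_study_bundle(bundle, outdir)
  bundle
}

#' Noise-free few-view study
#'
#' End-to-end reproduction of the noise-free simulation: generates the
#' Shepp-Logan truth and its 60-view sinogram, builds the dense-view FBP
#' prior, runs ART, ASD-POCS and API-TV, and collects final errors, row
#' profiles and convergence curves. When `outdir` is given, images are
#' written as 32-bit float TIFF and curves/profiles as CSV alongside a
#' manifest of every resolved parameter.
#'
#' @param config a [study_config()] (noise forced to 0).
#' @param outdir optional output directory.
#' @return A result bundle: `truth`, `sino`, `prior`, `results` (named
#'   list of `recon_result`), `final_errors`, `profiles`, `curves`.
#' @export
run_noise_free_study <- function(config = study_config(), outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  config$noise <- 0
  run_study(config, c("art", "asd-pocs", "api-tv"), outdir)
}

#' Noisy few-view study
#'
#' As [run_noise_free_study()] but with additive white noise (default 10%)
#' on the few-view sinogram, comparing the ASD-POCS and API-TV arms.
#' Deterministic given `config$seed`.
#'
#' @param config a [study_config()]; a zero `noise` field is promoted to
#'   the reference 10% level.
#' @param outdir optional output directory.
#' @return A result bundle, see [run_noise_free_study()].
#' @export
run_noisy_study <- function(config = study_config(noise = 0.10),
                            outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (config$noise <= 0) config$noise <- 0.10
  run_study(config, c("asd-pocs", "api-tv"), outdir)
}

#' Relative dose of a few-view scan
#'
#' Fraction of the full-scan dose delivered by a few-view scan, assuming
#' equal per-view exposure: `few_views / full_views`.
#'
#' @param few_views,full_views view counts (>= 1).
#' @return A fraction.
#' @export
dose_ratio <- function(few_views, full_views) {
  if (any(few_views < 1) || any(full_views < 1))
    stop("view counts must be >= 1", call. = FALSE)
  few_views / full_views
}

write_study_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_image_tiff(bundle$truth, file.path(outdir, "truth.tif"))
  write_image_tiff(bundle$prior, file.path(outdir, "prior.tif"))
  for (alg in names(bundle$results)) {
    write_image_tiff(bundle$results[[alg]]$image,
                     file.path(outdir, paste0(alg, ".tif")))
    write.csv(bundle$curves[[alg]],
              file.path(outdir, paste0(alg, "-curve.csv")),
              row.names = FALSE)
  }
  prof <- as.data.frame(bundle$profiles)
  write.csv(prof, file.path(outdir, "profiles.csv"), row.names = FALSE)
  cfg <- bundle$config
  manifest <- c(unclass(cfg)[setdiff(names(cfg), "params")],
                list(params = unclass(cfg$params)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
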