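# Shared study runs for the acceptance tests, computed once per session.
# The reference study is the full 256x256 / 60-view / 50-iteration setup;
# the scaled profile (128x128 image, 256 detector bins) is used where the
# full size adds nothing.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

reference_noise_free_run <- function() {
  cached("noise_free_256", run_noise_free_study(study_config()))
}

reference_noisy_run <- function() {
  cached("noisy_256", run_noisy_study(study_config(noise = 0.10, seed = 1)))
}

scaled_config <- function(...) {
  study_config(image_n = 128L, n_det = 256L, profile_row = 64L, ...)
}

scaled_noise_free_run <- function() {
  cached("noise_free_128",
         run_noise_free_study(scaled_config(params = recon_params(n_main = 30))))
}
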