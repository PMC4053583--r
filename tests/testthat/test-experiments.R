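# Module tests run the scaled study profile (128x128 image, 256 detector
# bins, 30 main iterations); the full 256x256 reference study is exercised
# by the acceptance suite.

test_that("the noise-free study bundle has the documented contract", {
  outdir <- withr::local_tempdir()
  b <- scaled_noise_free_run()
  write_study_bundle <- apitv:::write_study_bundle
  write_study_bundle(b, outdir)

  expect_named(b$results, c("art", "asd-pocs", "api-tv"))
  expect_s3_class(b$truth, "image_grid")
  expect_s3_class(b$prior, "image_grid")
  expect_length(b$final_errors, 3L)
  expect_true(all(vapply(b$curves, nrow, 0L) == 30L))
  expect_length(b$profiles$truth, 128L)

  for (f in c("truth.tif", "prior.tif", "art.tif", "asd-pocs.tif",
              "api-tv.tif", "profiles.csv", "manifest.yaml"))
    expect_true(file.exists(file.path(outdir, f)))
  back <- read_image_tiff(file.path(outdir, "truth.tif"))
  expect_equal(back$data, b$truth$data, tolerance = 1e-5)
  manifest <- yaml::read_yaml(file.path(outdir, "manifest.yaml"))
  expect_equal(manifest$params$alpha, 0.85)
  expect_equal(manifest$n_views, 60L)
})

test_that("TV regularization beats plain ART on scaled few-view data", {
  b <- scaled_noise_free_run()
  expect_lt(b$final_errors[["asd-pocs"]], b$final_errors[["art"]])
  expect_lt(b$final_errors[["api-tv"]], b$final_errors[["art"]])
  # row-profile deviation ordering matches the image-error ordering
  msd <- vapply(b$profiles[c("art", "asd-pocs")], function(p)
    mean((p - b$profiles$truth)^2), numeric(1))
  expect_lt(msd[["asd-pocs"]], msd[["art"]])
})

test_that("noisy studies are seed-deterministic and noise never helps", {
  cfg <- scaled_config(noise = 0.10, seed = 5,
                       params = recon_params(n_main = 10))
  n1 <- run_noisy_study(cfg)
  n2 <- run_noisy_study(cfg)
  expect_identical(n1$results$`api-tv`$image$data,
                   n2$results$`api-tv`$image$data)
  expect_named(n1$results, c("asd-pocs", "api-tv"))

  clean <- run_noise_free_study(scaled_config(
    seed = 5, params = recon_params(n_main = 10)))
  for (alg in c("asd-pocs", "api-tv"))
    expect_gt(n1$final_errors[[alg]], clean$final_errors[[alg]])
})

test_that("studies rerun bit-identically from their configuration", {
  cfg <- scaled_config(params = recon_params(n_main = 3))
  a <- run_noise_free_study(cfg)
  b <- run_noise_free_study(cfg)
  for (alg in names(a$results))
    expect_identical(a$results[[alg]]$image$data,
                     b$results[[alg]]$image$data)
})

test_that("dose_ratio is the exact view-count fraction", {
  expect_identical(dose_ratio(120, 360), 1 / 3)
  expect_identical(dose_ratio(60, 360), 1 / 6)
  expect_identical(dose_ratio(77, 77), 1)
  expect_error(dose_ratio(0, 360), ">= 1")
  expect_error(dose_ratio(10, 0), ">= 1")
})
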