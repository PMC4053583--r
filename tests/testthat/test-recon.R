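# A small determined system: 2 views at right angles, 2 rays each,
# hitting a 2x2 image.
square_system <- function() {
  scan_geometry(sod = 50, sdd = 100, n_views = 2,
                angles = c(0, pi / 2), n_det = 2, det_pitch = 2,
                image_n = 2, pixel_size = 1)
}

test_that("ART sweeps converge on a consistent system", {
  g <- square_system()
  truth <- matrix(c(1, 2, 3, 4), 2, 2)
  sino <- forward_project(truth, g)
  f <- matrix(0, 2, 2)
  for (i in 1:50) f <- art_sweep(f, sino, g)$data
  resid <- forward_project(f, g)$data - sino$data
  expect_lt(sqrt(sum(resid^2)), 1e-10)

  # starting at a solution, a sweep changes nothing
  f2 <- art_sweep(truth, sino, g)$data
  expect_equal(f2, truth, tolerance = 1e-14)

  # zero data, zero start stays zero
  z <- art_sweep(matrix(0, 2, 2), sinogram(matrix(0, 2, 2), g), g)$data
  expect_identical(z, matrix(0, 2, 2))
})

test_that("positivity projection clips negatives and is idempotent", {
  expect_identical(enforce_positivity(matrix(c(1, 2), 1)),
                   matrix(c(1, 2), 1))
  expect_identical(enforce_positivity(matrix(c(-1, 2), 1)),
                   matrix(c(0, 2), 1))
  set.seed(5)
  m <- matrix(rnorm(16), 4, 4)
  once <- enforce_positivity(m)
  expect_identical(enforce_positivity(once), once)
})

test_that("the TV descent phase respects step size and decreases the objective", {
  params <- recon_params(alpha = 1, n_tv = 1, tau = 1e-8)
  edge <- cbind(matrix(0, 8, 4), matrix(1.5, 8, 4)) +
    matrix(rnorm(64, sd = 0.05), 8, 8)
  truth <- cbind(matrix(0, 8, 4), matrix(1.5, 8, 4))
  expect_identical(tv_descent_phase(edge, truth, params, 0)$data, edge)

  const <- matrix(2, 6, 6)
  expect_equal(tv_descent_phase(const, const, params, 0.1)$data, const)

  before <- tv_norm(edge - truth, tau = 1e-8)
  after_img <- tv_descent_phase(edge, truth, params, 0.01)$data
  expect_lt(tv_norm(after_img - truth, tau = 1e-8), before)
})

small_setup <- function(n_views = 12, image_n = 32, n_det = 48) {
  g <- scan_geometry(sod = 200, sdd = 400, n_views = n_views,
                     n_det = n_det, det_pitch = 2, image_n = image_n,
                     pixel_size = 1)
  truth <- rasterize(shepp_logan_spec("high_contrast"), image_n,
                     pixel_size = 1)
  list(geom = g, truth = truth, sino = forward_project(truth, g))
}

test_that("API-TV with alpha = 0 is bit-identical to ASD-POCS", {
  s <- small_setup()
  p <- recon_params(alpha = 0, n_main = 3)
  junk_prior <- matrix(runif(32 * 32), 32, 32)
  a <- api_tv_reconstruct(s$sino, s$geom, prior = junk_prior, params = p,
                          truth = s$truth)
  b <- asd_pocs_reconstruct(s$sino, s$geom, params = p, truth = s$truth)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$residual_history, b$residual_history)
  expect_identical(a$error_history, b$error_history)
})

test_that("stopping: epsilon = 0 runs n_main loops; a loose epsilon stops early", {
  s <- small_setup()
  p <- recon_params(alpha = 0, n_main = 4, epsilon = 0)
  r <- asd_pocs_reconstruct(s$sino, s$geom, params = p)
  expect_identical(r$iterations_run, 4L)
  expect_length(r$residual_history, 4L)
  expect_null(r$error_history)

  p2 <- recon_params(alpha = 0, n_main = 4, epsilon = 1e12)
  r2 <- asd_pocs_reconstruct(s$sino, s$geom, params = p2)
  expect_identical(r2$iterations_run, 1L)
})

test_that("reconstructions are nonnegative and deterministic", {
  s <- small_setup()
  p <- recon_params(alpha = 0, n_main = 3, seed = 7)
  r1 <- asd_pocs_reconstruct(s$sino, s$geom, params = p, truth = s$truth)
  r2 <- asd_pocs_reconstruct(s$sino, s$geom, params = p, truth = s$truth)
  expect_identical(r1$image$data, r2$image$data)
  expect_identical(r1$error_history, r2$error_history)
  expect_true(all(r1$image$data >= 0))
  r3 <- art_reconstruct(s$sino, s$geom, params = recon_params(n_main = 2))
  expect_true(all(r3$image$data >= 0))
})

test_that("plain ART equals API-TV with the TV phase disabled", {
  s <- small_setup()
  p <- recon_params(alpha = 0.4, n_tv = 0L, n_main = 3)
  prior <- matrix(0.5, 32, 32)
  a <- api_tv_reconstruct(s$sino, s$geom, prior = prior, params = p,
                          truth = s$truth)
  b <- art_reconstruct(s$sino, s$geom,
                       params = recon_params(n_main = 3), truth = s$truth)
  expect_identical(a$image$data, b$image$data)
  expect_identical(b$algorithm, "ART")
})

test_that("TV arms beat plain ART on few-view data; a perfect prior beats no prior", {
  s <- small_setup(n_views = 15, image_n = 48, n_det = 64)
  p <- recon_params(n_main = 10)
  art <- art_reconstruct(s$sino, s$geom, params = p, truth = s$truth)
  asd <- asd_pocs_reconstruct(s$sino, s$geom, params = p, truth = s$truth)
  api <- api_tv_reconstruct(s$sino, s$geom, prior = s$truth, params = p,
                            truth = s$truth)
  expect_lt(asd$error_history[10], art$error_history[10])
  # with prior = truth, API-TV is at least as accurate at every iteration
  expect_true(all(api$error_history <= asd$error_history))
})

test_that("reconstruction inputs are validated", {
  s <- small_setup()
  expect_error(api_tv_reconstruct(s$sino, s$geom, prior = NULL,
                                  params = recon_params(alpha = 0.85)),
               "prior image is required")
  expect_error(api_tv_reconstruct(s$sino, s$geom,
                                  prior = matrix(0, 8, 8),
                                  params = recon_params()),
               "does not match")
  expect_error(recon_params(alpha = 2), "\\[0, 1\\]")
  expect_error(recon_params(lambda_art = 2), "\\(0, 2\\)")
  expect_error(recon_params(n_main = 0), "n_main")
  expect_error(recon_params(epsilon = -1), "epsilon")
})
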