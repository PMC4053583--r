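test_that("forward projection is linear and zero on zero images", {
  g <- tiny_geometry()
  z <- forward_project(matrix(0, 8, 8), g)
  expect_true(all(z$data == 0))

  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  s1 <- forward_project(x, g)$data
  s2 <- forward_project(2.75 * x, g)$data
  expect_equal(s2, 2.75 * s1)
  expect_error(forward_project(matrix(0, 7, 7), g), "does not match")
})

test_that("the central ray through a uniform disk integrates to the chord", {
  n <- 128
  r_mm <- 40
  g <- scan_geometry(sod = 500, sdd = 1000, n_views = 1, n_det = 101,
                     det_pitch = 1, image_n = n, pixel_size = 1)
  cen <- (n + 1) / 2
  disk <- (outer(seq_len(n) - cen, seq_len(n) - cen,
                 function(r, c) sqrt(r^2 + c^2)) <= r_mm) * 1.0
  s <- forward_project(disk, g)$data
  expect_lt(abs(s[1, 51] - 2 * r_mm), g$pixel_size)
  # against a brute-force fine-sampled integral of the same pixelized disk
  e <- ray_endpoints(g, 1, 51)
  oracle <- sampled_line_integral(disk, 1, e$source[1], e$source[2],
                                  e$detector[1, 1], e$detector[1, 2])
  expect_lt(abs(s[1, 51] - oracle), 1e-2)
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- tiny_geometry()
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(64), 8, 8)
    y <- matrix(rnorm(4 * 12), 4, 12)
    lhs <- sum(forward_project(x, g)$data * y)
    rhs <- sum(x * back_project(y, g)$data)
    expect_lt(abs(lhs - rhs), 1e-10 * max(1, abs(lhs)))
  }
  expect_true(all(back_project(matrix(0, 4, 12), g)$data == 0))
})

test_that("projection operators match a brute-force assembled matrix", {
  for (n in c(4, 16)) {
    g <- tiny_geometry(image_n = n, n_views = 3, n_det = 8,
                       det_pitch = n / 3.1, sod = 3 * n, sdd = 6 * n)
    A_ref <- brute_system_matrix(g)
    A_pkg <- as.matrix(system_matrix(g))
    expect_lt(max(abs(A_pkg - A_ref)), 1e-9)

    set.seed(n)
    x <- matrix(rnorm(n * n), n, n)
    fp <- as.vector(t(forward_project(x, g)$data))
    expect_equal(fp, as.vector(A_ref %*% as.vector(x)), tolerance = 1e-12)

    y <- rnorm(nrow(A_ref))
    bp <- back_project(matrix(y, g$n_views, g$n_det, byrow = TRUE), g)$data
    expect_equal(as.vector(bp), as.vector(crossprod(A_ref, y)),
                 tolerance = 1e-12)
  }
})

test_that("a single sinogram bin backprojects onto its ray's pixels only", {
  g <- tiny_geometry(image_n = 8, n_views = 2, n_det = 6)
  y <- matrix(0, 2, 6)
  y[2, 3] <- 1
  img <- back_project(y, g)$data
  A <- brute_system_matrix(g)
  ray <- (2 - 1) * 6 + 3
  expect_identical(which(img != 0), which(A[ray, ] != 0))
})

test_that("row norms are squared intersection-length sums", {
  # horizontal central ray (odd detector count) crosses all n pixels of a
  # row, each with length = pixel_size
  n <- 8
  g <- scan_geometry(sod = 100, sdd = 200, n_views = 1, n_det = 5,
                     det_pitch = 10, image_n = n, pixel_size = 2)
  rn <- row_norms(g)
  expect_equal(rn[1, 3], n * 2^2)
  # outermost rays (offset 20 mm, iso offset 10 mm > half-image 8 mm) miss
  expect_identical(rn[1, 1], 0)
  expect_identical(rn[1, 5], 0)
  # agreement with the brute-force matrix
  g2 <- tiny_geometry(image_n = 4, n_views = 3, n_det = 6, det_pitch = 1.7)
  expect_equal(as.vector(t(row_norms(g2))),
               as.vector(rowSums(brute_system_matrix(g2)^2)),
               tolerance = 1e-12)
})

test_that("analytic phantom projection matches closed-form chords", {
  g <- scan_geometry(sod = 500, sdd = 1000, n_views = 1, n_det = 101,
                     det_pitch = 1, image_n = 128, pixel_size = 1)
  # centered disk, radius 0.3 phantom units = 19.2 mm: central chord 38.4 mm
  disk <- phantom_spec(list(ellipse_spec(0, 0, 0.3, 0.3, 0, 1.5)))
  s <- project_phantom(disk, g)$data
  expect_equal(s[1, 51], 1.5 * 38.4, tolerance = 1e-10)
  # rays beyond the disk are exactly zero
  expect_identical(s[1, 1], 0)
  # off-center rotated ellipse vs fine-sampled rasterized integral
  ell <- phantom_spec(list(ellipse_spec(0.2, -0.1, 0.4, 0.25, 35, 2)))
  sa <- project_phantom(ell, g)$data
  fine <- rasterize(ell, 1024, pixel_size = 128 / 1024)$data
  e <- ray_endpoints(g, 1, 44)
  oracle <- sampled_line_integral(fine, 128 / 1024,
                                  e$source[1], e$source[2],
                                  e$detector[1, 1], e$detector[1, 2])
  expect_equal(sa[1, 44], oracle, tolerance = 5e-2)
})
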