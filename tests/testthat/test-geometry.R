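test_that("the reference geometry matches the simulation protocol", {
  g <- default_sim_geometry()
  expect_equal(g$sod, 500)
  expect_equal(g$sdd, 1000)
  expect_equal(g$n_views, 60L)
  expect_equal(g$n_det, 512L)
  expect_equal(g$det_pitch, 1.0)
  expect_equal(g$image_n, 256L)
  expect_equal(unique(round(diff(g$angles), 12)), round(2 * pi / 60, 12))
})

test_that("geometry invariants are validated", {
  expect_error(scan_geometry(sod = 1000, sdd = 500), "sod < sdd")
  expect_error(scan_geometry(det_pitch = 0), "det_pitch")
  expect_error(scan_geometry(pixel_size = -1), "pixel_size")
  expect_error(scan_geometry(n_views = 3, angles = c(0, 2, 1)),
               "strictly increasing")
  expect_error(scan_geometry(n_views = 2, angles = c(0, 7)), "2\\*pi")
  expect_error(scan_geometry(n_det_rows = 2), "fan-beam")
})

test_that("ray endpoints follow the source/panel conventions", {
  g <- scan_geometry(sod = 100, sdd = 250, n_views = 4, n_det = 5,
                     det_pitch = 3, image_n = 16, pixel_size = 1)
  # central element of view 1 (source on +x axis): ray along the x axis
  e <- ray_endpoints(g, 1, 3)
  expect_equal(e$source, c(100, 0))
  expect_equal(e$detector[1, ], c(100 - 250, 0))

  # outermost element centers sit at +-(n_det-1)/2 * pitch about the panel
  # center, transaxially
  eo <- ray_endpoints(g, 1, c(1, 5))
  expect_equal(eo$detector[, 2], c(-6, 6))

  # opposite views: central rays are anti-parallel through the isocenter
  g2 <- scan_geometry(sod = 100, sdd = 250, n_views = 2,
                      angles = c(0, pi), n_det = 5, det_pitch = 3,
                      image_n = 16, pixel_size = 1)
  a <- ray_endpoints(g2, 1, 3)
  b <- ray_endpoints(g2, 2, 3)
  da <- a$detector[1, ] - a$source
  db <- b$detector[1, ] - b$source
  expect_equal(da / sqrt(sum(da^2)), -db / sqrt(sum(db^2)))

  expect_error(ray_endpoints(g, 9, 1), "view index")
  expect_error(ray_endpoints(g, 1, 6), "detector index")
})

test_that("vectorized endpoints agree with per-ray endpoints", {
  g <- tiny_geometry()
  ep <- apitv:::all_ray_endpoints(g)
  for (v in c(1, 3)) for (d in c(1, 7, 12)) {
    k <- (v - 1) * g$n_det + d
    e <- ray_endpoints(g, v, d)
    expect_equal(c(ep$sx[k], ep$sy[k]), e$source)
    expect_equal(c(ep$ex[k], ep$ey[k]), as.vector(e$detector))
  }
})

test_that("the phantom support circle is inside the fan at default settings", {
  g <- default_sim_geometry()
  # largest Shepp-Logan extent: 0.92 in phantom units
  support <- 0.92 * g$image_n * g$pixel_size / 2
  cov <- fan_coverage(g, radius = support)
  expect_true(cov$covered)
  expect_lt(cov$max_offset, cov$panel_half_width)
})
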