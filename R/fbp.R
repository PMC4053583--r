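#' Fan-beam filtered backprojection (flat detector)
#'
#' Standard full-scan FBP for equispaced (flat-panel) fan-beam data:
#' projections are rebinned to a virtual detector through the isocenter,
#' cosine pre-weighted, ramp-filtered along detector rows (band-limited
#' Ram-Lak kernel, zero-padded to the next power of two, optionally
#' apodized), and backprojected with the fan-beam distance weight
#' `sod^2 / U^2`. A full 2*pi scan is assumed (every ray measured twice,
#' hence the 1/2 in the backprojection weight).
#'
#' @param sino a [sinogram()].
#' @param geom a [scan_geometry()]; defaults to the sinogram's own.
#' @param filter `"ram-lak"` (default, no apodization), `"shepp-logan"`,
#'   or `"hann"`.
#' @return An [image_grid()] of side `geom$image_n`.
#' @export
fbp_reconstruct <- function(sino, geom = sino$geom,
                            filter = c("ram-lak", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  stopifnot(inherits(geom, "scan_geometry"))
  g <- if (inherits(sino, "sinogram")) sino$data else sino
  if (!is.matrix(g) || nrow(g) != geom$n_views || ncol(g) != geom$n_det)
    stop("sinogram shape does not match geometry", call. = FALSE)
  if (geom$n_views < 2L)
    stop("FBP needs at least 2 views", call. = FALSE)

  n_det <- geom$n_det
  # virtual detector at the isocenter: sample spacing scaled by sod/sdd
  d <- geom$det_pitch * geom$sod / geom$sdd
  s <- (seq_len(n_det) - (n_det + 1) / 2) * d
  w <- geom$sod / sqrt(geom$sod^2 + s^2)          # cosine pre-weighting

  # band-limited ramp kernel h[k]: 1/(4 d^2) at 0, -1/(pi k d)^2 for odd k
  npad <- 2^ceiling(log2(2 * n_det))
  h <- numeric(npad)
  h[1] <- 1 / (4 * d^2)
  k <- seq(1, n_det, by = 2)
  h[1 + k] <- -1 / (pi * k * d)^2
  h[npad + 1 - k] <- -1 / (pi * k * d)^2
  H <- Re(fft(h))
  if (filter != "ram-lak") {
    nu <- c(seq(0, npad / 2), seq(npad / 2 - 1, 1)) / npad  # cycles/sample
    win <- switch(filter,
      "shepp-logan" = ifelse(nu == 0, 1, sin(pi * nu) / (pi * nu)),
      "hann" = 0.5 * (1 + cos(2 * pi * nu)))
    H <- H * win
  }

  gw <- sweep(g, 2L, w, `*`)
  pad <- matrix(0, geom$n_views, npad - n_det)
  G <- t(stats::mvfft(t(cbind(gw, pad))))
  q <- Re(t(stats::mvfft(t(G * rep(H, each = geom$n_views)),
                         inverse = TRUE))) / npad
  q <- q[, seq_len(n_det), drop = FALSE] * d      # convolution integral step

  n <- geom$image_n
  ps <- geom$pixel_size
  xc <- rep(((seq_len(n)) - (n + 1) / 2) * ps, each = n)   # column-major x
  yc <- rep(((n + 1) / 2 - seq_len(n)) * ps, times = n)    # row 1 on top
  f <- numeric(n * n)
  s0 <- s[1]
  for (v in seq_len(geom$n_views)) {
    b <- geom$angles[v]
    U <- geom$sod - (xc * cos(b) + yc * sin(b))
    tt <- -xc * sin(b) + yc * cos(b)
    sp <- tt * geom$sod / U
    pos <- (sp - s0) / d + 1
    i0 <- floor(pos)
    frac <- pos - i0
    ok <- i0 >= 1 & i0 <= n_det - 1
    qi <- numeric(length(pos))
    qv <- q[v, ]
    qi[ok] <- qv[i0[ok]] * (1 - frac[ok]) + qv[i0[ok] + 1L] * frac[ok]
    f <- f + (geom$sod^2 / U^2) * qi
  }
  dbeta <- 2 * pi / geom$n_views
  image_grid(matrix(f * dbeta / 2, n, n), pixel_size = ps)
}

#' Prior image from a dense-view scan
#'
#' Builds the prior image used by the API-TV solver: a conventional FBP
#' reconstruction from densely sampled projections. Given a phantom spec,
#' a dense-view sinogram is simulated first (same geometry except for the
#' view count); given a sinogram, it is reconstructed as is.
#'
#' By default the dense-view scan is simulated analytically
#' ([project_phantom()]): a physical prior scan measures the continuous
#' object, and projecting the pixelized phantom instead (the
#' `"discrete"` option) commits an inverse crime whose detector-domain
#' staircase puts substantial ramp-amplified ripple into the FBP prior.
#'
#' @param x a [phantom_spec()] or a [sinogram()].
#' @param geom a [scan_geometry()] describing the target grid and detector
#'   (required for a phantom spec; defaults to the sinogram's own).
#' @param dense_views number of views of the prior scan (default 360, the
#'   conventional full-scan protocol).
#' @param filter FBP filter, see [fbp_reconstruct()].
#' @param simulation for a phantom spec: `"analytic"` (default, exact
#'   chord lengths of the continuous phantom) or `"discrete"` (Siddon
#'   projection of the pixelized phantom).
#' @return An [image_grid()] prior.
#' @export
make_prior <- function(x, geom = NULL, dense_views = 360,
                       filter = "ram-lak",
                       simulation = c("analytic", "discrete")) {
  simulation <- match.arg(simulation)
  if (dense_views < 2) stop("dense_views must be >= 2", call. = FALSE)
  if (inherits(x, "phantom_spec")) {
    if (is.null(geom))
      stop("`geom` is required when building a prior from a phantom spec",
           call. = FALSE)
    dense <- scan_geometry(sod = geom$sod, sdd = geom$sdd,
                           n_views = dense_views, n_det = geom$n_det,
                           det_pitch = geom$det_pitch,
                           image_n = geom$image_n,
                           pixel_size = geom$pixel_size)
    sino <- if (simulation == "analytic") {
      project_phantom(x, dense)
    } else {
      truth <- rasterize(x, dense$image_n, pixel_size = dense$pixel_size)
      forward_project(truth, dense)
    }
    fbp_reconstruct(sino, dense, filter = filter)
  } else if (inherits(x, "sinogram")) {
    fbp_reconstruct(x, if (is.null(geom)) x$geom else geom, filter = filter)
  } else {
    stop("`x` must be a phantom_spec or a sinogram", call. = FALSE)
  }
}
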