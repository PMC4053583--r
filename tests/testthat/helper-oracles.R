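# Independent oracles used across tests. These deliberately avoid the
# package's Siddon traversal and gradient code paths.

# Exact length of the segment S->E inside the axis-aligned rectangle
# [xlo,xhi] x [ylo,yhi] (Liang-Barsky parametric clipping).
clip_ray_length <- function(sx, sy, ex, ey, xlo, xhi, ylo, yhi) {
  rx <- ex - sx
  ry <- ey - sy
  L <- sqrt(rx^2 + ry^2)
  t0 <- 0
  t1 <- 1
  for (side in list(c(-rx, sx - xlo), c(rx, xhi - sx),
                    c(-ry, sy - ylo), c(ry, yhi - sy))) {
    p <- side[1]; q <- side[2]
    if (p == 0) {
      if (q < 0) return(0)
    } else {
      r <- q / p
      if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 >= t1) return(0)
  (t1 - t0) * L
}

# Dense system matrix assembled pixel-by-pixel from clip_ray_length
# (brute force; small geometries only). Same ray and pixel ordering as
# system_matrix(): view-major rays, column-major pixels, row 1 on top.
brute_system_matrix <- function(geom) {
  n <- geom$image_n
  ps <- geom$pixel_size
  half <- n * ps / 2
  n_rays <- geom$n_views * geom$n_det
  A <- matrix(0, n_rays, n * n)
  for (v in seq_len(geom$n_views)) {
    ends <- ray_endpoints(geom, v, seq_len(geom$n_det))
    for (d in seq_len(geom$n_det)) {
      ray <- (v - 1) * geom$n_det + d
      for (c in seq_len(n)) for (r in seq_len(n)) {
        xlo <- -half + (c - 1) * ps
        yhi <- half - (r - 1) * ps
        A[ray, (c - 1) * n + r] <- clip_ray_length(
          ends$source[1], ends$source[2],
          ends$detector[d, 1], ends$detector[d, 2],
          xlo, xlo + ps, yhi - ps, yhi)
      }
    }
  }
  A
}

# Brute-force line integral of an image along S->E by fine sampling.
sampled_line_integral <- function(img, pixel_size, sx, sy, ex, ey,
                                  n_samples = 200000L) {
  n <- nrow(img)
  half <- n * pixel_size / 2
  t <- (seq_len(n_samples) - 0.5) / n_samples
  x <- sx + t * (ex - sx)
  y <- sy + t * (ey - sy)
  L <- sqrt((ex - sx)^2 + (ey - sy)^2)
  c <- floor((x + half) / pixel_size) + 1
  r <- floor((half - y) / pixel_size) + 1
  ok <- c >= 1 & c <= n & r >= 1 & r <= n
  sum(img[cbind(r[ok], c[ok])]) * L / n_samples
}

# Central-difference numerical gradient of a scalar function of a matrix.
numeric_gradient <- function(fun, m, h = 1e-5) {
  g <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(m)) {
    mp <- m; mp[i] <- mp[i] + h
    mm <- m; mm[i] <- mm[i] - h
    g[i] <- (fun(mp) - fun(mm)) / (2 * h)
  }
  g
}

# Small geometry used by many projector tests.
tiny_geometry <- function(image_n = 8, n_views = 4, n_det = 12,
                          det_pitch = 2, sod = 50, sdd = 100,
                          pixel_size = 1) {
  scan_geometry(sod = sod, sdd = sdd, n_views = n_views, n_det = n_det,
                det_pitch = det_pitch, image_n = image_n,
                pixel_size = pixel_size)
}
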