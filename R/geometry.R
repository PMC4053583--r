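#' Circular-trajectory fan-beam scan geometry
#'
#' Describes a circular source trajectory with a flat detector panel.
#' Conventions (fixed; results are invariant to any internally consistent
#' choice): view 1 places the source on the +x axis, rotation is
#' counter-clockwise; the panel is perpendicular to the source--isocenter
#' line at distance `sdd` from the source; detector element 1 sits at the
#' panel edge with negative transaxial coordinate.
#'
#' @param sod source-to-rotation-axis distance, mm.
#' @param sdd source-to-detector distance, mm (must exceed `sod`).
#' @param n_views number of projection views.
#' @param angles view angles in radians, strictly increasing within
#'   `[0, 2*pi)`; default evenly spaced over the full circle.
#' @param n_det detector elements per row.
#' @param det_pitch detector element pitch, mm.
#' @param n_det_rows detector rows (1 = fan beam; only 1 is supported).
#' @param image_n reconstruction grid side, pixels.
#' @param pixel_size reconstruction pixel size, mm.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sod = 500, sdd = 1000, n_views = 60, angles = NULL,
                          n_det = 512, det_pitch = 1.0, n_det_rows = 1L,
                          image_n = 256L, pixel_size = 1.0) {
  if (!(sod > 0 && sdd > sod))
    stop("require 0 < sod < sdd (got sod = ", sod, ", sdd = ", sdd, ")",
         call. = FALSE)
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("n_views must be >= 1", call. = FALSE)
  if (is.null(angles)) {
    angles <- 2 * pi * (seq_len(n_views) - 1L) / n_views
  } else {
    if (length(angles) != n_views)
      stop("length(angles) must equal n_views", call. = FALSE)
    if (any(angles < 0 | angles >= 2 * pi))
      stop("angles must lie in [0, 2*pi)", call. = FALSE)
    if (n_views > 1L && any(diff(angles) <= 0))
      stop("angles must be strictly increasing", call. = FALSE)
  }
  if (det_pitch <= 0) stop("det_pitch must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  n_det <- as.integer(n_det)
  image_n <- as.integer(image_n)
  n_det_rows <- as.integer(n_det_rows)
  if (n_det < 1L) stop("n_det must be >= 1", call. = FALSE)
  if (n_det_rows != 1L)
    stop("only single-row (fan-beam) detectors are supported", call. = FALSE)
  if (image_n < 2L) stop("image_n must be >= 2", call. = FALSE)
  structure(list(sod = sod, sdd = sdd, n_views = n_views, angles = angles,
                 n_det = n_det, det_pitch = det_pitch,
                 n_det_rows = n_det_rows, image_n = image_n,
                 pixel_size = pixel_size),
            class = "scan_geometry")
}

#' @method print scan_geometry
#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<scan_geometry> SOD %.4g mm, SDD %.4g mm, %d views over [%.3f, %.3f] rad\n",
    "  detector: %d x %d elements, pitch %.4g mm\n",
    "  image: %d x %d pixels, %.4g mm/pixel\n"),
    x$sod, x$sdd, x$n_views, x$angles[1], x$angles[x$n_views],
    x$n_det, x$n_det_rows, x$det_pitch, x$image_n, x$image_n, x$pixel_size))
  invisible(x)
}

#' Reference simulation geometry
#'
#' The default few-view study: source radius 500 mm, source-to-detector
#' distance 1000 mm, 60 views evenly spaced over 360 degrees, a 512-element
#' flat panel with 1 mm pitch, and a 256 x 256 reconstruction grid at
#' 1 mm/pixel (256 mm field of view spanning the phantom with margin).
#'
#' @param ... overrides passed on to [scan_geometry()].
#' @return A `scan_geometry`.
#' @export
default_sim_geometry <- function(...) {
  scan_geometry(sod = 500, sdd = 1000, n_views = 60, n_det = 512,
                det_pitch = 1.0, image_n = 256L, pixel_size = 1.0, ...)
}

#' Source and detector-element positions of one ray
#'
#' @param geom a [scan_geometry()].
#' @param view view index, 1-based.
#' @param det detector element index, 1-based (element 1 at the
#'   negative-transaxial panel edge). May be a vector.
#' @return A list with `source` (length-2 xy, mm) and `detector`
#'   (`length(det) x 2` matrix of element centers, mm).
#' @export
ray_endpoints <- function(geom, view, det) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (length(view) != 1L || view < 1L || view > geom$n_views)
    stop("view index out of range [1, ", geom$n_views, "]", call. = FALSE)
  if (any(det < 1L | det > geom$n_det))
    stop("detector index out of range [1, ", geom$n_det, "]", call. = FALSE)
  b <- geom$angles[view]
  src <- geom$sod * c(cos(b), sin(b))
  u <- -c(cos(b), sin(b))           # source -> isocenter direction
  v <- c(-sin(b), cos(b))           # transaxial detector axis
  center <- src + geom$sdd * u
  off <- (det - (geom$n_det + 1) / 2) * geom$det_pitch
  detpt <- cbind(center[1] + off * v[1], center[2] + off * v[2])
  list(source = src, detector = detpt)
}

# Endpoints for every ray, view-major order: ray id (v-1)*n_det + d.
# Returns vectors sx, sy, ex, ey of length n_views * n_det.
all_ray_endpoints <- function(geom) {
  b <- geom$angles
  cb <- cos(b); sb <- sin(b)
  off <- (seq_len(geom$n_det) - (geom$n_det + 1) / 2) * geom$det_pitch
  # panel center per view
  cx <- geom$sod * cb - geom$sdd * cb
  cy <- geom$sod * sb - geom$sdd * sb
  n_det <- geom$n_det
  # outer(off, .) is n_det x n_views; column-major vectorization runs the
  # detector index fastest, matching the view-major ray ordering.
  list(
    sx = rep(geom$sod * cb, each = n_det),
    sy = rep(geom$sod * sb, each = n_det),
    ex = rep(cx, each = n_det) + as.vector(outer(off, -sb)),
    ey = rep(cy, each = n_det) + as.vector(outer(off, cb))
  )
}

#' Transaxial fan coverage of a support circle
#'
#' For a point at distance `r` from the rotation axis, the largest detector
#' coordinate (mm on the panel) its projection reaches over a full rotation
#' is `sdd * r / sqrt(sod^2 - r^2)`. This helper compares that extreme to
#' the panel half-width, so one can assert that an object support circle is
#' fully inside the fan for every view.
#'
#' @param geom a [scan_geometry()].
#' @param radius support radius, mm; default is the phantom support
#'   inscribed in the image field of view (half the image side).
#' @return A list with `max_offset` (mm), `panel_half_width` (mm) and
#'   logical `covered`.
#' @export
fan_coverage <- function(geom, radius = geom$image_n * geom$pixel_size / 2) {
  stopifnot(inherits(geom, "scan_geometry"), radius >= 0, radius < geom$sod)
  max_off <- geom$sdd * radius / sqrt(geom$sod^2 - radius^2)
  half <- geom$n_det / 2 * geom$det_pitch
  list(max_offset = max_off, panel_half_width = half,
       covered = max_off <= half)
}
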