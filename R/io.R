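#' Write / read an image as 32-bit float TIFF
#'
#' Images are stored as single-precision float TIFF. Because the TIFF
#' writer stores samples in `[0, 1]`, values are affinely mapped to that
#' range on write and the mapping (`offset`, `scale`) plus the pixel size
#' are recorded in a YAML sidecar (`<path>.yaml`) read back on load.
#'
#' @param img an [image_grid()].
#' @param path output path (`.tif`).
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns an [image_grid()].
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  lo <- min(img$data)
  hi <- max(img$data)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img$data - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(offset = lo, scale = scale,
                        pixel_size = img$pixel_size),
                   paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- tiff::readTIFF(path)
  image_grid(m * meta$scale + meta$offset, pixel_size = meta$pixel_size)
}

#' Write / read a sinogram as 32-bit float TIFF with a geometry sidecar
#'
#' The projection data go to a float TIFF (same affine mapping as
#' [write_image_tiff()]); the generating [scan_geometry()] and the value
#' mapping go to a YAML sidecar.
#'
#' @param sino a [sinogram()].
#' @param path output path (`.tif`).
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram`
#'   returns a [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  lo <- min(sino$data)
  hi <- max(sino$data)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((sino$data - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(offset = lo, scale = scale,
                        geometry = geometry_to_list(sino$geom)),
                   paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- tiff::readTIFF(path)
  sinogram(m * meta$scale + meta$offset, geometry_from_list(meta$geometry))
}

geometry_to_list <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  unclass(geom)
}

geometry_from_list <- function(x) {
  scan_geometry(sod = x$sod, sdd = x$sdd, n_views = x$n_views,
                angles = x$angles, n_det = x$n_det,
                det_pitch = x$det_pitch, n_det_rows = x$n_det_rows,
                image_n = x$image_n, pixel_size = x$pixel_size)
}

#' Write / read a scan geometry as YAML
#'
#' @param geom a [scan_geometry()].
#' @param path file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns a [scan_geometry()].
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(geometry_to_list(geom), path, precision = 15)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  geometry_from_list(yaml::read_yaml(path))
}
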