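#' Image on a regular square pixel lattice
#'
#' Thin container pairing a square numeric matrix of attenuation values with
#' its physical pixel size. Row 1 is the top of the image (largest y),
#' column 1 the left (smallest x); the grid is centred on the rotation axis.
#'
#' @param data square numeric matrix of finite attenuation values.
#' @param pixel_size physical pixel side length in mm (> 0).
#' @return An object of class `image_grid` with fields `data` and
#'   `pixel_size`.
#' @export
image_grid <- function(data, pixel_size = 1) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) != ncol(data))
    stop("`data` must be square (got ", nrow(data), " x ", ncol(data), ")",
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` must be finite", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "image_grid")
}

#' @method print image_grid
#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d, pixel %.4g mm, range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$data)

# Accept either an image_grid or a bare square matrix; return the matrix.
as_image_matrix <- function(img, arg = "img") {
  if (inherits(img, "image_grid")) return(img$data)
  if (is.matrix(img) && is.numeric(img)) {
    if (nrow(img) != ncol(img))
      stop("`", arg, "` must be square", call. = FALSE)
    return(img)
  }
  stop("`", arg, "` must be an image_grid or a square numeric matrix",
       call. = FALSE)
}

#' Projection data container
#'
#' A sinogram holds fan-beam line-integral data as an `n_views x n_det`
#' matrix (one row per view, columns ordered with detector index 1 at the
#' negative-transaxial panel edge) together with the geometry that generated
#' it. Values are in mm times attenuation.
#'
#' @param data numeric matrix, `n_views x n_det`, finite.
#' @param geom a [scan_geometry()].
#' @return An object of class `sinogram` with fields `data` and `geom`.
#' @export
sinogram <- function(data, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!is.matrix(data) || !is.numeric(data))
    stop("sinogram `data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) != geom$n_views || ncol(data) != geom$n_det)
    stop(sprintf(
      "sinogram shape %d x %d inconsistent with geometry (%d views, %d detectors)",
      nrow(data), ncol(data), geom$n_views, geom$n_det), call. = FALSE)
  if (!all(is.finite(data)))
    stop("sinogram `data` must be finite", call. = FALSE)
  structure(list(data = data, geom = geom), class = "sinogram")
}

#' @method print sinogram
#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d views x %d detectors, range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.sinogram <- function(x) dim(x$data)
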