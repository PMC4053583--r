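#' Image error (sum of squared differences)
#'
#' The quantitative image-quality figure used throughout the simulation
#' studies: `E = sum((truth - recon)^2)` over all pixels — a plain sum of
#' squared differences, with no square root and no normalization. For a
#' size-independent figure see [image_rmse()].
#'
#' @param recon reconstructed image ([image_grid()] or matrix).
#' @param truth ground-truth image, same shape.
#' @return A nonnegative scalar.
#' @export
image_error <- function(recon, truth) {
  a <- as_plain_matrix(recon, "recon")
  b <- as_plain_matrix(truth, "truth")
  if (!identical(dim(a), dim(b)))
    stop("`recon` and `truth` shapes differ", call. = FALSE)
  sum((b - a)^2)
}

#' Root-mean-square error per pixel
#'
#' Normalized companion of [image_error()]:
#' `sqrt(image_error / n_pixels)`. Kept under a distinct name so the two
#' are never conflated.
#'
#' @inheritParams image_error
#' @return A nonnegative scalar.
#' @export
image_rmse <- function(recon, truth) {
  a <- as_plain_matrix(recon, "recon")
  sqrt(image_error(recon, truth) / length(a))
}

# metrics accept any numeric matrix (not necessarily square)
as_plain_matrix <- function(x, arg) {
  if (inherits(x, "image_grid")) return(x$data)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("`", arg, "` must be an image_grid or a numeric matrix",
       call. = FALSE)
}

#' Horizontal line profile
#'
#' The pixel values of one image row, left to right. Rows are indexed
#' 1-based from the top of the image, so "the 128th row" of a 256-pixel
#' image is `row = 128`.
#'
#' @param img an [image_grid()] or matrix.
#' @param row row index, 1-based.
#' @return A numeric vector of length `ncol(img)`.
#' @export
extract_profile <- function(img, row) {
  m <- as_plain_matrix(img, "img")
  row <- as.integer(row)
  if (is.na(row) || row < 1L || row > nrow(m))
    stop("row index out of range [1, ", nrow(m), "]", call. = FALSE)
  m[row, ]
}

#' Convergence curve of a reconstruction
#'
#' Tabulates the per-main-iteration image error recorded during a
#' reconstruction run with ground truth supplied.
#'
#' @param result a `recon_result`.
#' @return A data frame with columns `iteration` and `error`.
#' @export
convergence_curve <- function(result) {
  stopifnot(inherits(result, "recon_result"))
  if (is.null(result$error_history))
    stop("no error_history: the reconstruction was run without a ",
         "ground-truth image, so per-iteration errors were not recorded",
         call. = FALSE)
  data.frame(iteration = seq_len(result$iterations_run),
             error = result$error_history)
}
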