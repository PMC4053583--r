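#' Isotropic total variation of an image
#'
#' Sum over pixels of the Euclidean norm of the backward differences,
#' \deqn{\|f\|_{TV} = \sum_{s,t} \sqrt{(f_{s,t}-f_{s-1,t})^2 +
#'   (f_{s,t}-f_{s,t-1})^2 (+ \tau)},}
#' with replicate (Neumann) boundaries: out-of-range differences are zero,
#' so a constant image has TV exactly 0. With `tau > 0` this is the
#' smoothed surrogate whose exact gradient [tv_gradient()] computes; the
#' default `tau = 0` is the TV functional itself.
#'
#' @param img an [image_grid()] or square numeric matrix (side >= 2).
#' @param tau smoothing constant added under each square root (>= 0).
#' @return A non-negative scalar.
#' @export
tv_norm <- function(img, tau = 0) {
  m <- as_image_matrix(img)
  if (nrow(m) < 2L) stop("image must have at least 2 pixels per dimension",
                         call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  d <- tv_diffs(m)
  sum(sqrt(d$dr^2 + d$dc^2 + tau))
}

# backward differences with replicate boundary (first row/col -> 0)
tv_diffs <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  dr <- m - m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dc <- m - m[, c(1L, seq_len(p - 1L)), drop = FALSE]
  list(dr = dr, dc = dc)
}

#' Smoothed gradient of the TV functional
#'
#' Exact gradient of the tau-smoothed isotropic TV (see [tv_norm()]): each
#' pixel accumulates the derivative of its own backward-difference term
#' plus its appearance as a neighbor in the terms of the pixel below and
#' the pixel to the right, every denominator stabilized by `+ tau` under
#' the square root. `tau` keeps the denominators nonzero on flat regions;
#' a constant image has an exactly zero gradient.
#'
#' @param img an [image_grid()] or square numeric matrix.
#' @param tau smoothing constant (> 0).
#' @return A numeric matrix, same shape as the input image.
#' @export
tv_gradient <- function(img, tau = 1e-8) {
  m <- as_image_matrix(img)
  if (!(tau > 0)) stop("tau must be > 0", call. = FALSE)
  n <- nrow(m)
  p <- ncol(m)
  d <- tv_diffs(m)
  D <- sqrt(d$dr^2 + d$dc^2 + tau)
  A <- d$dr / D
  B <- d$dc / D
  A + B - rbind(A[-1L, , drop = FALSE], 0) - cbind(B[, -1L, drop = FALSE], 0)
}

#' Prior-blended TV descent direction
#'
#' The descent direction of the API-TV objective
#' \eqn{\alpha \|f - f_p\|_{TV} + (1-\alpha) \|f\|_{TV}}: by the chain
#' rule the prior term's gradient with respect to `f` is the TV gradient
#' evaluated at the difference image `f - prior`, so the result is
#' `alpha * tv_gradient(img - prior) + (1 - alpha) * tv_gradient(img)`.
#' At `alpha = 0` this is exactly (bitwise) the plain TV gradient and the
#' prior is ignored; at `alpha = 1` only the difference image matters.
#'
#' @param img current image ([image_grid()] or matrix).
#' @param prior prior image, same shape.
#' @param alpha blend weight in `[0, 1]`.
#' @param tau smoothing constant, see [tv_gradient()].
#' @return A numeric matrix, same shape as `img`.
#' @export
blended_tv_gradient <- function(img, prior, alpha, tau = 1e-8) {
  m <- as_image_matrix(img)
  p <- as_image_matrix(prior, arg = "prior")
  if (!identical(dim(m), dim(p)))
    stop("`img` and `prior` shapes differ", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (alpha == 0) return(tv_gradient(m, tau))
  if (alpha == 1) return(tv_gradient(m - p, tau))
  alpha * tv_gradient(m - p, tau) + (1 - alpha) * tv_gradient(m, tau)
}
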