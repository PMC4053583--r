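#' Parameters of the iterative reconstructors
#'
#' Collects every tunable of the API-TV / ASD-POCS / ART solvers.
#'
#' @param alpha prior blend weight in `[0, 1]`; 0.85 is the reference
#'   setting, 0 reduces API-TV to ASD-POCS.
#' @param lambda_art ART (Kaczmarz) relaxation, in `(0, 2)`.
#' @param n_art inner ART sweeps per main loop (I).
#' @param n_tv inner TV gradient-descent steps per main loop (K); 0
#'   disables the TV phase (plain ART).
#' @param n_main main-loop iterations.
#' @param tv_step_rule `"art-scaled"` (default): the TV step magnitude is
#'   `tv_step * decay^(m-1) * ||df_ART||_2`, where `||df_ART||` is the norm
#'   of the change made by the preceding ART + positivity phase — the
#'   adaptive balancing convention of ASD-POCS; or `"fixed"`: the step is
#'   `tv_step` itself.
#' @param tv_step step magnitude (`"fixed"`) or scale factor
#'   (`"art-scaled"`, default 0.2).
#' @param tv_step_decay per-main-loop geometric decay of the art-scaled
#'   step (default 0.95).
#' @param epsilon data-residual stopping tolerance: iteration stops early
#'   once `||M f - g|| <= epsilon` (default 0, so `n_main` binds).
#' @param tau TV smoothing constant, see [tv_gradient()].
#' @param seed optional integer; when given, the ray order of each ART
#'   sweep is a seeded random shuffle instead of the default sequential
#'   view-then-detector order.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(alpha = 0.85, lambda_art = 1.0, n_art = 1L,
                         n_tv = 10L, n_main = 50L,
                         tv_step_rule = c("art-scaled", "fixed"),
                         tv_step = 0.2, tv_step_decay = 0.95,
                         epsilon = 0, tau = 1e-8, seed = NULL) {
  tv_step_rule <- match.arg(tv_step_rule)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  if (!(lambda_art > 0 && lambda_art < 2))
    stop("lambda_art must be in (0, 2)", call. = FALSE)
  n_art <- as.integer(n_art); n_tv <- as.integer(n_tv)
  n_main <- as.integer(n_main)
  if (n_art < 1L) stop("n_art must be >= 1", call. = FALSE)
  if (n_tv < 0L) stop("n_tv must be >= 0", call. = FALSE)
  if (n_main < 1L) stop("n_main must be >= 1", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (tv_step < 0) stop("tv_step must be >= 0", call. = FALSE)
  if (!(tau > 0)) stop("tau must be > 0", call. = FALSE)
  structure(list(alpha = alpha, lambda_art = lambda_art, n_art = n_art,
                 n_tv = n_tv, n_main = n_main, tv_step_rule = tv_step_rule,
                 tv_step = tv_step, tv_step_decay = tv_step_decay,
                 epsilon = epsilon, tau = tau, seed = seed),
            class = "recon_params")
}

#' One full ART (Kaczmarz) sweep
#'
#' For each ray `j` in `order`, updates
#' `f <- f + lambda * (g_j - <M_j, f>) / ||M_j||^2 * M_j`.
#' Rays with zero row norm (missing the grid) are skipped.
#'
#' @param img starting image ([image_grid()] or matrix, side
#'   `geom$image_n`).
#' @param sino measured [sinogram()].
#' @param geom a [scan_geometry()].
#' @param lambda_art relaxation factor.
#' @param order ray visiting order, a permutation of
#'   `1:(n_views * n_det)` in view-major ray ids; default sequential.
#' @return An [image_grid()] after one full pass.
#' @export
art_sweep <- function(img, sino, geom, lambda_art = 1.0, order = NULL) {
  stopifnot(inherits(geom, "scan_geometry"))
  m <- as_image_matrix(img)
  if (nrow(m) != geom$image_n)
    stop("image side does not match geometry", call. = FALSE)
  g <- if (inherits(sino, "sinogram")) sino$data else sino
  if (!is.matrix(g) || nrow(g) != geom$n_views || ncol(g) != geom$n_det)
    stop("sinogram shape does not match geometry", call. = FALSE)
  ep <- all_ray_endpoints(geom)
  n_rays <- length(ep$sx)
  if (is.null(order)) order <- seq_len(n_rays)
  out <- cpp_art_sweep(m, as.vector(t(g)), as.integer(order) - 1L,
                       lambda_art, geom$pixel_size,
                       ep$sx, ep$sy, ep$ex, ep$ey)
  image_grid(out, pixel_size = geom$pixel_size)
}

#' Positivity projection
#'
#' Projects the image onto the nonnegativity constraint set: pixelwise
#' `max(value, 0)`. Idempotent.
#'
#' @param img an [image_grid()] or matrix.
#' @return Same type as the input.
#' @export
enforce_positivity <- function(img) {
  if (inherits(img, "image_grid")) {
    img$data <- pmax(img$data, 0)
    img
  } else if (is.matrix(img) && is.numeric(img)) {
    pmax(img, 0)
  } else {
    stop("`img` must be an image_grid or a numeric matrix", call. = FALSE)
  }
}

#' TV gradient-descent phase
#'
#' `n_tv` steps of `f <- f - step_size * d / ||d||_2` with
#' `d = blended_tv_gradient(f, prior, alpha, tau)`, the direction
#' renormalized at every step. A zero-gradient image is returned
#' unchanged.
#'
#' @param img current image.
#' @param prior prior image (ignored when `params$alpha == 0`).
#' @param params a [recon_params()].
#' @param step_size nonnegative step magnitude.
#' @return An [image_grid()].
#' @export
tv_descent_phase <- function(img, prior, params, step_size) {
  if (step_size < 0) stop("step_size must be >= 0", call. = FALSE)
  m <- as_image_matrix(img)
  ps <- if (inherits(img, "image_grid")) img$pixel_size else 1
  p <- if (is.null(prior)) matrix(0, nrow(m), ncol(m)) else
    as_image_matrix(prior, arg = "prior")
  if (step_size > 0 && params$n_tv > 0L) {
    for (k in seq_len(params$n_tv)) {
      d <- blended_tv_gradient(m, p, params$alpha, params$tau)
      nd <- sqrt(sum(d * d))
      if (nd == 0) break
      m <- m - (step_size / nd) * d
    }
  }
  image_grid(m, pixel_size = ps)
}

new_recon_result <- function(image, residual_history, error_history,
                             iterations_run, algorithm, params) {
  structure(list(image = image, residual_history = residual_history,
                 error_history = error_history,
                 iterations_run = iterations_run, algorithm = algorithm,
                 params = params),
            class = "recon_result")
}

#' @method print recon_result
#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, %d iterations, final residual %.6g",
              x$algorithm, x$iterations_run,
              x$residual_history[x$iterations_run]))
  if (!is.null(x$error_history))
    cat(sprintf(", final image error %.6g", x$error_history[x$iterations_run]))
  cat("\n")
  invisible(x)
}

#' Adaptive prior image TV (API-TV) reconstruction
#'
#' Solves the constrained problem "minimize the (prior-blended) TV of `f`
#' subject to `||M f - g|| <= epsilon` and `f >= 0`" by interlaced
#' projections: starting from `f = 0`, each main iteration runs `n_art`
#' ART sweeps (data consistency), the positivity projection, then `n_tv`
#' normalized gradient-descent steps on the blended TV objective
#' `alpha * ||f - f_p||_TV + (1 - alpha) * ||f||_TV`. With `alpha = 0`
#' the prior drops out and the algorithm is exactly ASD-POCS. Iteration
#' stops after `n_main` loops or as soon as the data residual falls to
#' `epsilon`.
#'
#' @param sino measured [sinogram()].
#' @param geom a [scan_geometry()]; defaults to the sinogram's own.
#' @param prior prior image on the reconstruction grid (required when
#'   `alpha > 0`).
#' @param params a [recon_params()].
#' @param truth optional ground-truth [image_grid()]; when supplied the
#'   per-iteration sum-of-squared-differences image error is recorded.
#' @return A `recon_result` with fields `image`, `residual_history`,
#'   `error_history` (NULL without `truth`), `iterations_run`,
#'   `algorithm`, `params`.
#' @export
api_tv_reconstruct <- function(sino, geom = sino$geom, prior = NULL,
                               params = recon_params(), truth = NULL) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(params, "recon_params"))
  g <- if (inherits(sino, "sinogram")) sino$data else sino
  if (!is.matrix(g) || nrow(g) != geom$n_views || ncol(g) != geom$n_det)
    stop("sinogram shape does not match geometry", call. = FALSE)
  pm <- NULL
  if (params$alpha > 0) {
    if (is.null(prior))
      stop("a prior image is required when alpha > 0", call. = FALSE)
    pm <- as_image_matrix(prior, arg = "prior")
    if (nrow(pm) != geom$image_n)
      stop("prior grid does not match geometry image_n", call. = FALSE)
  }
  tm <- NULL
  if (!is.null(truth)) {
    tm <- as_image_matrix(truth, arg = "truth")
    if (nrow(tm) != geom$image_n)
      stop("truth grid does not match geometry image_n", call. = FALSE)
  }

  ep <- all_ray_endpoints(geom)
  gvec <- as.vector(t(g))
  n_rays <- length(gvec)
  shuffle <- !is.null(params$seed)
  if (shuffle) {
    rng <- local_rng_seed(params$seed)
    on.exit(rng(), add = TRUE)
  }

  f <- matrix(0, geom$image_n, geom$image_n)
  residual_history <- numeric(params$n_main)
  error_history <- if (is.null(tm)) NULL else numeric(params$n_main)
  iterations <- 0L
  for (it in seq_len(params$n_main)) {
    f_prev <- f
    order0 <- if (shuffle) sample.int(n_rays) - 1L else seq_len(n_rays) - 1L
    for (i in seq_len(params$n_art)) {
      f <- cpp_art_sweep(f, gvec, order0, params$lambda_art,
                         geom$pixel_size, ep$sx, ep$sy, ep$ex, ep$ey)
    }
    f <- pmax(f, 0)
    if (params$n_tv > 0L) {
      step <- if (params$tv_step_rule == "fixed") params$tv_step
      else params$tv_step * params$tv_step_decay^(it - 1L) *
        sqrt(sum((f - f_prev)^2))
      if (step > 0) {
        for (k in seq_len(params$n_tv)) {
          d <- if (is.null(pm)) tv_gradient(f, params$tau)
          else blended_tv_gradient(f, pm, params$alpha, params$tau)
          nd <- sqrt(sum(d * d))
          if (nd == 0) break
          f <- f - (step / nd) * d
        }
      }
    }
    res <- cpp_forward(f, geom$pixel_size, ep$sx, ep$sy, ep$ex, ep$ey) - gvec
    residual_history[it] <- sqrt(sum(res * res))
    if (!is.null(tm)) error_history[it] <- sum((tm - f)^2)
    iterations <- it
    if (residual_history[it] <= params$epsilon) break
  }
  # the TV phase ends each loop and can leave tiny negatives; the returned
  # image satisfies the f >= 0 constraint. Histories record the raw iterate.
  f <- pmax(f, 0)
  new_recon_result(image_grid(f, pixel_size = geom$pixel_size),
                   residual_history[seq_len(iterations)],
                   if (is.null(error_history)) NULL else
                     error_history[seq_len(iterations)],
                   iterations,
                   algorithm = if (params$alpha > 0) "API-TV" else "ASD-POCS",
                   params = params)
}

#' ASD-POCS reconstruction (no prior)
#'
#' The TV-constrained baseline: identical to [api_tv_reconstruct()] with
#' the prior blend weight forced to 0, so only the image's own TV is
#' descended and no prior image is needed.
#'
#' @inheritParams api_tv_reconstruct
#' @return A `recon_result`.
#' @export
asd_pocs_reconstruct <- function(sino, geom = sino$geom,
                                 params = recon_params(), truth = NULL) {
  params$alpha <- 0
  api_tv_reconstruct(sino, geom, prior = NULL, params = params,
                     truth = truth)
}

#' Plain ART reconstruction
#'
#' ART sweeps and the positivity projection only — no TV phase
#' (`n_tv = 0`); the conventional algebraic baseline.
#'
#' @inheritParams api_tv_reconstruct
#' @return A `recon_result`.
#' @export
art_reconstruct <- function(sino, geom = sino$geom,
                            params = recon_params(), truth = NULL) {
  params$alpha <- 0
  params$n_tv <- 0L
  res <- api_tv_reconstruct(sino, geom, prior = NULL, params = params,
                            truth = truth)
  res$algorithm <- "ART"
  res
}

# Seed the RNG reproducibly, returning a restorer for the previous state.
local_rng_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
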