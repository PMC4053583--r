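#' Additive white noise on a sinogram
#'
#' Adds zero-mean Gaussian noise with per-element standard deviation
#' `level` times a reference amplitude of the sinogram — by default the
#' root-mean-square of its nonzero entries, so "10% white noise" means
#' `sd = 0.10 * RMS`. The realization is deterministic given the seed and
#' depends only on the sinogram shape (pure additive model), not its
#' content.
#'
#' @param sino a [sinogram()].
#' @param level noise fraction (>= 0); 0 returns the input unchanged.
#' @param seed integer seed for reproducibility.
#' @param reference amplitude reference: `"rms"` (default, RMS of nonzero
#'   entries), `"max"`, or `"mean"` (of nonzero entries).
#' @return A [sinogram()] with the same geometry.
#' @export
add_white_noise <- function(sino, level, seed,
                            reference = c("rms", "max", "mean")) {
  stopifnot(inherits(sino, "sinogram"))
  reference <- match.arg(reference)
  if (!is.numeric(level) || length(level) != 1L || level < 0)
    stop("noise `level` must be a single nonnegative number", call. = FALSE)
  if (level == 0) return(sino)
  g <- sino$data
  nz <- g[g != 0]
  ref <- switch(reference,
                rms = if (length(nz)) sqrt(mean(nz^2)) else 0,
                max = max(abs(g)),
                mean = if (length(nz)) mean(abs(nz)) else 0)
  restore <- local_rng_seed(seed)
  on.exit(restore(), add = TRUE)
  eta <- matrix(rnorm(length(g), mean = 0, sd = level * ref),
                nrow = nrow(g), ncol = ncol(g))
  sinogram(g + eta, sino$geom)
}
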