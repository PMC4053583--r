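#' Forward projection (discrete line integrals)
#'
#' Computes the fan-beam sinogram of an image: each entry is the
#' intersection-length-weighted sum of pixel values along the ray from the
#' source to a detector element center, with exact per-pixel path lengths
#' from a Siddon-style traversal. Rays that miss the grid give 0. Together
#' with [back_project()] this forms a matched operator pair (exact
#' adjoints), which makes the algebraic data-consistency projection in the
#' iterative solvers well defined.
#'
#' @param img an [image_grid()] (or square matrix) with side `geom$image_n`.
#' @param geom a [scan_geometry()].
#' @return A [sinogram()].
#' @export
forward_project <- function(img, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  m <- as_image_matrix(img)
  if (nrow(m) != geom$image_n)
    stop("image side ", nrow(m), " does not match geometry image_n = ",
         geom$image_n, call. = FALSE)
  ep <- all_ray_endpoints(geom)
  v <- cpp_forward(m, geom$pixel_size, ep$sx, ep$sy, ep$ex, ep$ey)
  sinogram(matrix(v, nrow = geom$n_views, ncol = geom$n_det, byrow = TRUE),
           geom)
}

#' Backprojection (exact adjoint of the forward projector)
#'
#' Applies the transpose of the forward-projection operator: sinogram
#' values are smeared back along their rays with the same intersection-
#' length weights.
#'
#' @param sino a [sinogram()] (or `n_views x n_det` matrix).
#' @param geom a [scan_geometry()].
#' @return An [image_grid()].
#' @export
back_project <- function(sino, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  m <- if (inherits(sino, "sinogram")) sino$data else sino
  if (!is.matrix(m) || nrow(m) != geom$n_views || ncol(m) != geom$n_det)
    stop("sinogram shape does not match geometry", call. = FALSE)
  ep <- all_ray_endpoints(geom)
  img <- cpp_back(as.vector(t(m)), geom$image_n, geom$pixel_size,
                  ep$sx, ep$sy, ep$ex, ep$ey)
  image_grid(img, pixel_size = geom$pixel_size)
}

#' Per-ray squared weight norms
#'
#' For each ray, the sum of squared pixel intersection lengths — the
#' squared Euclidean norm of the corresponding system-matrix row, used to
#' normalize Kaczmarz (ART) updates. Rays missing the grid have norm 0.
#'
#' @param geom a [scan_geometry()].
#' @return An `n_views x n_det` matrix of squared norms (mm^2).
#' @export
row_norms <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  ep <- all_ray_endpoints(geom)
  v <- cpp_row_norms(geom$image_n, geom$pixel_size,
                     ep$sx, ep$sy, ep$ex, ep$ey)
  matrix(v, nrow = geom$n_views, ncol = geom$n_det, byrow = TRUE)
}

#' Analytic forward projection of an ellipse phantom
#'
#' Exact line integrals of the continuous phantom: for each ray, the sum
#' over ellipses of intensity times the chord length (mm) of the ray
#' through the ellipse, computed in closed form. Unlike
#' [forward_project()], which projects a pixelized image, this samples the
#' continuous object a physical scan would measure, so reconstructing from
#' it does not commit the inverse crime. Used by default to simulate the
#' dense-view prior scan.
#'
#' @param spec a [phantom_spec()] (coordinates in `[-1, 1]` phantom units;
#'   the phantom spans the image field of view
#'   `image_n * pixel_size` mm).
#' @param geom a [scan_geometry()].
#' @return A [sinogram()].
#' @export
project_phantom <- function(spec, geom) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geom, "scan_geometry"))
  h <- geom$image_n * geom$pixel_size / 2     # phantom unit -> mm
  ep <- all_ray_endpoints(geom)
  dx <- ep$ex - ep$sx
  dy <- ep$ey - ep$sy
  L <- sqrt(dx^2 + dy^2)
  ux <- dx / L
  uy <- dy / L
  g <- numeric(length(ux))
  for (e in spec$ellipses) {
    th <- e$rotation * pi / 180
    ct <- cos(th); st <- sin(th)
    a <- e$semi_axis_a * h; b <- e$semi_axis_b * h
    rx <- ep$sx - e$center_x * h
    ry <- ep$sy - e$center_y * h
    # ray in the ellipse's unit-circle frame; t stays physical arc length
    Ax <- ( rx * ct + ry * st) / a
    Ay <- (-rx * st + ry * ct) / b
    Bx <- ( ux * ct + uy * st) / a
    By <- (-ux * st + uy * ct) / b
    qa <- Bx^2 + By^2
    qb <- 2 * (Ax * Bx + Ay * By)
    qc <- Ax^2 + Ay^2 - 1
    disc <- qb^2 - 4 * qa * qc
    pos <- disc > 0
    g[pos] <- g[pos] + e$intensity * sqrt(disc[pos]) / qa[pos]
  }
  sinogram(matrix(g, nrow = geom$n_views, ncol = geom$n_det, byrow = TRUE),
           geom)
}

#' Explicit sparse system matrix
#'
#' Assembles the projection operator as a sparse matrix with one row per
#' ray (view-major ordering: ray `(v-1)*n_det + d`) and one column per
#' pixel (column-major image vectorization). Intended for small grids and
#' tests; the iterative solvers apply the operator matrix-free.
#'
#' @param geom a [scan_geometry()].
#' @return A `dgCMatrix` of dimension `(n_views*n_det) x image_n^2`.
#' @export
system_matrix <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  ep <- all_ray_endpoints(geom)
  n_rays <- length(ep$sx)
  ii <- jj <- xx <- vector("list", n_rays)
  for (r in seq_len(n_rays)) {
    tr <- cpp_trace(ep$sx[r], ep$sy[r], ep$ex[r], ep$ey[r],
                    geom$image_n, geom$pixel_size)
    if (length(tr$index)) {
      ii[[r]] <- rep.int(r, length(tr$index))
      jj[[r]] <- tr$index
      xx[[r]] <- tr$length
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n_rays, geom$image_n^2))
}
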