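# Toy-scale non-uniform Fourier operators and bin-axis finite differences.

#' Radial k-space trajectory for the toy reconstruction
#'
#' Spoke samples run diametrically through k-space centre; angles follow a
#' golden-angle or uniform scheme. Frequencies are in cycles/pixel in
#' [-0.5, 0.5).
#'
#' @param n_spokes Number of spokes.
#' @param n_samples Samples per spoke.
#' @param scheme `"golden"` (default) or `"uniform"` angle ordering.
#' @return Tibble with `spoke`, `sample`, `angle`, `kx`, `ky`.
#' @export
radial_trajectory <- function(n_spokes, n_samples, scheme = c("golden", "uniform")) {
  scheme <- match.arg(scheme)
  ga <- pi * (3 - sqrt(5))
  angles <- switch(scheme,
                   golden = (seq_len(n_spokes) - 1) * ga %% pi,
                   uniform = (seq_len(n_spokes) - 1) * pi / n_spokes)
  rad <- seq(-0.5, 0.5 - 1 / n_samples, length.out = n_samples)
  tibble(spoke = rep(seq_len(n_spokes), each = n_samples),
         sample = rep(seq_len(n_samples), n_spokes),
         angle = rep(angles, each = n_samples),
         kx = rad * cos(rep(angles, each = n_samples)),
         ky = rad * sin(rep(angles, each = n_samples)))
}

#' Fully sampled Cartesian trajectory
#'
#' @param nx Image size (square).
#' @return Tibble with `kx`, `ky` covering the full DFT grid, for which the
#'   forward operator of [nudft_matrix()] is unitary.
#' @export
cartesian_trajectory <- function(nx) {
  f <- (seq_len(nx) - 1 - floor(nx / 2)) / nx
  g <- expand.grid(kx = f, ky = f)
  tibble(kx = g$kx, ky = g$ky)
}

#' Explicit non-uniform discrete Fourier matrix
#'
#' Returns the (n_samples x n_pixels) complex matrix of
#' exp(-2 pi i (kx px + ky py)) / sqrt(n_pixels) over centred pixel
#' coordinates; at toy scale the forward model is this explicit summation.
#' On the full Cartesian grid of [cartesian_trajectory()] the matrix is
#' unitary.
#'
#' @param kx,ky Sample frequencies in cycles/pixel.
#' @param nx,ny Image dimensions.
#' @return Complex matrix; pixels are column-major (x fastest).
#' @export
nudft_matrix <- function(kx, ky, nx, ny = nx) {
  px <- seq_len(nx) - 1 - floor(nx / 2)
  py <- seq_len(ny) - 1 - floor(ny / 2)
  grid_x <- rep(px, times = ny)
  grid_y <- rep(py, each = nx)
  phase <- outer(kx, grid_x) + outer(ky, grid_y)
  exp(-2i * pi * phase) / sqrt(nx * ny)
}

#' First-difference operator along a bin axis
#'
#' Differences along the cardiac axis are cyclic (the heartbeat is
#' periodic); along the respiratory axis they are non-cyclic. `x` is a
#' 3-D array `[pixel, cardiac_bin, respiratory_bin]`. A single bin along
#' the chosen axis yields the zero operator (a zero-filled result for the
#' cyclic axis, a zero-extent result for the non-cyclic one).
#'
#' @param x 3-D numeric/complex array `[pixel, cardiac, respiratory]`.
#' @param axis `"cardiac"` or `"respiratory"`.
#' @return Array of differences (same shape for the cyclic axis; one fewer
#'   slice along the respiratory axis).
#' @export
finite_difference <- function(x, axis = c("cardiac", "respiratory")) {
  axis <- match.arg(axis)
  d <- dim(x)
  if (axis == "cardiac") {
    if (d[2] == 1L) return(array(0 * x[1], dim = d))
    x[, c(seq_len(d[2])[-1], 1L), , drop = FALSE] - x
  } else {
    if (d[3] == 1L) return(array(0 * x[1], dim = c(d[1], d[2], 0L)))
    x[, , -1L, drop = FALSE] - x[, , -d[3], drop = FALSE]
  }
}

#' Adjoint of [finite_difference()]
#'
#' Satisfies `<Dx, u> = <x, D^T u>` (real inner product on stacked
#' real/imaginary parts) for all `x`, `u`.
#'
#' @param u Difference array as produced by [finite_difference()].
#' @param axis `"cardiac"` or `"respiratory"`.
#' @return Array with the shape of the original image stack.
#' @export
finite_difference_adjoint <- function(u, axis = c("cardiac", "respiratory")) {
  axis <- match.arg(axis)
  d <- dim(u)
  if (axis == "cardiac") {
    if (d[2] == 1L) return(array(0 * u[1], dim = d))
    u[, c(d[2], seq_len(d[2] - 1L)), , drop = FALSE] - u
  } else {
    n3 <- d[3] + 1L
    out <- array(0 * if (length(u) > 0) u[1] else 0+0i, dim = c(d[1], d[2], n3))
    if (d[3] == 0L) return(out)
    out[, , 1L] <- -u[, , 1L]
    if (n3 > 2L) {
      for (r in 2L:(n3 - 1L)) out[, , r] <- u[, , r - 1L] - u[, , r]
    }
    out[, , n3] <- u[, , d[3]]
    out
  }
}
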