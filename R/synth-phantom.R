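# Synthetic images with known ground truth: a sigmoid-edge phantom for the
# sharpness metric and a beating-disk cine phantom for the toy recon.

#' Sigmoid-edge phantom image
#'
#' Builds an image whose intensity along every line perpendicular to a
#' reference curve follows the sigmoid edge model
#' \eqn{f(x) = a_2 + (a_1 - a_2) / (1 + 10^{(a_0 - x) s})}, with x the
#' signed distance from the curve (positive on the side the curve normal
#' points to). The defaults give a straight vertical edge through the image
#' centre.
#'
#' @param a0_px Edge-centre offset from the curve in pixels.
#' @param a1,a2 Maximum and minimum intensity (`a1 > a2`).
#' @param s Sigmoid steepness (larger = sharper edge).
#' @param image_size Square image side in pixels (>= 32).
#' @param curve_control_points Two-column matrix/data frame of (x, y)
#'   control points in pixel coordinates; `NULL` for a vertical line at
#'   the image centre.
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param seed Integer seed for the noise.
#' @return List of class `edge_phantom`: `image` (matrix, first index x),
#'   `curve` (the fitted interpolating curve), and the generating `params`.
#' @export
make_edge_phantom <- function(a0_px = 0, a1 = 100, a2 = 10, s = 0.5,
                              image_size = 64, curve_control_points = NULL,
                              noise_sd = 0, seed = 1L) {
  if (a1 <= a2) abort("`a1` must exceed `a2`.",
                      class = "sgmotion_invalid_parameter")
  if (image_size < 32) abort("`image_size` must be >= 32.",
                             class = "sgmotion_invalid_parameter")
  check_non_negative(noise_sd, "noise_sd")
  if (is.null(curve_control_points)) {
    mid <- (image_size + 1) / 2
    curve_control_points <- cbind(x = c(mid, mid), y = c(1, image_size))
  }
  curve <- fit_bezier(curve_control_points)

  # signed distance of every pixel to the curve (dense polyline; the sign
  # follows the curve normal, rotated +90 deg from the tangent)
  dense <- curve_points(curve, n = 40L * (nrow(curve$points) - 1L) + 1L)
  gx <- rep(seq_len(image_size), times = image_size)
  gy <- rep(seq_len(image_size), each = image_size)
  dists <- signed_distance_to_polyline(gx, gy, dense)
  img <- a2 + (a1 - a2) / (1 + 10^((a0_px - dists) * s))
  if (noise_sd > 0) {
    img <- img + with_seed(seed, rnorm(length(img), 0, noise_sd))
  }
  structure(list(image = matrix(img, image_size, image_size),
                 curve = curve,
                 params = list(a0_px = a0_px, a1 = a1, a2 = a2, s = s,
                               image_size = image_size, noise_sd = noise_sd,
                               seed = seed)),
            class = "edge_phantom")
}

# signed distance from points to a dense polyline (positive along +normal)
signed_distance_to_polyline <- function(px, py, poly) {
  n <- nrow(poly)
  best_d2 <- rep(Inf, length(px))
  best_sign <- rep(1, length(px))
  for (i in seq_len(n - 1L)) {
    ax <- poly$x[i]; ay <- poly$y[i]
    bx <- poly$x[i + 1L]; by <- poly$y[i + 1L]
    vx <- bx - ax; vy <- by - ay
    vv <- vx^2 + vy^2
    t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / vv, 0), 1)
    cx <- ax + t * vx; cy <- ay + t * vy
    d2 <- (px - cx)^2 + (py - cy)^2
    cross <- vx * (py - ay) - vy * (px - ax)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_sign[upd] <- ifelse(cross[upd] >= 0, 1, -1)
  }
  best_sign * sqrt(best_d2)
}

#' Beating-disk cine phantom frame
#'
#' A smooth-edged disk whose radius expands and contracts with cardiac
#' phase (maximal at mid-cycle), optionally displaced by respiration, over
#' a static background feature. Used to make reconstruction quality
#' sensitive to cardiac binning fidelity.
#'
#' @param nx Image size (square).
#' @param cardiac_phase Phase in cycles (0 = trigger; radius minimal).
#' @param resp_disp_px Respiratory displacement in pixels along y.
#' @return Real `nx x nx` matrix (first index x).
#' @export
disk_phantom <- function(nx, cardiac_phase, resp_disp_px = 0) {
  ctr <- (nx + 1) / 2
  gx <- rep(seq_len(nx), times = nx)
  gy <- rep(seq_len(nx), each = nx)
  r0 <- 0.18 * nx
  dr <- 0.10 * nx
  rad <- r0 + dr * (1 - cos(2 * pi * cardiac_phase)) / 2
  d <- sqrt((gx - ctr)^2 + (gy - ctr - resp_disp_px)^2)
  img <- 1 / (1 + exp((d - rad) / 0.7))
  # static background feature
  d2 <- sqrt((gx - 0.22 * nx)^2 + (gy - 0.75 * nx)^2)
  img <- img + 0.5 / (1 + exp((d2 - 0.08 * nx) / 0.7))
  matrix(img, nx, nx)
}

#' Simulate radial k-space of the beating-disk phantom
#'
#' For each readout, evaluates the dynamic phantom at that readout's
#' cardiac phase (and respiratory displacement) and samples one radial
#' spoke of its k-space with the explicit non-uniform DFT.
#'
#' @param phases Cardiac phase (cycles, fractional part used) per readout.
#' @param angles Spoke angle (radians) per readout.
#' @param nx Image size.
#' @param n_samples Samples per spoke.
#' @param resp_disp_px Respiratory displacement per readout (default 0).
#' @param coil_sens Optional `nx x nx x n_coils` sensitivity array
#'   (default one uniform coil).
#' @param noise_sd Complex Gaussian noise SD added to the samples.
#' @param seed Integer seed for the noise.
#' @return List: `y` (complex array samples x coils x readouts), `kx`,
#'   `ky` (samples x readouts), `angles`, `phases`, `nx`.
#' @export
simulate_cine_radial <- function(phases, angles, nx, n_samples,
                                 resp_disp_px = 0, coil_sens = NULL,
                                 noise_sd = 0, seed = 1L) {
  n_read <- length(phases)
  stopifnot(length(angles) == n_read)
  resp_disp_px <- rep_len(resp_disp_px, n_read)
  if (is.null(coil_sens)) coil_sens <- array(1, dim = c(nx, nx, 1L))
  n_coils <- dim(coil_sens)[3]
  sens <- matrix(coil_sens, nx * nx, n_coils)
  rad <- seq(-0.5, 0.5 - 1 / n_samples, length.out = n_samples)

  y <- array(0+0i, dim = c(n_samples, n_coils, n_read))
  kx <- matrix(0, n_samples, n_read)
  ky <- matrix(0, n_samples, n_read)
  # cache the spoke operator per unique angle
  ua <- unique(angles)
  Acache <- lapply(ua, function(a) {
    nudft_matrix(rad * cos(a), rad * sin(a), nx)
  })
  names(Acache) <- sprintf("%.12f", ua)
  with_seed(seed, {
    for (i in seq_len(n_read)) {
      a <- angles[i]
      A <- Acache[[sprintf("%.12f", a)]]
      frame <- as.vector(disk_phantom(nx, phases[i], resp_disp_px[i]))
      y[, , i] <- A %*% (sens * frame)
      kx[, i] <- rad * cos(a)
      ky[, i] <- rad * sin(a)
    }
    if (noise_sd > 0) {
      y <- y + array(complex(real = rnorm(length(y), 0, noise_sd),
                             imaginary = rnorm(length(y), 0, noise_sd)),
                     dim = dim(y))
    }
  })
  list(y = y, kx = kx, ky = ky, angles = angles, phases = phases, nx = nx)
}

#' Group simulated radial readouts into reconstruction bins
#'
#' @param sim Output of [simulate_cine_radial()].
#' @param card_bin 0-based cardiac bin per readout (NA = rejected).
#' @param resp_bin 0-based respiratory bin per readout (default all 0).
#' @return The `y_bins` nested list consumed by [recon_problem()].
#' @export
group_kspace_by_bins <- function(sim, card_bin, resp_bin = NULL) {
  n_read <- dim(sim$y)[3]
  if (is.null(resp_bin)) resp_bin <- rep(0L, n_read)
  n_card <- max(card_bin, na.rm = TRUE) + 1L
  n_resp <- max(resp_bin, na.rm = TRUE) + 1L
  n_coils <- dim(sim$y)[2]
  out <- vector("list", n_resp)
  for (r in seq_len(n_resp)) {
    out[[r]] <- vector("list", n_card)
    for (c in seq_len(n_card)) {
      sel <- which(!is.na(card_bin) & card_bin == (c - 1L) &
                     resp_bin == (r - 1L))
      if (length(sel) == 0L) {
        out[[r]][[c]] <- list(kx = numeric(0), ky = numeric(0),
                              y = matrix(0+0i, 0, n_coils))
        next
      }
      out[[r]][[c]] <- list(
        kx = as.vector(sim$kx[, sel]),
        ky = as.vector(sim$ky[, sel]),
        y = matrix(aperm(sim$y[, , sel, drop = FALSE], c(1, 3, 2)),
                   ncol = n_coils))
    }
  }
  out
}
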