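# Interpolating curve and perpendicular-profile sampling for the edge
# sharpness measurement.

#' Interpolating cubic curve through measurement points
#'
#' Fits a piecewise cubic curve passing through every input point
#' (Catmull-Rom tangents expressed in cubic Bezier form, one-sided
#' tangents at the ends), with an arc-length parameterization for even
#' spacing of the perpendicular sampling lines.
#'
#' @param points Two-column matrix or data frame of (x, y) positions,
#'   >= 2 rows, no duplicated consecutive points.
#' @return Object of class `bezier_curve`.
#' @export
fit_bezier <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  colnames(pts) <- c("x", "y")
  n <- nrow(pts)
  if (n < 2L) abort("need at least 2 points.",
                    class = "sgmotion_invalid_parameter")
  if (any(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2) == 0)) {
    abort("duplicate consecutive points.", class = "sgmotion_invalid_parameter")
  }
  # Tangents by circular-arc estimation: direction is the bisector of the
  # adjacent chord directions, magnitude the chord mean corrected for the
  # local turning angle (arc = chord * (phi/2)/sin(phi/2)). Exact for
  # points on a circle or a straight line; plain Catmull-Rom chords sag by
  # about 1% of radius on coarsely sampled circles.
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  arc_k <- function(phi) if (abs(phi) < 1e-9) 1 else (phi / 2) / sin(phi / 2)
  tang <- matrix(0, n, 2)
  if (n == 2L) {
    tang[1, ] <- pts[2, ] - pts[1, ]
    tang[2, ] <- pts[2, ] - pts[1, ]
  } else {
    chords <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
    clen <- sqrt(rowSums(chords^2))
    cdir <- chords / clen
    # signed turning angle at interior point i: from chord i-1 to chord i
    phi <- vapply(seq_len(n - 2L), function(i) {
      atan2(cdir[i, 1] * cdir[i + 1, 2] - cdir[i, 2] * cdir[i + 1, 1],
            sum(cdir[i, ] * cdir[i + 1, ]))
    }, numeric(1))
    for (i in 2:(n - 1)) {
      dir <- cdir[i - 1, ] + cdir[i, ]
      nd <- sqrt(sum(dir^2))
      dir <- if (nd < 1e-12) cdir[i, ] else dir / nd   # cusp fallback
      tang[i, ] <- dir * mean(clen[c(i - 1, i)]) * arc_k(phi[i - 1])
    }
    tang[1, ] <- rot(cdir[1, ], -phi[1] / 2) * clen[1] * arc_k(phi[1])
    tang[n, ] <- rot(cdir[n - 1, ], phi[n - 2] / 2) * clen[n - 1] *
      arc_k(phi[n - 2])
  }
  # per-segment Bezier control points
  segs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    segs[[i]] <- rbind(pts[i, ],
                       pts[i, ] + tang[i, ] / 3,
                       pts[i + 1, ] - tang[i + 1, ] / 3,
                       pts[i + 1, ])
  }
  curve <- structure(list(points = as.data.frame(pts), segments = segs),
                     class = "bezier_curve")
  # arc-length table on a fine grid
  fine <- curve_points(curve, n = 200L * (n - 1L) + 1L)
  seg_len <- sqrt(diff(fine$x)^2 + diff(fine$y)^2)
  curve$arc_table <- data.frame(t = fine$t, s = c(0, cumsum(seg_len)))
  curve$length <- sum(seg_len)
  curve
}

# evaluate the curve at global parameter t in [0, 1] (uniform in segments)
bezier_eval <- function(curve, t) {
  n_seg <- length(curve$segments)
  u <- pmin(pmax(t, 0), 1) * n_seg
  i <- pmin(floor(u), n_seg - 1)
  lt <- u - i
  out <- matrix(0, length(t), 2)
  for (s in unique(i)) {
    sel <- which(i == s)
    B <- curve$segments[[s + 1]]
    lts <- lt[sel]
    b0 <- (1 - lts)^3; b1 <- 3 * lts * (1 - lts)^2
    b2 <- 3 * lts^2 * (1 - lts); b3 <- lts^3
    out[sel, ] <- cbind(b0, b1, b2, b3) %*% B
  }
  data.frame(x = out[, 1], y = out[, 2])
}

# derivative wrt the global parameter
bezier_deriv <- function(curve, t) {
  n_seg <- length(curve$segments)
  u <- pmin(pmax(t, 0), 1) * n_seg
  i <- pmin(floor(u), n_seg - 1)
  lt <- u - i
  out <- matrix(0, length(t), 2)
  for (s in unique(i)) {
    sel <- which(i == s)
    B <- curve$segments[[s + 1]]
    lts <- lt[sel]
    d0 <- -3 * (1 - lts)^2
    d1 <- 3 * (1 - lts)^2 - 6 * lts * (1 - lts)
    d2 <- 6 * lts * (1 - lts) - 3 * lts^2
    d3 <- 3 * lts^2
    out[sel, ] <- cbind(d0, d1, d2, d3) %*% B * n_seg
  }
  data.frame(x = out[, 1], y = out[, 2])
}

#' Points along a fitted curve
#'
#' @param curve A `bezier_curve`.
#' @param n Number of points, uniform in the curve parameter.
#' @return Data frame with `t`, `x`, `y`.
#' @export
curve_points <- function(curve, n = 200L) {
  t <- seq(0, 1, length.out = n)
  cbind(t = t, bezier_eval(curve, t))
}

# global parameter t at normalized arc length s in [0, 1]
bezier_t_at_arclength <- function(curve, s) {
  approx(curve$arc_table$s / curve$length, curve$arc_table$t,
         xout = pmin(pmax(s, 0), 1), rule = 2)$y
}

#' Sample intensity profiles perpendicular to a curve
#'
#' Places `n_lines` lines at equal arc-length spacing along the curve
#' (endpoints included, so adjacent spacing is length/(n_lines - 1)), each
#' perpendicular to the local tangent, and samples the image by bilinear
#' interpolation at sub-pixel positions. The profile coordinate is signed
#' and centred on the curve (positive along the +90 deg normal). Lines
#' that exit the image are dropped with a warning.
#'
#' @param curve A `bezier_curve` in pixel coordinates.
#' @param n_lines Number of perpendicular lines.
#' @param half_length_px Half-length of each line in pixels.
#' @param image Intensity matrix (first index x, second y).
#' @param step_px Sampling step along each line (default 0.5 px).
#' @return Tibble with `line`, `arc_s`, `offset_px`, `x`, `y`, `intensity`.
#' @export
sample_perpendiculars <- function(curve, n_lines, half_length_px, image,
                                  step_px = 0.5) {
  stopifnot(inherits(curve, "bezier_curve"))
  nxi <- nrow(image); nyi <- ncol(image)
  s_pos <- seq(0, 1, length.out = n_lines)
  t_pos <- bezier_t_at_arclength(curve, s_pos)
  ctr <- bezier_eval(curve, t_pos)
  dv <- bezier_deriv(curve, t_pos)
  tl <- sqrt(dv$x^2 + dv$y^2)
  normal <- cbind(-dv$y / tl, dv$x / tl)
  offs <- seq(-half_length_px, half_length_px, by = step_px)

  res <- vector("list", n_lines)
  dropped <- 0L
  for (j in seq_len(n_lines)) {
    px <- ctr$x[j] + offs * normal[j, 1]
    py <- ctr$y[j] + offs * normal[j, 2]
    if (any(px < 1 | px > nxi | py < 1 | py > nyi)) {
      dropped <- dropped + 1L
      next
    }
    res[[j]] <- tibble(line = j, arc_s = s_pos[j], offset_px = offs,
                       x = px, y = py,
                       intensity = bilinear_interp(image, px, py))
  }
  if (dropped > 0L) {
    warn(sprintf("%d of %d perpendicular lines exit the image and were dropped.",
                 dropped, n_lines))
  }
  dplyr::bind_rows(res)
}

# bilinear interpolation on a matrix, coordinates in pixel units (1-based)
bilinear_interp <- function(img, x, y) {
  x0 <- pmin(pmax(floor(x), 1L), nrow(img) - 1L)
  y0 <- pmin(pmax(floor(y), 1L), ncol(img) - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    img[cbind(x0 + 1L, y0 + 1L)] * fx * fy
}
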