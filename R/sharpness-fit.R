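#' Fit the sigmoid edge model to an intensity profile
#'
#' Least-squares fit of
#' \deqn{f(x) = a_2 + \frac{a_1 - a_2}{1 + 10^{(a_0 - x) s}}}
#' where `a2` and `a1` are the minimum and maximum intensity, `a0` the
#' position of the half-way intensity and `s` the steepness. The exponent
#' is read multiplicatively, `(a0 - x) * s`, so a larger `|s|` means a
#' steeper edge; the reciprocal parameterization differs only by `s -> 1/s`
#' and leaves the rise distance invariant under refitting.
#' Initialization: `a1 = max`, `a2 = min`, `a0` at the mid-intensity
#' coordinate, `s` from the central-difference slope there.
#'
#' @param profile Data frame with columns `offset_px` (profile coordinate)
#'   and `intensity`, or two numeric vectors via `x`/`y` names; >= 8
#'   non-constant samples.
#' @param max_iter Iteration cap of the Levenberg-Marquardt fit.
#' @return Object of class `sigmoid_fit`: `a0`, `a1`, `a2`, `s`,
#'   `residual` (RMS), `converged`, and the data. Non-convergence flags
#'   `converged = FALSE` rather than erroring so callers can exclude the
#'   line.
#' @export
fit_sigmoid <- function(profile, max_iter = 200) {
  if (is.data.frame(profile)) {
    x <- profile$offset_px %||% profile$x
    y <- profile$intensity %||% profile$y
  } else {
    abort("`profile` must be a data frame.",
          class = "sgmotion_invalid_parameter")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 8L) abort("need >= 8 profile samples.",
                            class = "sgmotion_invalid_parameter")
  if (diff(range(y)) == 0) abort("constant profile.",
                                 class = "sgmotion_invalid_parameter")

  a1_0 <- max(y); a2_0 <- min(y)
  mid <- (a1_0 + a2_0) / 2
  i_mid <- which.min(abs(y - mid))
  a0_0 <- x[i_mid]
  i_lo <- max(i_mid - 1L, 1L); i_hi <- min(i_mid + 1L, length(x))
  slope <- (y[i_hi] - y[i_lo]) / (x[i_hi] - x[i_lo])
  s_0 <- 4 * slope / ((a1_0 - a2_0) * log(10))
  if (!is.finite(s_0) || s_0 == 0) s_0 <- 0.5
  # exactly-zero starts defeat the relative-step numeric gradient
  rng <- diff(range(y))
  if (a0_0 == 0) a0_0 <- 0.25 * median(diff(sort(x)))
  if (a1_0 == 0) a1_0 <- 1e-3 * rng
  if (a2_0 == 0) a2_0 <- -1e-3 * rng

  # Levenberg-Marquardt on the residuals with an analytic Jacobian (the
  # formula-interface machinery rejects some perfectly fine starts as
  # "singular gradient"); overflow-safe in the saturated tails
  model <- function(p) {
    e <- pmin(pmax((p[1] - x) * p[4], -300), 300)
    p[3] + (p[2] - p[3]) / (1 + 10^e)
  }
  jacobian <- function(p) {
    e <- pmin(pmax((p[1] - x) * p[4], -300), 300)
    u <- 10^e
    inv_den <- 1 / (1 + u)
    ratio <- u * inv_den^2                       # u/(1+u)^2, -> 0 in tails
    cbind(a0 = -(p[2] - p[3]) * log(10) * p[4] * ratio,
          a1 = inv_den,
          a2 = 1 - inv_den,
          s = -(p[2] - p[3]) * log(10) * (p[1] - x) * ratio)
  }
  dx <- median(diff(sort(x)))
  starts <- list(
    c(a0_0, a1_0, a2_0, s_0),
    c(a0_0 + 0.5 * dx, a1_0 + 0.02 * rng, a2_0 - 0.02 * rng, 1.25 * s_0),
    c(a0_0 - 0.5 * dx, a1_0 + 0.05 * rng, a2_0 - 0.05 * rng,
      0.5 * sign(s_0)))
  fit <- NULL
  fit_ok <- FALSE
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         fn = function(p) model(p) - y,
                         jac = jacobian,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(cand)) next
    if (is.null(fit)) fit <- cand
    rms <- sqrt(mean(cand$fvec^2))
    if (cand$info %in% 1:3 || rms < 1e-8 * rng) {
      fit <- cand
      fit_ok <- TRUE
      break
    }
  }

  if (is.null(fit)) {
    out <- list(a0 = a0_0, a1 = a1_0, a2 = a2_0, s = s_0,
                residual = NA_real_, converged = FALSE,
                data = tibble(offset_px = x, intensity = y))
  } else {
    cf <- fit$par
    out <- list(a0 = cf[1], a1 = cf[2], a2 = cf[3], s = cf[4],
                residual = sqrt(mean(fit$fvec^2)),
                converged = fit_ok && cf[2] > cf[3] &&
                  is.finite(cf[4]) && cf[4] != 0,
                data = tibble(offset_px = x, intensity = y))
  }
  structure(out, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>\n")
  cat(sprintf("  a0 = %.3f px, a1 = %.2f, a2 = %.2f, s = %.4f\n",
              x$a0, x$a1, x$a2, x$s))
  cat(sprintf("  RMS residual %.4g, converged: %s\n", x$residual, x$converged))
  invisible(x)
}

# the sigmoid and its analytic inverse
sigmoid_edge <- function(x, a0, a1, a2, s) {
  a2 + (a1 - a2) / (1 + 10^((a0 - x) * s))
}
sigmoid_edge_inv <- function(y, a0, a1, a2, s) {
  a0 - log10((a1 - a2) / (y - a2) - 1) / s
}

#' 10%-90% rise distance of a fitted edge
#'
#' Converts the fitted sigmoid into a physical edge width:
#' \deqn{RD = \frac{FOV}{BR} \left| f^{-1}(a_2 + 0.9\,(a_1-a_2))
#'   - f^{-1}(a_2 + 0.1\,(a_1-a_2)) \right|}
#' where FOV/BR is the pixel size in mm. With the multiplicative exponent
#' this equals \eqn{(FOV/BR)\, 2 \log_{10} 9 / |s|} in closed form; both
#' the numerical inverse and the closed form are computed and must agree.
#' A shorter rise distance means a sharper edge. Near-zero steepness is
#' censored at the profile window width rather than reported as infinite.
#'
#' @param fit A converged `sigmoid_fit`.
#' @param fov_mm Field of view in mm.
#' @param br Base resolution (matrix size in pixels across the FOV).
#' @param window_px Censoring width in px for degenerate fits; defaults to
#'   the fitted profile's coordinate range.
#' @return One-row tibble: `rd_mm`, `rd_closed_form_mm`, `censored`.
#' @export
rise_distance <- function(fit, fov_mm, br, window_px = NULL) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!isTRUE(fit$converged)) {
    abort("rise distance requires a converged fit.",
          class = "sgmotion_invalid_parameter")
  }
  check_positive(fov_mm, "fov_mm"); check_positive(br, "br")
  px_mm <- fov_mm / br
  if (is.null(window_px)) {
    window_px <- diff(range(fit$data$offset_px))
    if (!is.finite(window_px) || window_px == 0) window_px <- br
  }
  if (abs(fit$s) < 2 * log10(9) / window_px) {
    return(tibble(rd_mm = px_mm * window_px,
                  rd_closed_form_mm = px_mm * 2 * log10(9) / abs(fit$s),
                  censored = TRUE))
  }
  dl <- fit$a1 - fit$a2
  hi <- sigmoid_edge_inv(fit$a2 + 0.9 * dl, fit$a0, fit$a1, fit$a2, fit$s)
  lo <- sigmoid_edge_inv(fit$a2 + 0.1 * dl, fit$a0, fit$a1, fit$a2, fit$s)
  tibble(rd_mm = px_mm * abs(hi - lo),
         rd_closed_form_mm = px_mm * 2 * log10(9) / abs(fit$s),
         censored = FALSE)
}

#' Edge sharpness of an image along a measured interface
#'
#' End-to-end sharpness measurement: interpolating curve through the
#' interface points, evenly spaced perpendicular intensity profiles,
#' per-line sigmoid fits, and the median 10%-90% rise distance over
#' converged lines (median, not mean, so diverged or dropped lines do not
#' dominate).
#'
#' @param image Intensity matrix (first index x).
#' @param control_points Interface points (two-column, pixel coordinates).
#' @param fov_mm,br Field of view (mm) and base resolution (px).
#' @param n_lines Number of perpendicular lines (default 20).
#' @param half_length_px Half-length of each profile (default 8 px).
#' @param step_px Sampling step along each profile (default 0.5 px;
#'   bilinear interpolation at off-grid positions slightly smooths very
#'   sharp edges, so pixel-aligned geometries may prefer 1 px).
#' @return List of class `sharpness_result`: `lines` (per-line tibble with
#'   fit parameters and `rd_mm`), `median_rd_mm`, `n_converged`.
#' @export
measure_sharpness <- function(image, control_points, fov_mm, br,
                              n_lines = 20, half_length_px = 8,
                              step_px = 0.5) {
  curve <- fit_bezier(control_points)
  prof <- sample_perpendiculars(curve, n_lines, half_length_px, image,
                                step_px = step_px)
  res <- prof |>
    dplyr::group_by(.data$line) |>
    dplyr::group_map(function(df, key) {
      f <- tryCatch(fit_sigmoid(df), error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$converged)) {
        return(tibble(line = key$line, a0 = NA_real_, a1 = NA_real_,
                      a2 = NA_real_, s = NA_real_, rd_mm = NA_real_,
                      censored = NA, converged = FALSE))
      }
      rd <- rise_distance(f, fov_mm, br)
      tibble(line = key$line, a0 = f$a0, a1 = f$a1, a2 = f$a2, s = f$s,
             rd_mm = rd$rd_mm, censored = rd$censored, converged = TRUE)
    }) |>
    dplyr::bind_rows()
  structure(list(lines = res,
                 median_rd_mm = median(res$rd_mm[res$converged], na.rm = TRUE),
                 n_converged = sum(res$converged)),
            class = "sharpness_result")
}

#' @export
print.sharpness_result <- function(x, ...) {
  cat("<sharpness_result>\n")
  cat(sprintf("  %d converged lines, median rise distance %.3f mm\n",
              x$n_converged, x$median_rd_mm))
  invisible(x)
}
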