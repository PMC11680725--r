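# Interpolating curve, perpendicular sampling, sigmoid fit and rise distance.

test_that("two points give an exact straight segment through both", {
  cv <- fit_bezier(cbind(c(1, 9), c(2, 6)))
  p <- curve_points(cv, 50)
  # linearity: y is an affine function of x along the curve
  fit <- lm(p$y ~ p$x)
  expect_lt(max(abs(residuals(fit))), 1e-12)
  expect_equal(unname(c(p$x[1], p$y[1])), c(1, 2), tolerance = 1e-12)
  expect_equal(unname(c(p$x[50], p$y[50])), c(9, 6), tolerance = 1e-12)
})

test_that("the curve interpolates its control points and rejects duplicates", {
  set.seed(1)
  pts <- cbind(cumsum(runif(6, 1, 3)), rnorm(6))
  cv <- fit_bezier(pts)
  at <- bezier_points_at <- curve_points(cv, 5 * 200 + 1)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((at$x - pts[i, 1])^2 + (at$y - pts[i, 2])^2)
    expect_lt(min(d), 1e-10)
  }
  expect_error(fit_bezier(rbind(c(0, 0), c(0, 0), c(1, 1))),
               class = "sgmotion_invalid_parameter")
  expect_error(fit_bezier(rbind(c(0, 0))), class = "sgmotion_invalid_parameter")
})

test_that("eight points on a circle are interpolated within 1% of radius", {
  th <- seq(0, 2 * pi, length.out = 9)[1:8]
  R <- 20
  cv <- fit_bezier(cbind(10 + R * cos(th), 10 + R * sin(th)))
  p <- curve_points(cv, 2000)
  rad <- sqrt((p$x - 10)^2 + (p$y - 10)^2)
  expect_lt(max(abs(rad - R)), 0.01 * R)
})

test_that("perpendicular lines are normal to the tangent and evenly spaced", {
  cv <- fit_bezier(cbind(c(5, 60), c(30, 30)))   # horizontal straight curve
  img <- matrix(1, 64, 64)
  prof <- sample_perpendiculars(cv, 10, 5, img)
  # all lines vertical: x constant within each line
  spread <- tapply(prof$x, prof$line, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-12)
  xs <- tapply(prof$x, prof$line, mean)
  expect_equal(max(abs(diff(xs) - 55 / 9)), 0, tolerance = 1e-6)

  # lines leaving the image are dropped with a warning
  cv2 <- fit_bezier(cbind(c(5, 60), c(3, 30)))   # early lines exit the top
  expect_warning(p2 <- sample_perpendiculars(cv2, 10, 6, img), "dropped")
  expect_lt(length(unique(p2$line)), 10)
  expect_gt(length(unique(p2$line)), 0)
})

test_that("profiles across the edge phantom match the generating sigmoid", {
  ph <- make_edge_phantom(a0_px = 0, a1 = 100, a2 = 10, s = 0.5,
                          image_size = 64)
  ctr <- (64 + 1) / 2
  cv <- fit_bezier(cbind(c(ctr, ctr), c(12, 52)))
  prof <- sample_perpendiculars(cv, 8, 10, ph$image)
  pred <- 10 + 90 / (1 + 10^(-prof$offset_px * 0.5))
  rms <- sqrt(mean((prof$intensity - pred)^2))
  expect_lt(rms / 90, 0.01)
})

test_that("sigmoid self-fit recovers exact parameters and symmetries", {
  x <- seq(-10, 10, by = 0.25)
  y <- 10 + (100 - 10) / (1 + 10^((0 - x) * 0.5))
  f <- fit_sigmoid(data.frame(offset_px = x, intensity = y))
  expect_true(f$converged)
  expect_equal(c(f$a0, f$a1, f$a2, f$s), c(0, 100, 10, 0.5), tolerance = 1e-6)

  # reversing the profile negates s but leaves the rise distance unchanged
  fr <- fit_sigmoid(data.frame(offset_px = -x, intensity = y))
  expect_equal(fr$s, -f$s, tolerance = 1e-6)
  expect_equal(rise_distance(fr, 220, 220)$rd_mm,
               rise_distance(f, 220, 220)$rd_mm, tolerance = 1e-6)

  expect_error(fit_sigmoid(data.frame(offset_px = 1:5, intensity = 1:5)),
               class = "sgmotion_invalid_parameter")
})

test_that("noisy profiles still recover the steepness within 5%", {
  x <- seq(-10, 10, by = 0.25)
  clean <- 10 + 90 / (1 + 10^((0 - x) * 0.5))
  s_hat <- vapply(1:100, function(seed) {
    set.seed(seed)
    f <- fit_sigmoid(data.frame(offset_px = x,
                                intensity = clean + rnorm(length(x), 0, 1.8)))
    f$s
  }, numeric(1))
  expect_lt(abs(mean(s_hat) - 0.5) / 0.5, 0.05)
})

test_that("rise distance matches its closed form and scaling laws", {
  x <- seq(-10, 10, by = 0.25)
  mk <- function(s) fit_sigmoid(data.frame(
    offset_px = x, intensity = 10 + 90 / (1 + 10^((0 - x) * s))))
  f1 <- mk(1)
  rd1 <- rise_distance(f1, fov_mm = 220, br = 220)
  expect_equal(rd1$rd_mm, rd1$rd_closed_form_mm, tolerance = 1e-9)
  expect_equal(rd1$rd_mm, 2 * log10(9), tolerance = 1e-6)

  f2 <- mk(2)
  expect_equal(rise_distance(f2, 220, 220)$rd_mm, rd1$rd_mm / 2,
               tolerance = 1e-6)

  # affine intensity changes leave the rise distance untouched
  f_aff <- fit_sigmoid(data.frame(offset_px = x,
                                  intensity = 500 + 7 * (10 + 90 / (1 + 10^(-x)))))
  expect_equal(rise_distance(f_aff, 220, 220)$rd_mm, rd1$rd_mm,
               tolerance = 1e-6)

  # near-flat fits are censored at the window, not infinite
  f_flat <- f1; f_flat$s <- 1e-9
  rd_c <- rise_distance(f_flat, 220, 220)
  expect_true(rd_c$censored)
  expect_true(is.finite(rd_c$rd_mm))
})

test_that("the sharpness pipeline closes the loop on the phantom", {
  ph <- make_edge_phantom(a0_px = 0, a1 = 100, a2 = 10, s = 0.5,
                          image_size = 64)
  # pixel-aligned geometry: integer curve x, integer line spacing and step
  pts <- cbind(c(32, 32), c(10, 54))
  ms <- measure_sharpness(ph$image, pts, fov_mm = 220, br = 220,
                          n_lines = 12, half_length_px = 10, step_px = 1)
  s_med <- median(ms$lines$s, na.rm = TRUE)
  expect_lt(abs(s_med - 0.5) / 0.5, 0.01)
})

test_that("blurring monotonically increases the median rise distance", {
  ph <- make_edge_phantom(a0_px = 0, a1 = 100, a2 = 10, s = 1.2,
                          image_size = 64)
  pts <- cbind(c(32, 32), c(12, 52))
  rd <- vapply(c(0, 0.8, 1.6, 2.4), function(sg) {
    img <- gaussian_blur(ph$image, sg)
    measure_sharpness(img, pts, 220, 220, n_lines = 10,
                      half_length_px = 10)$median_rd_mm
  }, numeric(1))
  expect_true(all(diff(rd) > 0))
})
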