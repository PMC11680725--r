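# Synthetic physiology, SI stack, ECG and phantom generators.

test_that("constant-rate physiology yields exact metronome triggers", {
  gt <- simulate_physio(hr_mean_bpm = 60, hr_sd_bpm = 0, rsa_gain_bpm = 0,
                        duration_s = 300, seed = 1)
  iv <- diff(gt$trigger_times_ms)
  expect_length(iv, 300)
  expect_true(all(abs(iv - 1000) < 1e-6))
  # conservation: triggers = intervals + 1
  expect_equal(length(gt$trigger_times_ms), length(iv) + 1L)
  expect_equal(length(gt$resp_waveform), round(300 * gt$fs_hz))
})

test_that("physiology generator validates its parameters", {
  expect_error(simulate_physio(hr_mean_bpm = 20), class = "sgmotion_invalid_parameter")
  expect_error(simulate_physio(duration_s = -5), class = "sgmotion_invalid_parameter")
  expect_error(simulate_physio(duration_s = 10), class = "sgmotion_invalid_parameter")
  expect_error(simulate_physio(fs_hz = 0), class = "sgmotion_invalid_parameter")
})

test_that("identical seeds give bit-identical simulations", {
  a <- simulate_physio(rsa_gain_bpm = 4, duration_s = 60, seed = 7)
  b <- simulate_physio(rsa_gain_bpm = 4, duration_s = 60, seed = 7)
  expect_identical(a, b)
  sa <- simulate_si_stack(a, n_positions = 8, n_coils = 2, seed = 3)
  sb <- simulate_si_stack(b, n_positions = 8, n_coils = 2, seed = 3)
  expect_identical(sa$readouts, sb$readouts)
  ea <- simulate_ecg_train(a, 0.05, 0.05, 3, seed = 5)
  eb <- simulate_ecg_train(b, 0.05, 0.05, 3, seed = 5)
  expect_identical(ea$time_ms, eb$time_ms)
})

test_that("respiratory sinus arrhythmia couples intervals to the breath", {
  # no coupling: inspiratory and expiratory rates agree to Monte-Carlo error
  diffs0 <- vapply(1:10, function(s) {
    gt <- simulate_physio(hr_sd_bpm = 2, rsa_gain_bpm = 0, duration_s = 120,
                          seed = s)
    r <- rsa_split(trigger_train(gt$trigger_times_ms, "ground-truth"),
                   gt$resp_waveform, gt$fs_hz)
    r$diff_bpm
  }, numeric(1))
  expect_lt(abs(mean(diffs0)), 1)

  # positive coupling: inspiration intervals shorter, by direct bookkeeping
  gt <- simulate_physio(hr_sd_bpm = 0, rsa_gain_bpm = 6, duration_s = 300,
                        seed = 2)
  iv <- diff(gt$trigger_times_ms)
  mid_s <- (head(gt$trigger_times_ms, -1) + iv / 2) / 1000
  flow <- approx(gt$time_s, gt$resp_flow, xout = mid_s, rule = 2)$y
  expect_lt(mean(iv[flow > 0]), mean(iv[flow < 0]))

  # monotonicity: larger gain, larger inspiration/expiration split
  gap <- function(gain) {
    mean(vapply(1:20, function(s) {
      g <- simulate_physio(hr_sd_bpm = 1, rsa_gain_bpm = gain,
                           duration_s = 60, seed = s)
      r <- rsa_split(trigger_train(g$trigger_times_ms, "ground-truth"),
                     g$resp_waveform, g$fs_hz)
      abs(r$diff_bpm)
    }, numeric(1)))
  }
  gaps <- c(gap(0), gap(3), gap(8))
  expect_true(all(diff(gaps) > 0))
})

test_that("noiseless SI stack is an exact low-rank mixture", {
  gt <- default_gt()
  st <- simulate_si_stack(gt, n_positions = 8, n_coils = 2, noise_sd = 0,
                          modulation_amplitude = 0, seed = 1)
  m <- assemble_sg_matrix(st)
  X <- m$values
  basis <- cbind(1, st$sources$resp, st$sources$cardiac)
  resid <- X - basis %*% qr.solve(basis, X)
  expect_lt(max(abs(resid)), 1e-9)

  # with modulation on, numerical rank stays below sources + levels (+ DC)
  st2 <- simulate_si_stack(gt, n_positions = 8, n_coils = 2, noise_sd = 0,
                           modulation_amplitude = 0.5, seed = 1)
  X2 <- assemble_sg_matrix(st2)$values
  X2c <- sweep(X2, 2, colMeans(X2))
  sv <- svd(X2c)$d
  expect_lte(sum(sv > 1e-8 * sv[1]), 2 + 22)
})

test_that("cardiac-dominated signals peak at the heart frequency", {
  gt <- default_gt()
  st <- default_stack()
  m <- assemble_sg_matrix(st)
  # column with the largest cardiac weight
  wc <- as.vector(st$weights$cardiac)
  j <- which.max(wc)
  x <- m$values[, j] - mean(m$values[, j])
  psd <- estimate_psd(x, st$fs_hz, segment_seconds = 30)
  in_card <- psd$freq_hz >= 0.5 & psd$freq_hz <= 2
  f_peak <- psd$freq_hz[in_card][which.max(psd$power[in_card])]
  # oracle: periodogram peak of the ground-truth cardiac source
  psd_true <- estimate_psd(st$sources$cardiac, st$fs_hz, 30)
  f_true <- psd_true$freq_hz[which.max(psd_true$power)]
  expect_lt(abs(f_peak - f_true), 0.05)
  # and the true peak sits at the simulated mean heart frequency
  expect_lt(abs(f_true - gt$params$hr_mean_bpm / 60), 0.05)
})

test_that("stack generator validates its parameters", {
  gt <- default_gt()
  expect_error(simulate_si_stack(gt, noise_sd = -1),
               class = "sgmotion_invalid_parameter")
  expect_error(simulate_si_stack(gt, n_positions = 4),
               class = "sgmotion_invalid_parameter")
  expect_error(simulate_si_stack(list()), class = "sgmotion_invalid_parameter")
})

test_that("defect-free ECG train reproduces the ground truth exactly", {
  gt <- default_gt()
  e <- simulate_ecg_train(gt, 0, 0, 0, seed = 1)
  expect_identical(e$time_ms, gt$trigger_times_ms)
  expect_identical(attr(e, "n_deleted"), 0L)
  expect_identical(attr(e, "n_inserted"), 0L)
})

test_that("ECG defects are injected with exact bookkeeping", {
  gt <- simulate_physio(hr_mean_bpm = 60, hr_sd_bpm = 0, duration_s = 300,
                        seed = 1)
  e <- simulate_ecg_train(gt, missing_rate = 0.05, extrasystole_rate = 0,
                          jitter_sd_ms = 0, seed = 9)
  nd <- attr(e, "n_deleted")
  expect_identical(nd, length(attr(e, "deleted_times_ms")))
  expect_identical(nrow(e), length(gt$trigger_times_ms) - nd)
  # every deletion in the constant train leaves a multiple-of-1000 gap
  iv <- diff(e$time_ms)
  expect_equal(sum(round(iv / 1000)) - length(iv), nd)
  # each isolated deletion produces exactly one 2000 ms interval
  expect_identical(sum(abs(iv - 2000) < 1e-6),
                   sum(round(iv / 1000) == 2))
  expect_error(simulate_ecg_train(gt, missing_rate = 0.5),
               class = "sgmotion_invalid_parameter")
})

test_that("edge phantom realizes the sigmoid model exactly", {
  ph <- make_edge_phantom(a0_px = 0, a1 = 100, a2 = 10, s = 0.5,
                          image_size = 64)
  mid <- (64 + 1) / 2
  row <- ph$image[, 32]                       # profile across the edge
  # the default curve runs bottom-to-top, so its +90 degree normal (the
  # positive profile coordinate, where intensity rises) points toward -x
  xx <- mid - seq_len(64)
  expect_lt(max(abs(row - (10 + 90 / (1 + 10^(-xx * 0.5))))), 1e-10)

  # steep limit approaches a step edge away from the centre
  ph2 <- make_edge_phantom(a0_px = 0, a1 = 100, a2 = 0, s = 50,
                           image_size = 64)
  row2 <- ph2$image[, 32]
  step <- ifelse(xx > 0, 100, 0)
  away <- abs(xx) > 1
  expect_lt(max(abs(row2[away] - step[away])), 1)

  expect_error(make_edge_phantom(a1 = 5, a2 = 10),
               class = "sgmotion_invalid_parameter")
  expect_error(make_edge_phantom(image_size = 16),
               class = "sgmotion_invalid_parameter")
})
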