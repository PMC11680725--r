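# ECG cleaning, alignment, the interval-SD metric and the RSA comparison.

test_that("moving-median cleaning flags forced defects and nothing else", {
  # one missing trigger in a metronome train
  times <- seq(0, 100000, by = 1000)
  gap <- times[-31]                       # 2000 ms interval at position 30
  tr <- clean_ecg(trigger_train(gap, "ECG"))
  fl <- attr(tr, "interval_flags")
  expect_identical(which(fl == "missing"), 30L)
  expect_identical(sum(fl != "valid"), 1L)

  # one inserted trigger splitting an interval 300/700
  ins <- sort(c(times, times[40] + 300))
  tr2 <- clean_ecg(trigger_train(ins, "ECG"))
  fl2 <- attr(tr2, "interval_flags")
  expect_identical(which(fl2 == "extrasystolic"), 40L)

  # constant train: never flagged
  tr3 <- clean_ecg(trigger_train(times, "ECG"))
  expect_true(all(attr(tr3, "interval_flags") == "valid"))

  # short trains shrink the window with a message
  expect_message(clean_ecg(trigger_train(times[1:12], "ECG")), "shrunk")
})

test_that("injected ECG deletions are detected with few false alarms", {
  hits <- 0; total <- 0; false_flags <- 0; intervals <- 0
  for (s in 1:10) {
    gt <- simulate_physio(hr_sd_bpm = 2, duration_s = 300, seed = s + 400)
    e <- simulate_ecg_train(gt, missing_rate = 0.02, seed = s)
    cl <- clean_ecg(e)
    fl <- attr(cl, "interval_flags")
    deleted <- attr(e, "deleted_times_ms")
    # a deletion is caught when its surrounding interval is flagged missing
    idx <- findInterval(deleted, cl$time_ms)
    hits <- hits + sum(fl[idx] == "missing")
    total <- total + length(deleted)
    # false flags: flagged intervals that contain no deletion at all
    false_flags <- false_flags + sum(fl != "valid") - length(unique(idx[fl[idx] != "valid"]))
    intervals <- intervals + length(fl)
  }
  expect_gte(hits / total, 0.95)
  expect_lt(false_flags / intervals, 0.01)
})

test_that("alignment recovers pure shifts to the search quantization", {
  gt <- simulate_physio(hr_sd_bpm = 3, duration_s = 120, seed = 5)
  ecg <- trigger_train(gt$trigger_times_ms, "ECG")
  sg0 <- trigger_train(gt$trigger_times_ms, "SG")
  expect_identical(align_triggers(sg0, ecg)$offset_ms, 0)

  sg130 <- trigger_train(gt$trigger_times_ms + 130, "SG")
  al <- align_triggers(sg130, ecg)
  expect_identical(al$offset_ms, -130)
  expect_equal(al$train$time_ms, ecg$time_ms, tolerance = 1e-9)

  sg134 <- trigger_train(gt$trigger_times_ms + 134, "SG")
  al2 <- align_triggers(sg134, ecg)
  expect_lte(abs(al2$offset_ms - (-134)), 5)

  far <- trigger_train(gt$trigger_times_ms + 1e7, "SG")
  expect_error(align_triggers(far, ecg), class = "sgmotion_invalid_parameter")
})

test_that("the interval-SD statistic matches hand arithmetic", {
  s_times <- c(0, cumsum(c(800, 820, 790)))
  e_times <- c(0, cumsum(c(810, 800, 800)))
  cmp <- compute_isd(trigger_train(s_times, "SG"), trigger_train(e_times, "ECG"))
  expect_equal(cmp$pairs$abs_diff_ms, c(10, 20, 10))
  expect_equal(cmp$mu_ms, 40 / 3, tolerance = 1e-12)
  expect_equal(cmp$isd_ms, sqrt(sum((c(10, 20, 10) - 40 / 3)^2) / 2),
               tolerance = 1e-12)
  expect_identical(cmp$n, 3L)

  # perfect agreement and shift invariance
  cmp0 <- compute_isd(trigger_train(e_times, "SG"), trigger_train(e_times, "ECG"))
  expect_identical(cmp0$mu_ms, 0)
  expect_identical(cmp0$isd_ms, 0)
  cmp_shift <- compute_isd(trigger_train(s_times + 5000, "SG"),
                           trigger_train(e_times + 5000, "ECG"))
  expect_equal(cmp_shift$isd_ms, cmp$isd_ms, tolerance = 1e-12)
})

test_that("interval-SD equals the explicit brute-force computation", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:60, 1)
    base <- cumsum(runif(n, 700, 1100))
    jit <- rnorm(n, 0, 8)
    cmp <- compute_isd(trigger_train(base + jit, "SG"),
                       trigger_train(base, "ECG"))
    expect_equal(cmp$isd_ms, isd_brute_force(base + jit, base),
                 tolerance = 1e-9)
  }
})

test_that("tidiers expose the comparison in broom form", {
  s_times <- c(0, cumsum(c(800, 820, 790)))
  e_times <- c(0, cumsum(c(810, 800, 800)))
  cmp <- compute_isd(trigger_train(s_times, "SG"), trigger_train(e_times, "ECG"))
  expect_named(generics::tidy(cmp),
               c("ecg_interval_index", "sg_interval_ms", "ecg_interval_ms",
                 "abs_diff_ms"))
  gl <- generics::glance(cmp)
  expect_identical(gl$n, 3L)
  expect_equal(gl$isd_ms, cmp$isd_ms)
})

test_that("RSA split is null without coupling and exact for constant rate", {
  gt0 <- simulate_physio(hr_mean_bpm = 72, hr_sd_bpm = 0, rsa_gain_bpm = 0,
                         duration_s = 120, seed = 3)
  r0 <- rsa_split(trigger_train(gt0$trigger_times_ms, "ground-truth"),
                  gt0$resp_waveform, gt0$fs_hz)
  expect_equal(r0$diff_bpm, 0, tolerance = 1e-9)

  # positive coupling raises inspiratory HR in nearly every seed
  wins <- vapply(1:20, function(s) {
    g <- simulate_physio(hr_sd_bpm = 1, rsa_gain_bpm = 5, duration_s = 90,
                         seed = s + 600)
    r <- rsa_split(trigger_train(g$trigger_times_ms, "ground-truth"),
                   g$resp_waveform, g$fs_hz)
    r$diff_bpm > 0
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("paired Bonett-Seier test behaves at the null and under scaling", {
  set.seed(2)
  d1 <- rnorm(50)
  bs0 <- bonett_seier_paired(d1, d1)
  expect_identical(bs0$statistic, 0)
  expect_identical(bs0$p_value, 0.5)

  d2 <- rnorm(50)
  a <- bonett_seier_paired(d1, d2, "two.sided")
  b <- bonett_seier_paired(d2, d1, "two.sided")
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)

  # 3x dispersion is detected in nearly every repetition
  rejections <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(50)
    y <- 3 * rnorm(50)
    bonett_seier_paired(x, y, "less")$p_value < 0.05
  }, logical(1))
  expect_gte(sum(rejections), 48)

  expect_error(bonett_seier_paired(rep(1, 10), rnorm(10)),
               class = "sgmotion_invalid_parameter")
})

test_that("Bonett-Seier p-values agree with a permutation oracle", {
  perm_p <- function(x, y, n_perm = 1e4) {
    n <- length(x)
    stat <- function(a, b) log(mean(abs(a - mean(a))) / mean(abs(b - mean(b))))
    obs <- stat(x, y)
    set.seed(99)
    cnt <- 0
    for (i in seq_len(n_perm)) {
      swap <- runif(n) < 0.5
      xp <- ifelse(swap, y, x)
      yp <- ifelse(swap, x, y)
      if (stat(xp, yp) <= obs) cnt <- cnt + 1
    }
    cnt / n_perm
  }
  set.seed(31)
  for (ratio in c(1, 1.4)) {
    x <- rnorm(50)
    y <- ratio * rnorm(50)
    p_bs <- bonett_seier_paired(x, y, "less")$p_value
    p_perm <- perm_p(x, y)
    expect_lt(abs(p_bs - p_perm), 0.02)
  }
})

test_that("Bland-Altman limits and regression react to bias and noise", {
  x <- seq(800, 1000, length.out = 100)
  ba0 <- bland_altman(x, x)
  expect_identical(ba0$mean_diff, 0)
  expect_identical(ba0$lower_loa, 0)
  expect_identical(ba0$upper_loa, 0)
  expect_equal(ba0$r_squared, 1)

  ba_bias <- bland_altman(x + 10, x)
  expect_equal(ba_bias$mean_diff, 10, tolerance = 1e-12)
  expect_equal(ba_bias$upper_loa - ba_bias$lower_loa, 0, tolerance = 1e-12)

  set.seed(4)
  e <- rnorm(500, 0, 5)
  xx <- runif(500, 700, 1100)
  ba_n <- bland_altman(xx + e, xx)
  width <- ba_n$upper_loa - ba_n$lower_loa
  expect_lt(abs(width - 2 * 1.96 * 5) / (2 * 1.96 * 5), 0.15)

  expect_error(bland_altman(1:2, 1:2), class = "sgmotion_invalid_parameter")
})
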