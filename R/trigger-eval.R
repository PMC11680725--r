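#' Flag missing and extrasystolic triggers in an ECG train
#'
#' For each trigger-to-trigger interval, the median of its 40 nearest
#' intervals (20 on each side in index order, truncated at the series edges)
#' is computed. Intervals longer than 1.5 x this moving median indicate a
#' missing trigger; intervals shorter than 0.5 x the median indicate a false
#' or extrasystolic trigger. Flagged intervals are excluded from downstream
#' pairing; a constant train is never flagged.
#'
#' @param t A `trigger_train` (>= 3 triggers).
#' @param window Number of neighbouring intervals in the moving median
#'   (shrinks, with a message, when fewer are available).
#' @param upper,lower Flagging thresholds relative to the moving median.
#' @return The train with per-trigger flags updated and an
#'   `interval_flags` attribute (`"valid"`, `"missing"`, `"extrasystolic"`
#'   per interval) consumed by [compute_isd()].
#' @export
clean_ecg <- function(t, window = 40, upper = 1.5, lower = 0.5) {
  t <- as_trigger_train(t)
  n <- nrow(t)
  if (n < 3L) abort("need at least 3 triggers.",
                    class = "sgmotion_invalid_parameter")
  iv <- diff(t$time_ms)
  m <- length(iv)
  if (m < window + 1L) {
    inform(sprintf("only %d intervals available; moving-median window shrunk from %d.",
                   m - 1L, window))
  }
  half <- window %/% 2L
  flags <- rep("valid", m)
  for (i in seq_len(m)) {
    lo <- max(1L, i - half)
    hi <- min(m, i + half)
    nb <- setdiff(lo:hi, i)
    med <- median(iv[nb])
    if (iv[i] > upper * med) flags[i] <- "missing"
    else if (iv[i] < lower * med) flags[i] <- "extrasystolic"
  }
  trig_flags <- rep("valid", n)
  trig_flags[which(flags == "missing")] <- "missing-adjacent"
  trig_flags[which(flags == "missing") + 1L] <- "missing-adjacent"
  trig_flags[which(flags == "extrasystolic") + 1L] <- "extrasystolic"
  t$flag <- trig_flags
  attr(t, "interval_flags") <- flags
  t
}

#' Align self-gated triggers to ECG triggers
#'
#' Self-gated triggers lag the ECG R-wave by an unknown physiological
#' offset. The SG train is shifted over offsets spanning plus/minus one
#' median interval in 10 ms increments; for each offset every SG trigger is
#' matched to its nearest ECG trigger (matches farther than 0.5 x the median
#' interval are excluded), and the offset minimizing the mean absolute
#' matched difference is returned together with the shifted train. Ties are
#' broken toward the smallest absolute offset.
#'
#' @param sg,ecg `trigger_train`s with overlapping time spans (>= 10
#'   triggers each).
#' @param step_ms Offset search increment in ms.
#' @return List with `train` (the shifted SG `trigger_train`) and
#'   `offset_ms` (the applied shift).
#' @export
align_triggers <- function(sg, ecg, step_ms = 10) {
  sg <- as_trigger_train(sg); ecg <- as_trigger_train(ecg)
  if (nrow(sg) < 10L || nrow(ecg) < 10L) {
    abort("need at least 10 triggers in each train.",
          class = "sgmotion_invalid_parameter")
  }
  med <- median(diff(ecg$time_ms))
  if (min(sg$time_ms) > max(ecg$time_ms) + med ||
      max(sg$time_ms) < min(ecg$time_ms) - med) {
    abort("trigger trains do not overlap in time.",
          class = "sgmotion_invalid_parameter")
  }
  half_n <- floor(med / step_ms)
  offsets <- seq(-half_n, half_n) * step_ms   # grid centred on zero shift
  score <- vapply(offsets, function(off) {
    d <- nearest_distance(sg$time_ms + off, ecg$time_ms)
    d <- d[d <= 0.5 * med]
    if (length(d) == 0L) Inf else mean(d)
  }, numeric(1))
  best <- order(score, abs(offsets))[1]
  off <- offsets[best]
  shifted <- trigger_train(sg$time_ms + off, source = sg$source[1],
                           flag = sg$flag)
  attr(shifted, "interval_flags") <- attr(sg, "interval_flags")
  list(train = shifted, offset_ms = off)
}

# |distance| from each x to its nearest y (y sorted)
nearest_distance <- function(x, y) {
  i <- findInterval(x, y)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(y))
  pmin(abs(x - y[lo]), abs(x - y[hi]))
}

# index of nearest y for each x
nearest_index <- function(x, y) {
  i <- findInterval(x, y)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(y))
  ifelse(abs(x - y[lo]) <= abs(x - y[hi]), lo, hi)
}

#' Interval standard deviation (ISD) between paired trigger trains
#'
#' The precision metric of the framework: consecutive SG intervals
#' \eqn{S_{n+1}-S_n} are paired with their corresponding ECG intervals
#' \eqn{E_{n+1}-E_n} (nearest-trigger matching, both triggers matched to
#' consecutive ECG triggers, flagged intervals excluded), the absolute
#' interval differences \eqn{d_n = |(S_{n+1}-S_n) - (E_{n+1}-E_n)|} are
#' formed, and
#'
#' \deqn{ISD = \sqrt{ \frac{1}{N-1} \sum_{n=1}^{N} (d_n - \mu)^2 }}
#'
#' with \eqn{\mu} the mean of the absolute differences over the N paired
#' intervals. A lower ISD means more precise triggers; it is 0 when all
#' interval differences are equal (in particular when all are 0), and it is
#' invariant to shifting both trains by a constant.
#'
#' @param sg Aligned SG `trigger_train` (see [align_triggers()]).
#' @param ecg Cleaned ECG `trigger_train` (see [clean_ecg()]).
#' @return Object of class `trigger_comparison`: list with `pairs` (tibble
#'   of paired intervals and differences), `mu_ms`, `isd_ms`, `n`,
#'   `offset_ms` if the SG train carries one, and the two source labels.
#' @export
compute_isd <- function(sg, ecg) {
  sg <- as_trigger_train(sg); ecg <- as_trigger_train(ecg)
  ecg_flags <- attr(ecg, "interval_flags") %||% rep("valid", nrow(ecg) - 1L)
  sg_flags <- attr(sg, "interval_flags") %||% rep("valid", nrow(sg) - 1L)

  med <- median(diff(ecg$time_ms))
  m <- nearest_index(sg$time_ms, ecg$time_ms)
  dist <- abs(sg$time_ms - ecg$time_ms[m])
  matched <- dist <= 0.5 * med

  ns <- nrow(sg)
  i <- seq_len(ns - 1L)
  ok <- matched[i] & matched[i + 1L] &
    (m[i + 1L] == m[i] + 1L) &
    ecg_flags[m[i]] == "valid" &
    sg_flags[i] == "valid"
  ok[is.na(ok)] <- FALSE
  idx <- i[ok]
  if (length(idx) < 2L) {
    abort("fewer than 2 paired intervals.",
          class = "sgmotion_invalid_parameter")
  }
  s_int <- sg$time_ms[idx + 1L] - sg$time_ms[idx]
  e_int <- ecg$time_ms[m[idx] + 1L] - ecg$time_ms[m[idx]]
  d <- abs(s_int - e_int)
  structure(
    list(pairs = tibble(ecg_interval_index = m[idx],
                        sg_interval_ms = s_int, ecg_interval_ms = e_int,
                        abs_diff_ms = d),
         mu_ms = mean(d), isd_ms = sd(d), n = length(d),
         offset_ms = attr(sg, "offset_ms"),
         sg_source = sg$source[1], ecg_source = ecg$source[1]),
    class = "trigger_comparison"
  )
}

#' @export
print.trigger_comparison <- function(x, ...) {
  cat("<trigger_comparison>\n")
  cat(sprintf("  %s vs %s: N = %d paired intervals\n",
              x$sg_source, x$ecg_source, x$n))
  cat(sprintf("  mu = %.2f ms, ISD = %.2f ms\n", x$mu_ms, x$isd_ms))
  invisible(x)
}

#' Compare heart rate between inspiration and expiration
#'
#' Assigns each cardiac interval to inspiration or expiration by the sign of
#' the respiratory derivative at the interval midpoint (the respiratory
#' signal must be conditioned so inspiration is high, see
#' [condition_respiratory()]), and compares the mean heart rates of the two
#' classes. With respiratory sinus arrhythmia the inspiratory mean is
#' higher. For a single subject the p-value is from a two-sample t-test
#' across intervals; use [rsa_test()] for the paired across-subject test.
#'
#' @param t A `trigger_train`.
#' @param resp Conditioned respiratory signal sampled at `fs_hz`.
#' @param fs_hz Sampling rate of `resp` in Hz.
#' @return One-row tibble: `mean_hr_insp_bpm`, `mean_hr_exp_bpm`,
#'   `diff_bpm`, `n_insp`, `n_exp`, `p_value`.
#' @export
rsa_split <- function(t, resp, fs_hz) {
  t <- as_trigger_train(t)
  iv <- trigger_intervals(t, valid_only = TRUE)
  mid_s <- (iv$start_ms + iv$end_ms) / 2 / 1000
  time_s <- (seq_along(resp) - 1) / fs_hz
  deriv <- c(diff(resp), NA) * fs_hz
  d_mid <- approx(time_s, deriv, xout = mid_s, rule = 2)$y
  insp <- d_mid > 0
  hr <- 60000 / iv$length_ms
  if (all(insp) || all(!insp)) {
    abort("all intervals fall in one respiratory phase; comparison undefined.",
          class = "sgmotion_undefined_comparison")
  }
  tol <- 1e-9 * mean(hr)
  p <- if (sd(hr[insp]) < tol && sd(hr[!insp]) < tol) {
    if (abs(mean(hr[insp]) - mean(hr[!insp])) < tol) 1 else 0
  } else {
    tryCatch(t.test(hr[insp], hr[!insp])$p.value, error = function(e) NA_real_)
  }
  tibble(mean_hr_insp_bpm = mean(hr[insp]),
         mean_hr_exp_bpm = mean(hr[!insp]),
         diff_bpm = mean(hr[insp]) - mean(hr[!insp]),
         n_insp = sum(insp), n_exp = sum(!insp),
         p_value = p)
}

#' Paired t-test of inspiratory vs expiratory heart rate across subjects
#'
#' @param per_subject Data frame with columns `mean_hr_insp_bpm` and
#'   `mean_hr_exp_bpm`, one row per subject (e.g. from binding
#'   [rsa_split()] results).
#' @return One-row tibble: subject-mean inspiratory and expiratory HR, mean
#'   difference and paired t-test p-value.
#' @export
rsa_test <- function(per_subject) {
  if (nrow(per_subject) < 2L) {
    abort("need at least 2 subjects for the paired test.",
          class = "sgmotion_invalid_parameter")
  }
  tt <- t.test(per_subject$mean_hr_insp_bpm, per_subject$mean_hr_exp_bpm,
               paired = TRUE)
  tibble(mean_hr_insp_bpm = mean(per_subject$mean_hr_insp_bpm),
         mean_hr_exp_bpm = mean(per_subject$mean_hr_exp_bpm),
         diff_bpm = unname(tt$estimate),
         p_value = tt$p.value,
         n_subjects = nrow(per_subject))
}
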