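#' Simulate coupled cardiac and respiratory ground-truth physiology
#'
#' Generates a respiratory waveform and a cardiac trigger train with known
#' ground truth for testing the self-gating pipeline. The respiratory waveform
#' is a band-limited breathing pattern with a long end-expiratory dwell
#' (a raised-cosine-power cycle, spectral content at the breathing frequency
#' and its second harmonic only, so it stays below 0.7 Hz for the default
#' 0.25 Hz breathing rate). Cardiac triggers are produced by an
#' integrate-and-fire oscillator whose instantaneous rate is
#'
#' \deqn{HR(t) = HR_{mean} + g \cdot \dot r(t) + \eta_n}
#'
#' where \eqn{\dot r(t)} is the respiratory flow (time derivative of the
#' waveform, normalized to unit peak) and \eqn{\eta_n} is white per-beat
#' heart-rate-variability noise. Coupling to the flow realizes respiratory
#' sinus arrhythmia: the heart rate rises during inspiration (positive flow)
#' and falls during expiration.
#'
#' @param hr_mean_bpm Mean heart rate in beats per minute (30--150).
#' @param hr_sd_bpm Per-beat heart-rate variability SD in bpm (>= 0).
#' @param resp_freq_hz Breathing frequency in Hz (must stay at or below
#'   0.35 Hz so the waveform, including its second harmonic, is band-limited
#'   to 0.7 Hz).
#' @param rsa_gain_bpm Respiratory sinus arrhythmia gain in bpm per unit of
#'   normalized respiratory flow; 0 decouples heart rate from respiration.
#' @param duration_s Simulated duration in seconds (>= 30).
#' @param fs_hz Sampling rate of the respiratory waveform in Hz; the default
#'   is one sample per 22-readout trajectory segment at TR = 2.84 ms,
#'   1/(22 x 2.84 ms) = 16.0 Hz.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `physio_ground_truth`: a list with
#'   `trigger_times_ms` (strictly increasing, starting at 0),
#'   `resp_waveform` (length `round(duration_s * fs_hz)`),
#'   `resp_phase` (factor, `"inspiration"`/`"expiration"` per sample),
#'   `resp_flow` (normalized derivative), `cardiac_phase` (beats, real),
#'   `time_s`, `fs_hz`, `beat_hr_bpm`, and `params`.
#' @examples
#' gt <- simulate_physio(hr_mean_bpm = 60, hr_sd_bpm = 0, rsa_gain_bpm = 0,
#'                       duration_s = 60, seed = 1)
#' range(diff(gt$trigger_times_ms))
#' @export
simulate_physio <- function(hr_mean_bpm = 60,
                            hr_sd_bpm = 2,
                            resp_freq_hz = 0.25,
                            rsa_gain_bpm = 0,
                            duration_s = 300,
                            fs_hz = 1 / (22 * 2.84e-3),
                            seed = 1L) {
  check_in_range(hr_mean_bpm, "hr_mean_bpm", 30, 150)
  check_non_negative(hr_sd_bpm, "hr_sd_bpm")
  check_in_range(resp_freq_hz, "resp_freq_hz", 0.05, 0.35)
  check_non_negative(rsa_gain_bpm, "rsa_gain_bpm")
  check_positive(duration_s, "duration_s")
  check_positive(fs_hz, "fs_hz")
  if (duration_s < 30) {
    abort("`duration_s` must be at least 30 s.",
          class = "sgmotion_invalid_parameter")
  }

  # analytic respiratory cycle: r(t) = cos^4(pi f t), dwell near 0 at
  # end-expiration, brief peaks at end-inspiration
  resp_fun <- function(t) cos(pi * resp_freq_hz * t)^4
  flow_fun <- function(t) {
    -4 * pi * resp_freq_hz * cos(pi * resp_freq_hz * t)^3 *
      sin(pi * resp_freq_hz * t)
  }
  flow_peak <- 4 * pi * resp_freq_hz * sqrt(27) / 16  # max of |cos^3 sin|

  n_samp <- round(duration_s * fs_hz)
  time_s <- (seq_len(n_samp) - 1) / fs_hz
  resp_waveform <- resp_fun(time_s)
  resp_flow <- flow_fun(time_s) / flow_peak
  resp_phase <- factor(ifelse(resp_flow > 0, "inspiration", "expiration"),
                       levels = c("inspiration", "expiration"))

  # integrate-and-fire on a fine grid; deterministic part of the phase rate
  # is accumulated by the trapezoid rule, per-beat HRV is added beat by beat
  dt <- 1e-3
  tg <- seq(0, duration_s, by = dt)
  rate <- (hr_mean_bpm + rsa_gain_bpm * flow_fun(tg) / flow_peak) / 60
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))

  n_beats_max <- ceiling(duration_s * (hr_mean_bpm + rsa_gain_bpm +
                                         6 * hr_sd_bpm) / 60) + 2L
  hrv <- with_seed(seed, {
    if (hr_sd_bpm > 0) rnorm(n_beats_max, 0, hr_sd_bpm) else numeric(n_beats_max)
  })

  triggers <- numeric(n_beats_max + 1L)
  triggers[1] <- 0
  n_trig <- 1L
  t_cur <- 0
  g_cur <- 0
  n_grid <- length(tg)
  win <- ceiling(6 * 60 / hr_mean_bpm / dt)  # search window ~6 mean beats
  repeat {
    eta <- hrv[n_trig] / 60
    i0 <- max(1L, findInterval(t_cur, tg))
    i1 <- min(n_grid, i0 + win)
    sl <- i0:i1
    # solve cum(t) - g_cur + eta * (t - t_cur) = 1 for the next trigger
    target <- cum[sl] + eta * (tg[sl] - t_cur) - g_cur
    hit <- which(target >= 1 - 1e-9 & tg[sl] > t_cur)
    if (length(hit) == 0L && i1 < n_grid) {
      sl <- i0:n_grid
      target <- cum[sl] + eta * (tg[sl] - t_cur) - g_cur
      hit <- which(target >= 1 - 1e-9 & tg[sl] > t_cur)
    }
    if (length(hit) == 0L) break
    i <- hit[1]
    if (i == 1L) break
    # linear interpolation between grid nodes
    f0 <- target[i - 1]; f1 <- target[i]
    t_next <- tg[sl[i - 1]] + dt * (1 - f0) / (f1 - f0)
    t_next <- min(t_next, duration_s)
    if (t_next <= t_cur) break
    n_trig <- n_trig + 1L
    triggers[n_trig] <- t_next
    t_cur <- t_next
    g_cur <- approx(tg, cum, xout = t_cur)$y
    if (t_cur >= duration_s - 1e-9) break
  }
  trigger_times_ms <- triggers[seq_len(n_trig)] * 1000

  # continuous cardiac phase at the coarse grid: piecewise over beats using
  # the same deterministic integral plus the per-beat HRV ramp
  cardiac_phase <- numeric(n_samp)
  trig_s <- trigger_times_ms / 1000
  beat_idx <- pmax(findInterval(time_s, trig_s), 1L)
  g_trig <- approx(tg, cum, xout = trig_s)$y
  g_t <- approx(tg, cum, xout = time_s)$y
  cardiac_phase <- (beat_idx - 1) + (g_t - g_trig[beat_idx]) +
    (hrv[beat_idx] / 60) * (time_s - trig_s[beat_idx])

  structure(
    list(
      trigger_times_ms = trigger_times_ms,
      resp_waveform = resp_waveform,
      resp_phase = resp_phase,
      resp_flow = resp_flow,
      cardiac_phase = cardiac_phase,
      time_s = time_s,
      fs_hz = fs_hz,
      beat_hr_bpm = hr_mean_bpm + hrv[seq_len(max(n_trig - 1L, 1L))],
      params = list(hr_mean_bpm = hr_mean_bpm, hr_sd_bpm = hr_sd_bpm,
                    resp_freq_hz = resp_freq_hz, rsa_gain_bpm = rsa_gain_bpm,
                    duration_s = duration_s, fs_hz = fs_hz, seed = seed)
    ),
    class = "physio_ground_truth"
  )
}

#' @export
print.physio_ground_truth <- function(x, ...) {
  p <- x$params
  cat("<physio_ground_truth>\n")
  cat(sprintf("  duration %g s at fs %.3f Hz (%d samples)\n",
              p$duration_s, p$fs_hz, length(x$resp_waveform)))
  cat(sprintf("  %d triggers, mean RR %.1f ms\n",
              length(x$trigger_times_ms), mean(diff(x$trigger_times_ms))))
  cat(sprintf("  HR %g +/- %g bpm, resp %g Hz, RSA gain %g bpm\n",
              p$hr_mean_bpm, p$hr_sd_bpm, p$resp_freq_hz, p$rsa_gain_bpm))
  invisible(x)
}
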