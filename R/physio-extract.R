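#' Welch-averaged power spectral density
#'
#' Splits the signal into Hann-windowed segments with 50% overlap, averages
#' the segment periodograms, and returns a one-sided density on a frequency
#' grid from 0 to fs/2.
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling rate in Hz.
#' @param segment_seconds Segment length in seconds (default 30 s; the
#'   signal must contain at least two segments).
#' @return Tibble with columns `freq_hz`, `power`.
#' @export
estimate_psd <- function(x, fs_hz, segment_seconds = 30) {
  check_positive(fs_hz, "fs_hz")
  check_positive(segment_seconds, "segment_seconds")
  nseg <- round(segment_seconds * fs_hz)
  if (length(x) < 2 * nseg) {
    abort("signal too short: need at least 2 Welch segments.",
          class = "sgmotion_invalid_parameter")
  }
  step <- floor(nseg / 2)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- fs_hz * sum(w^2)
  acc <- numeric(floor(nseg / 2) + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / scale
    half <- P[seq_len(floor(nseg / 2) + 1L)]
    # one-sided: double everything except DC (and Nyquist for even n)
    half[-1] <- half[-1] * 2
    if (nseg %% 2 == 0) half[length(half)] <- half[length(half)] / 2
    acc <- acc + half
  }
  tibble(freq_hz = (seq_along(acc) - 1L) * fs_hz / nseg,
         power = acc / length(starts))
}

#' Select the component with the most prominent spectral peak in a band
#'
#' For each component (normalized to unit variance so selection is
#' scale-invariant), the tallest local maximum of its Welch power spectral
#' density inside the band is fitted with a Gaussian on a local window
#' around the peak, and the component with the largest fitted amplitude is
#' selected. Ties are broken by lowest component index. Respiratory and
#' cardiac bands follow the physiological ranges 0.1--0.7 Hz and
#' 0.5--2.0 Hz.
#'
#' @param ss A `source_set`.
#' @param band_hz Length-2 numeric band (Hz), e.g. `c(0.1, 0.7)`.
#' @param segment_seconds Welch segment length passed to [estimate_psd()].
#' @param exclude Integer component indices to leave out of the candidacy
#'   (e.g. an already-selected respiratory component).
#' @return List with `index` (selected component) and `fit`, a one-row
#'   tibble (`component`, `amplitude`, `center_hz`, `width_hz`, `in_band`,
#'   `residual`, `fit_ok`), plus `candidates` with one row per component
#'   that had an in-band peak. Errors with class `sgmotion_no_candidate`
#'   when no component has an in-band local maximum; callers may fall back
#'   to the raw in-band power argmax (see [run_extraction()], which logs the
#'   fallback).
#' @export
select_component <- function(ss, band_hz, segment_seconds = 30,
                             exclude = integer()) {
  if (!inherits(ss, "source_set")) {
    abort("`ss` must be a source_set.", class = "sgmotion_invalid_parameter")
  }
  if (length(band_hz) != 2L || band_hz[1] >= band_hz[2]) {
    abort("`band_hz` must be an increasing length-2 numeric.",
          class = "sgmotion_invalid_parameter")
  }
  k <- ncol(ss$sources)
  fits <- vector("list", k)
  for (j in seq_len(k)) {
    if (j %in% exclude) next
    x <- ss$sources[, j]
    s <- sd(x)
    if (s < 1e-300) next
    psd <- estimate_psd(x / s, ss$fs_hz, segment_seconds)
    fits[[j]] <- fit_spectral_peak(psd, band_hz, component = j)
  }
  cand <- dplyr::bind_rows(fits[!vapply(fits, is.null, logical(1))])
  if (nrow(cand) == 0L) {
    abort(sprintf("no component has a local PSD maximum in [%g, %g] Hz.",
                  band_hz[1], band_hz[2]),
          class = "sgmotion_no_candidate")
  }
  best <- cand[order(-cand$amplitude, cand$component), , drop = FALSE][1, ]
  list(index = best$component, fit = best, candidates = cand)
}

# Fit a Gaussian to the tallest in-band local maximum of one PSD.
fit_spectral_peak <- function(psd, band_hz, component,
                              window_bins = 5L) {
  f <- psd$freq_hz; p <- psd$power
  n <- length(p)
  in_band <- which(f >= band_hz[1] & f <= band_hz[2])
  in_band <- in_band[in_band > 1L & in_band < n]
  if (length(in_band) == 0L) return(NULL)
  is_max <- p[in_band] > p[in_band - 1L] & p[in_band] >= p[in_band + 1L]
  peaks <- in_band[is_max]
  if (length(peaks) == 0L) return(NULL)
  ipk <- peaks[which.max(p[peaks])]

  win <- max(1L, ipk - window_bins):min(n, ipk + window_bins)
  fw <- f[win]; pw <- p[win]
  df <- f[2] - f[1]
  start <- list(a = max(pw) - min(pw), c = f[ipk], w = 2 * df, b = min(pw))
  fit <- tryCatch(
    minpack.lm::nlsLM(pw ~ a * exp(-(fw - c)^2 / (2 * w^2)) + b,
                      start = start,
                      lower = c(a = 0, c = min(fw), w = df / 4, b = -Inf),
                      upper = c(a = Inf, c = max(fw), w = diff(range(fw)) * 2,
                                b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(component = component, amplitude = p[ipk] - min(pw),
                  center_hz = f[ipk], width_hz = NA_real_,
                  in_band = TRUE, residual = NA_real_, fit_ok = FALSE))
  }
  cf <- coef(fit)
  tibble(component = component,
         amplitude = unname(cf["a"]),
         center_hz = unname(cf["c"]),
         width_hz = abs(unname(cf["w"])),
         in_band = cf["c"] >= band_hz[1] && cf["c"] <= band_hz[2],
         residual = sqrt(mean(stats::residuals(fit)^2)),
         fit_ok = TRUE)
}

#' Condition a respiratory component into a usable respiratory signal
#'
#' Zero-phase low-pass filters at 0.7 Hz to remove contamination from other
#' sources, removes the least-squares linear trend, and orients the signal
#' so that inspiration corresponds to higher values: breathing dwells at
#' end-expiration, so the long-dwell plateau must sit below the median,
#' i.e. the sign is flipped when the skewness is negative.
#'
#' @param x Numeric respiratory component.
#' @param fs_hz Sampling rate in Hz.
#' @param cutoff_hz Low-pass cutoff (default 0.7 Hz).
#' @return Conditioned numeric signal (same length).
#' @export
condition_respiratory <- function(x, fs_hz, cutoff_hz = 0.7) {
  check_positive(fs_hz, "fs_hz")
  bf <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "low")
  y <- zero_phase_filter(bf, x - mean(x),
                         pad = round(3 * fs_hz / cutoff_hz))
  idx <- seq_along(y)
  y <- stats::residuals(lm(y ~ idx))
  if (skewness(y) < 0) y <- -y
  as.numeric(y)
}

#' Detect cardiac triggers by interpolated zero crossings
#'
#' Band-passes the cardiac component to 0.5--2.0 Hz with a zero-phase
#' filter, removes the mean, and locates negative-to-positive zero crossings
#' with linear interpolation between samples (sub-sample timing in ms).
#' Crossings closer than 0.4 x the running median interval are suppressed
#' (refractory rule). The crossing polarity (rising vs falling) is chosen
#' automatically: the set with the steeper mean slope at its crossings wins
#' (the systolic upstroke localizes the trigger most precisely); near-equal
#' slopes fall back to the lower interval coefficient of variation, then to
#' rising. Both polarities of a sign-flipped input yield the same candidate
#' sets, so the detected triggers are identical.
#'
#' @param x Numeric cardiac component.
#' @param fs_hz Sampling rate in Hz.
#' @param band_hz Cardiac band for the internal band-pass filter.
#' @param refractory_factor Fraction of the running median interval below
#'   which a crossing is suppressed.
#' @param source Source label stamped on the returned train.
#' @return A `trigger_train` of sub-sample trigger times in ms.
#' @export
detect_triggers <- function(x, fs_hz, band_hz = c(0.5, 2.0),
                            refractory_factor = 0.4, source = "SG") {
  check_positive(fs_hz, "fs_hz")
  bf <- signal::butter(2, band_hz / (fs_hz / 2), type = "pass")
  y <- zero_phase_filter(bf, x - mean(x),
                         pad = round(3 * fs_hz / band_hz[1]))
  y <- y - mean(y)

  rising <- refractory_filter(zero_crossings_ms(y, fs_hz), refractory_factor)
  falling <- refractory_filter(zero_crossings_ms(-y, fs_hz), refractory_factor)

  cv <- function(t) {
    if (length(t) < 3L) return(Inf)
    iv <- diff(t); sd(iv) / mean(iv)
  }
  # mean |slope| of the signal at the crossing instants (per-ms units)
  slope_at <- function(t, sig) {
    if (length(t) == 0L) return(0)
    i <- pmin(pmax(floor(t / 1000 * fs_hz) + 1L, 1L), length(sig) - 1L)
    mean(abs(sig[i + 1L] - sig[i])) * fs_hz / 1000
  }
  cands <- list(rising = rising, falling = falling)
  slopes <- c(rising = slope_at(rising, y), falling = slope_at(falling, y))
  cvs <- vapply(cands, cv, numeric(1))
  rel <- abs(diff(slopes)) / max(max(slopes), 1e-300)
  pick <- if (rel > 1e-6) {
    names(slopes)[which.max(slopes)]
  } else if (cvs["falling"] < cvs["rising"]) "falling" else "rising"
  times <- cands[[pick]]
  if (length(times) < 3L) {
    abort("fewer than 3 zero crossings detected.",
          class = "sgmotion_too_few_crossings")
  }
  out <- trigger_train(times, source = source)
  attr(out, "polarity") <- pick
  out
}

# Forward-backward filtering with linear-prediction (Burg AR) end padding.
# Simple reflection padding flips the phase of in-band oscillations at the
# junction, and the resulting transient of a 0.5 Hz-corner IIR filter bleeds
# seconds into the record; AR extrapolation continues the oscillation
# phase-coherently, so filter transients stay inside the discarded pads.
zero_phase_filter <- function(bf, x, pad, ar_order = 20) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), 10L * n))
  extrapolate <- function(v) {
    fit <- tryCatch(stats::ar(v, aic = FALSE,
                              order.max = min(ar_order, n %/% 3),
                              method = "burg"),
                    error = function(e) NULL)
    if (is.null(fit) || fit$order == 0) return(rep(v[n], pad))
    as.numeric(predict(fit, n.ahead = pad, se.fit = FALSE))
  }
  fwd <- extrapolate(x)
  bwd <- rev(extrapolate(rev(x)))
  y <- signal::filtfilt(bf, c(bwd, x, fwd))
  y[(pad + 1L):(pad + n)]
}

# negative-to-positive crossings of y, sub-sample by linear interpolation,
# returned in ms (sample i sits at time (i - 1) / fs)
zero_crossings_ms <- function(y, fs_hz) {
  n <- length(y)
  i <- which(y[-n] < 0 & y[-1] >= 0)
  if (length(i) == 0L) return(numeric(0))
  frac <- -y[i] / (y[i + 1L] - y[i])
  ((i - 1L) + frac) / fs_hz * 1000
}

# greedy refractory suppression against the running median of the last
# accepted intervals
refractory_filter <- function(times, factor, history = 20L) {
  if (length(times) < 2L) return(times)
  acc <- times[1]
  for (t in times[-1]) {
    iv <- diff(acc)
    if (length(iv) == 0L) {
      acc <- c(acc, t)
      next
    }
    med <- median(tail(iv, history))
    if (t - acc[length(acc)] >= factor * med) acc <- c(acc, t)
  }
  acc
}
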