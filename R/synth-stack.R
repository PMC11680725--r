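#' Simulate a superior-inferior (SI) readout stack
#'
#' Builds the complex k-space SI readouts that a free-running 3D radial
#' acquisition records once per 22-line trajectory segment. In projection
#' space, each (SI position, coil) time series is the linear mixture
#'
#' \deqn{P_{p,c}(t) = B_{p,c} + w^{resp}_{p,c}\, r(t) + w^{card}_{p,c}\, s(t)
#'   + m_{p,c}(j(t)) + \epsilon(t)}
#'
#' with a smooth baseline \eqn{B}, the centred respiratory waveform
#' \eqn{r(t)}, a cardiac waveform \eqn{s(t) = \sin(2\pi\phi(t))} of the
#' ground-truth cardiac phase (rising zero-crossing exactly at each trigger),
#' an additive trajectory modulation keyed to the periodic segment position
#' index \eqn{j(t)} (22 levels, mimicking the angle-dependent signal of the
#' pseudo-periodic spiral phyllotaxis pattern), and white Gaussian noise.
#' The per-source spatial weight maps are smooth bumps along SI (respiration
#' broad, heart localized and overlapping it) with per-coil gain factors, so
#' the sources share spatial support across coils — the regime in which plain
#' PCA tends to return mixed components. The stack's complex readouts are the
#' inverse Fourier transform of the projections, so that
#' [assemble_sg_matrix()] recovers them.
#'
#' @param gt A `physio_ground_truth`.
#' @param n_positions Number of SI positions (>= 8).
#' @param n_coils Number of receiver coils (>= 2).
#' @param noise_sd Gaussian noise SD in projection units (>= 0).
#' @param modulation_amplitude Scale of the 22-level trajectory modulation.
#' @param resp_amplitude,cardiac_amplitude Source amplitudes in projection
#'   units (defaults 6 and 2 against a baseline of ~10: near the diaphragm
#'   the projection swings between lung and liver intensity, so the
#'   respiratory excursion is comparable to the baseline, and the cardiac
#'   signal is several times smaller; respiration dominates SI projections).
#' @param seed Integer seed for weights, modulation levels and noise.
#' @return An object of class `si_stack`: list with complex `readouts`
#'   (time x position x coil), integer `segment_index` (0-based, period 22),
#'   `fs_hz`, `ground_truth`, per-source `weights`
#'   (position x coil matrices), `sources` (the noiseless time series),
#'   `modulation_levels` (22 x n_columns), and `baseline`.
#' @export
simulate_si_stack <- function(gt, n_positions = 16, n_coils = 4,
                              noise_sd = 0.5, modulation_amplitude = 0.3,
                              resp_amplitude = 6, cardiac_amplitude = 2,
                              seed = 1L) {
  if (!inherits(gt, "physio_ground_truth")) {
    abort("`gt` must come from simulate_physio().",
          class = "sgmotion_invalid_parameter")
  }
  if (n_positions < 8) abort("`n_positions` must be >= 8.",
                             class = "sgmotion_invalid_parameter")
  if (n_coils < 2) abort("`n_coils` must be >= 2.",
                         class = "sgmotion_invalid_parameter")
  check_non_negative(noise_sd, "noise_sd")
  check_non_negative(modulation_amplitude, "modulation_amplitude")

  n_t <- length(gt$resp_waveform)
  segment_index <- (seq_len(n_t) - 1L) %% 22L

  resp_src <- gt$resp_waveform - mean(gt$resp_waveform)
  # fundamental plus a weak second harmonic: the systolic upstroke (rising
  # zero crossing, exactly at each trigger) is steeper than the diastolic
  # downslope, as in real cardiac self-gating waveforms
  card_src <- sin(2 * pi * gt$cardiac_phase) +
    0.35 * sin(4 * pi * gt$cardiac_phase)

  pos <- seq_len(n_positions)
  with_seed(seed, {
    # spatial profiles: broad respiratory bump, narrower cardiac bump
    # overlapping it; distinct per-coil gains
    w_resp_pos <- exp(-(pos - 0.55 * n_positions)^2 / (2 * (0.35 * n_positions)^2))
    w_card_pos <- exp(-(pos - 0.45 * n_positions)^2 / (2 * (0.15 * n_positions)^2))
    g_resp <- runif(n_coils, 0.5, 1.5)
    g_card <- runif(n_coils, 0.5, 1.5)
    w_resp <- resp_amplitude * outer(w_resp_pos, g_resp)
    w_card <- cardiac_amplitude * outer(w_card_pos, g_card)

    baseline_pos <- 10 + 2 * exp(-(pos - 0.5 * n_positions)^2 /
                                   (2 * (0.4 * n_positions)^2))
    baseline <- outer(baseline_pos, runif(n_coils, 0.8, 1.2))

    n_col <- n_positions * n_coils
    mod_levels <- matrix(rnorm(22L * n_col, 0, 1) * modulation_amplitude,
                         nrow = 22L)

    # projection-space signal, time x position x coil
    proj <- array(0, dim = c(n_t, n_positions, n_coils))
    for (c in seq_len(n_coils)) {
      proj[, , c] <- outer(resp_src, w_resp[, c]) +
        outer(card_src, w_card[, c]) +
        matrix(baseline[, c], n_t, n_positions, byrow = TRUE)
      col0 <- (c - 1L) * n_positions
      proj[, , c] <- proj[, , c] +
        mod_levels[segment_index + 1L, col0 + seq_len(n_positions)]
    }
    if (noise_sd > 0) {
      proj <- proj + array(rnorm(length(proj), 0, noise_sd), dim = dim(proj))
    }

    # back to k-space readouts: inverse FFT of the de-centred projections
    readouts <- array(complex(real = 0), dim = dim(proj))
    for (c in seq_len(n_coils)) {
      shifted <- t(apply(proj[, , c], 1L, ifftshift))
      readouts[, , c] <- t(apply(shifted, 1L, function(v)
        fft(v, inverse = TRUE) / length(v)))
    }

    structure(
      list(readouts = readouts,
           segment_index = segment_index,
           fs_hz = gt$fs_hz,
           ground_truth = gt,
           weights = list(resp = w_resp, cardiac = w_card),
           sources = list(resp = resp_src, cardiac = card_src),
           modulation_levels = mod_levels,
           baseline = baseline,
           params = list(n_positions = n_positions, n_coils = n_coils,
                         noise_sd = noise_sd,
                         modulation_amplitude = modulation_amplitude,
                         resp_amplitude = resp_amplitude,
                         cardiac_amplitude = cardiac_amplitude,
                         seed = seed)),
      class = "si_stack"
    )
  })
}

# inverse of fftshift (distinct for odd lengths)
ifftshift <- function(x) {
  n <- length(x)
  idx <- c(seq(n - floor(n / 2) + 1L, n), seq_len(n - floor(n / 2)))
  x[idx]
}

#' @export
print.si_stack <- function(x, ...) {
  d <- dim(x$readouts)
  cat("<si_stack>\n")
  cat(sprintf("  %d readouts x %d SI positions x %d coils at fs %.3f Hz\n",
              d[1], d[2], d[3], x$fs_hz))
  cat(sprintf("  noise_sd %g, modulation %g\n",
              x$params$noise_sd, x$params$modulation_amplitude))
  invisible(x)
}

#' Save / load an SI stack
#'
#' Serializes the stack (complex readout array, segment index, sampling rate
#' and ground truth) to a single-file container and reads it back.
#'
#' @param stack An `si_stack`.
#' @param path File path (conventionally `.rds`).
#' @return `save_si_stack` returns `path` invisibly; `load_si_stack` the
#'   restored `si_stack`.
#' @export
save_si_stack <- function(stack, path) {
  stopifnot(inherits(stack, "si_stack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname save_si_stack
#' @export
load_si_stack <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "si_stack"))
  x
}
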