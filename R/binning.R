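#' Respiratory amplitude binning into equally populated phases
#'
#' Divides the conditioned respiratory signal into `n_phases` equally
#' populated amplitude bins from end-expiration (bin 0, lowest amplitudes)
#' to end-inspiration. Equal population to within one readout is guaranteed
#' by rank-based assignment; values tied at a threshold are assigned in
#' occurrence order so that, where distinct thresholds exist, a value equal
#' to a threshold falls in the lower bin.
#'
#' @param resp Conditioned respiratory value per readout.
#' @param n_phases Number of respiratory phases (default 4).
#' @return Tibble with `readout_index`, `resp_value`, `resp_bin` (0-based).
#' @export
bin_respiratory <- function(resp, n_phases = 4) {
  if (n_phases < 2) abort("`n_phases` must be >= 2.",
                          class = "sgmotion_invalid_parameter")
  n <- length(resp)
  if (diff(range(resp)) == 0) {
    abort("constant respiratory signal: no amplitude range to bin.",
          class = "sgmotion_invalid_parameter")
  }
  r <- rank(resp, ties.method = "first")
  bin <- as.integer(floor((r - 1) * n_phases / n))
  tibble(readout_index = seq_len(n), resp_value = resp, resp_bin = bin)
}

#' Cardiac phase binning from trigger intervals
#'
#' The average cardiac interval is divided by the desired bin width
#' (rounding half away from zero, floor 1) to give the number of bins per
#' cardiac cycle; each trigger-to-trigger interval is then divided into
#' that number of phase bins, so every bin spans interval/n_bins of its own
#' cycle regardless of the cycle's length. Readouts before the first or
#' after the last trigger are rejected. For a mean interval of 1000 ms and
#' the standard 50 ms width this yields 20 bins.
#'
#' @param t A `trigger_train`.
#' @param readout_times_ms Acquisition time of each readout in ms.
#' @param width_ms Desired cardiac bin width in ms (default 50).
#' @return Tibble with `readout_index`, `time_ms`, `card_bin` (0-based, NA
#'   when rejected), `status` (`"ok"` or `"rejected"`); attribute `n_bins`.
#' @export
bin_cardiac <- function(t, readout_times_ms, width_ms = 50) {
  check_positive(width_ms, "width_ms")
  t <- as_trigger_train(t)
  if (nrow(t) < 2L) abort("need at least 2 triggers.",
                          class = "sgmotion_invalid_parameter")
  times <- t$time_ms
  n_bins <- max(1L, as.integer(round_half_away(mean(diff(times)) / width_ms)))

  idx <- findInterval(readout_times_ms, times)
  inside <- idx >= 1L & readout_times_ms < times[length(times)]
  phase <- rep(NA_real_, length(readout_times_ms))
  phase[inside] <- (readout_times_ms[inside] - times[idx[inside]]) /
    (times[idx[inside] + 1L] - times[idx[inside]])
  bin <- ifelse(inside, pmin(floor(n_bins * phase), n_bins - 1L), NA_integer_)
  out <- tibble(readout_index = seq_along(readout_times_ms),
                time_ms = readout_times_ms,
                card_bin = as.integer(bin),
                status = ifelse(inside, "ok", "rejected"))
  attr(out, "n_bins") <- n_bins
  attr(out, "width_ms") <- width_ms
  out
}

#' Combine respiratory and cardiac bin assignments
#'
#' @param resp_bins Output of [bin_respiratory()].
#' @param card_bins Output of [bin_cardiac()] over the same readouts.
#' @return Tibble of class `bin_assignment` with `readout_index`, `time_ms`,
#'   `resp_bin`, `card_bin`, `status`; attributes `n_cardiac_bins`,
#'   `width_ms`.
#' @export
bin_assignment <- function(resp_bins, card_bins) {
  if (nrow(resp_bins) != nrow(card_bins)) {
    abort("assignments cover different numbers of readouts.",
          class = "sgmotion_invalid_parameter")
  }
  out <- tibble(readout_index = card_bins$readout_index,
                time_ms = card_bins$time_ms,
                resp_bin = resp_bins$resp_bin,
                card_bin = card_bins$card_bin,
                status = card_bins$status)
  attr(out, "n_cardiac_bins") <- attr(card_bins, "n_bins")
  attr(out, "width_ms") <- attr(card_bins, "width_ms")
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Write a bin assignment as CSV
#'
#' Columns: `readout_index`, `time_ms`, `resp_bin`, `card_bin`, `status`.
#'
#' @param a A `bin_assignment` (or compatible tibble).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bin_csv <- function(a, path) {
  write.csv(as.data.frame(a), path, row.names = FALSE)
  invisible(path)
}
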