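#' Simulate a defective ECG trigger recording
#'
#' Starts from the ground-truth trigger train and injects the defects that the
#' ECG cleaning stage must detect: independent trigger deletions (missed
#' R-waves), spurious insertions at random mid-interval positions
#' (extrasystolic/false triggers), and Gaussian timing jitter. The defect
#' bookkeeping is attached so tests can verify detection against truth.
#'
#' @param gt A `physio_ground_truth` from [simulate_physio()].
#' @param missing_rate Per-trigger deletion probability in \[0, 0.2\].
#' @param extrasystole_rate Per-interval insertion probability in \[0, 0.2\].
#' @param jitter_sd_ms SD of Gaussian timing jitter in ms (>= 0).
#' @param seed Integer seed.
#' @return A `trigger_train` with `source = "ECG"`. Attributes:
#'   `deleted_times_ms`, `inserted_times_ms`, `n_deleted`, `n_inserted`.
#' @export
simulate_ecg_train <- function(gt, missing_rate = 0, extrasystole_rate = 0,
                               jitter_sd_ms = 0, seed = 1L) {
  check_in_range(missing_rate, "missing_rate", 0, 0.2)
  check_in_range(extrasystole_rate, "extrasystole_rate", 0, 0.2)
  check_non_negative(jitter_sd_ms, "jitter_sd_ms")
  times <- if (inherits(gt, "physio_ground_truth")) gt$trigger_times_ms else
    as_trigger_train(gt)$time_ms
  n <- length(times)

  with_seed(seed, {
    # deletions: first and last kept so the train still spans the recording
    del <- runif(n) < missing_rate
    del[c(1L, n)] <- FALSE
    kept <- times[!del]

    # insertions at random positions inside surviving intervals
    nk <- length(kept)
    ins_draw <- runif(nk - 1L) < extrasystole_rate
    ins_times <- kept[-nk][ins_draw] +
      runif(sum(ins_draw), 0.2, 0.8) * diff(kept)[ins_draw]

    out_times <- c(kept, ins_times)
    inserted <- c(rep(FALSE, nk), rep(TRUE, length(ins_times)))
    ord <- order(out_times)
    out_times <- out_times[ord]
    inserted <- inserted[ord]

    if (jitter_sd_ms > 0) {
      out_times <- out_times + rnorm(length(out_times), 0, jitter_sd_ms)
      ord2 <- order(out_times)
      out_times <- out_times[ord2]
      inserted <- inserted[ord2]
    }
    # guard against (astronomically unlikely) ties after jitter
    while (any(diff(out_times) <= 0)) {
      out_times[c(FALSE, diff(out_times) <= 0)] <-
        out_times[c(FALSE, diff(out_times) <= 0)] + 1e-6
      ord2 <- order(out_times)
      out_times <- out_times[ord2]
      inserted <- inserted[ord2]
    }

    out <- trigger_train(out_times, source = "ECG")
    attr(out, "deleted_times_ms") <- times[del]
    attr(out, "inserted_times_ms") <- sort(ins_times)
    attr(out, "n_deleted") <- sum(del)
    attr(out, "n_inserted") <- length(ins_times)
    attr(out, "truth_inserted") <- inserted
    out
  })
}
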