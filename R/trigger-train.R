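#' Construct a trigger train
#'
#' A trigger train is a tibble of strictly increasing event times in
#' milliseconds with a per-trigger validity flag and a source label
#' (`"ECG"`, `"SG-PCA"`, `"SG-SOBI"`, `"SG-ICA"`, `"ground-truth"`, ...).
#'
#' @param times_ms Numeric vector of strictly increasing times in ms.
#' @param source Single source label.
#' @param flag Per-trigger flag, recycled; one of `"valid"`,
#'   `"missing-adjacent"`, `"extrasystolic"`.
#' @return A tibble of class `trigger_train` with columns `time_ms`,
#'   `source`, `flag`.
#' @export
trigger_train <- function(times_ms, source = "unknown", flag = "valid") {
  if (length(times_ms) == 0L) {
    abort("a trigger train needs at least one trigger.",
          class = "sgmotion_invalid_parameter")
  }
  if (any(!is.finite(times_ms))) {
    abort("trigger times must be finite.", class = "sgmotion_invalid_parameter")
  }
  if (any(diff(times_ms) <= 0)) {
    abort("trigger times must be strictly increasing.",
          class = "sgmotion_invalid_parameter")
  }
  flag <- rep_len(flag, length(times_ms))
  out <- tibble(time_ms = as.numeric(times_ms),
                source = as.character(source),
                flag = flag)
  class(out) <- c("trigger_train", class(out))
  out
}

is_trigger_train <- function(x) inherits(x, "trigger_train")

as_trigger_train <- function(x, source = "unknown") {
  if (is_trigger_train(x)) return(x)
  if (is.numeric(x)) return(trigger_train(x, source = source))
  if (is.data.frame(x) && "time_ms" %in% names(x)) {
    return(trigger_train(x$time_ms,
                         source = if ("source" %in% names(x)) x$source[1] else source,
                         flag = if ("flag" %in% names(x)) x$flag else "valid"))
  }
  abort("cannot interpret input as a trigger train.",
        class = "sgmotion_invalid_parameter")
}

#' Trigger-to-trigger intervals of a train
#'
#' @param t A `trigger_train` (or numeric vector of times in ms).
#' @param valid_only Drop intervals adjacent to a flagged trigger.
#' @return Tibble with columns `interval_index`, `start_ms`, `end_ms`,
#'   `length_ms`, `flag`.
#' @export
trigger_intervals <- function(t, valid_only = FALSE) {
  t <- as_trigger_train(t)
  n <- nrow(t)
  if (n < 2L) {
    abort("need at least 2 triggers to form intervals.",
          class = "sgmotion_invalid_parameter")
  }
  iflag <- attr(t, "interval_flags") %||% rep("valid", n - 1L)
  out <- tibble(interval_index = seq_len(n - 1L),
                start_ms = t$time_ms[-n],
                end_ms = t$time_ms[-1],
                length_ms = diff(t$time_ms),
                flag = iflag)
  if (valid_only) out <- out[out$flag == "valid", , drop = FALSE]
  out
}

#' Write / read a trigger train as CSV
#'
#' The on-disk format has columns `time_ms`, `source`, `flag`.
#'
#' @param t A `trigger_train`.
#' @param path File path.
#' @return `write_trigger_csv` returns `path` invisibly; `read_trigger_csv`
#'   returns a `trigger_train`.
#' @export
write_trigger_csv <- function(t, path) {
  t <- as_trigger_train(t)
  write.csv(as.data.frame(t[, c("time_ms", "source", "flag")]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trigger_csv
#' @export
read_trigger_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  trigger_train(df$time_ms, source = df$source[1], flag = df$flag)
}
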