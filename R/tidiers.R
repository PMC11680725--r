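# broom-style tidiers for the package's fitted objects.

#' Tidy a trigger comparison
#'
#' @param x A `trigger_comparison` from [compute_isd()].
#' @param ... Unused.
#' @return The paired-interval tibble (`ecg_interval_index`,
#'   `sg_interval_ms`, `ecg_interval_ms`, `abs_diff_ms`).
#' @method tidy trigger_comparison
#' @export
tidy.trigger_comparison <- function(x, ...) x$pairs

#' @rdname tidy.trigger_comparison
#' @return `glance()`: one-row tibble with `sg_source`, `ecg_source`, `n`,
#'   `mu_ms`, `isd_ms`, `offset_ms`.
#' @method glance trigger_comparison
#' @export
glance.trigger_comparison <- function(x, ...) {
  tibble(sg_source = x$sg_source, ecg_source = x$ecg_source,
         n = x$n, mu_ms = x$mu_ms, isd_ms = x$isd_ms,
         offset_ms = x$offset_ms %||% NA_real_)
}

#' Tidy a sigmoid edge fit
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`a0`, `a1`, `a2`, `s`).
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("a0", "a1", "a2", "s"),
         estimate = c(x$a0, x$a1, x$a2, x$s))
}

#' @rdname tidy.sigmoid_fit
#' @return `glance()`: one-row tibble with the parameters, RMS residual
#'   and convergence flag.
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(a0 = x$a0, a1 = x$a1, a2 = x$a2, s = x$s,
         residual = x$residual, converged = x$converged,
         n = nrow(x$data))
}

#' @rdname tidy.sigmoid_fit
#' @param data Ignored; the fit stores its own profile.
#' @return `augment()`: the profile with `.fitted` and `.resid` columns.
#' @method augment sigmoid_fit
#' @export
augment.sigmoid_fit <- function(x, data = NULL, ...) {
  fitted <- sigmoid_edge(x$data$offset_px, x$a0, x$a1, x$a2, x$s)
  dplyr::mutate(x$data, .fitted = fitted, .resid = intensity - fitted)
}

#' Tidy a source set
#'
#' @param x A `source_set`.
#' @param ... Unused.
#' @return Long tibble with `time_s`, `component`, `value`.
#' @method tidy source_set
#' @export
tidy.source_set <- function(x, ...) {
  n <- nrow(x$sources); k <- ncol(x$sources)
  tibble(time_s = rep((seq_len(n) - 1) / x$fs_hz, k),
         component = rep(seq_len(k), each = n),
         value = as.vector(x$sources))
}

#' @rdname tidy.source_set
#' @return `glance()`: one-row tibble with `method`, `n_sources`,
#'   `n_time`, `explained_variance` (sum, PCA only), `converged`.
#' @method glance source_set
#' @export
glance.source_set <- function(x, ...) {
  tibble(method = x$method, n_sources = ncol(x$sources),
         n_time = nrow(x$sources),
         explained_variance = if (is.null(x$explained_variance)) NA_real_
                              else sum(x$explained_variance),
         converged = isTRUE(x$converged))
}
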