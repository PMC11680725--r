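# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline facet_wrap
#'   labs geom_vline theme_minimal geom_col
NULL

#' Plot estimated source time series
#'
#' @param object A `source_set`.
#' @param max_seconds Show at most this many seconds (default 60).
#' @param ... Unused.
#' @return A ggplot with one facet per component.
#' @method autoplot source_set
#' @export
autoplot.source_set <- function(object, max_seconds = 60, ...) {
  df <- tidy.source_set(object)
  df <- df[df$time_s <= max_seconds, ]
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~component, ncol = 1, strip.position = "right") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("%s sources", object$method)) +
    theme_minimal()
}

#' Power spectral densities of all components with selection bands
#'
#' @param ss A `source_set`.
#' @param bands Named list of frequency bands (Hz) drawn as vertical lines.
#' @param segment_seconds Welch segment length.
#' @return A ggplot faceted by component.
#' @export
plot_component_psd <- function(ss,
                               bands = list(respiratory = c(0.1, 0.7),
                                            cardiac = c(0.5, 2.0)),
                               segment_seconds = 30) {
  k <- ncol(ss$sources)
  df <- dplyr::bind_rows(lapply(seq_len(k), function(j) {
    x <- ss$sources[, j]
    dplyr::mutate(estimate_psd(x / sd(x), ss$fs_hz, segment_seconds),
                  component = j)
  }))
  p <- ggplot(df, aes(x = .data$freq_hz, y = .data$power)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "frequency (Hz)", y = "PSD",
         title = sprintf("%s component spectra", ss$method)) +
    theme_minimal()
  for (b in bands) {
    p <- p + geom_vline(xintercept = b, linetype = "dashed",
                        colour = "steelblue", linewidth = 0.3)
  }
  p
}

#' Bland-Altman plot of a trigger comparison
#'
#' @param object A `trigger_comparison`.
#' @param ... Unused.
#' @return A ggplot of interval differences against interval means with
#'   the mean difference and 95% limits of agreement.
#' @method autoplot trigger_comparison
#' @export
autoplot.trigger_comparison <- function(object, ...) {
  p <- object$pairs
  d <- p$sg_interval_ms - p$ecg_interval_ms
  m <- (p$sg_interval_ms + p$ecg_interval_ms) / 2
  md <- mean(d); sdd <- sd(d)
  ggplot(tibble(mean_ms = m, diff_ms = d),
         aes(x = .data$mean_ms, y = .data$diff_ms)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = md) +
    geom_hline(yintercept = md + c(-1.96, 1.96) * sdd, linetype = "dashed") +
    labs(x = "mean interval (ms)", y = "SG - ECG interval (ms)",
         title = sprintf("%s vs %s (ISD %.1f ms)",
                         object$sg_source, object$ecg_source, object$isd_ms)) +
    theme_minimal()
}

#' Profile and fitted sigmoid of an edge measurement
#'
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @return A ggplot of the sampled profile with the fitted edge model.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  aug <- augment.sigmoid_fit(object)
  ggplot(aug, aes(x = .data$offset_px)) +
    geom_point(aes(y = .data$intensity), size = 0.8, alpha = 0.6) +
    geom_line(aes(y = .data$.fitted), colour = "forestgreen") +
    labs(x = "profile coordinate (px)", y = "intensity",
         title = sprintf("sigmoid edge fit (s = %.3f)", object$s)) +
    theme_minimal()
}

#' ISD summary plot for a method comparison
#'
#' @param per_subject The `per_subject` tibble from [compare_methods()].
#' @return A ggplot of per-subject ISD by method.
#' @export
plot_isd_comparison <- function(per_subject) {
  ggplot(per_subject,
         aes(x = .data$method, y = .data$isd_ms, group = .data$subject)) +
    geom_line(alpha = 0.3) +
    geom_point() +
    labs(x = NULL, y = "ISD (ms)", title = "Trigger precision by method") +
    theme_minimal()
}

#' Image preview of a reconstruction result
#'
#' @param object A `recon_result`.
#' @param resp_bin,card_bin 1-based bin indices to display (defaults: first
#'   respiratory bin, all cardiac bins as facets).
#' @param ... Unused.
#' @return A ggplot raster of the magnitude image(s).
#' @method autoplot recon_result
#' @export
autoplot.recon_result <- function(object, resp_bin = 1, card_bin = NULL, ...) {
  cbs <- card_bin %||% seq_len(object$n_card)
  df <- dplyr::bind_rows(lapply(cbs, function(cb) {
    img <- Mod(object$images[, , cb, resp_bin])
    tibble(x = rep(seq_len(object$nx), times = object$nx),
           y = rep(seq_len(object$nx), each = object$nx),
           intensity = as.vector(img),
           cardiac_bin = cb)
  }))
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    facet_wrap(~cardiac_bin) +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    labs(x = NULL, y = NULL, fill = NULL,
         title = "Motion-resolved reconstruction (magnitude)") +
    theme_minimal()
}
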