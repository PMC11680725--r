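#' Configuration for an end-to-end extraction run
#'
#' Flat list of the simulation and analysis parameters, with physical units
#' in the key names. Defaults reproduce the standard study conditions of
#' the synthetic module: 5 minutes at one SI readout per 22-line segment.
#'
#' @param duration_s,fs_hz,hr_mean_bpm,hr_sd_bpm,resp_freq_hz,rsa_gain_bpm
#'   Physiology simulation parameters, see [simulate_physio()].
#' @param n_positions,n_coils,noise_sd,modulation_amplitude SI stack
#'   parameters, see [simulate_si_stack()].
#' @param ecg_missing_rate,ecg_extrasystole_rate,ecg_jitter_sd_ms ECG
#'   defect parameters, see [simulate_ecg_train()].
#' @param methods Subset of `c("PCA", "SOBI", "ICA")`.
#' @param n_components Dimensionality kept by [pca_reduce()].
#' @param resp_band_hz,cardiac_band_hz Physiological selection bands.
#' @param bin_width_ms Cardiac bin width, [bin_cardiac()].
#' @param n_resp_phases Respiratory phases, [bin_respiratory()].
#' @param seed Master seed of the run.
#' @return A named list of class `sg_config`.
#' @export
sg_config <- function(duration_s = 300, fs_hz = 1 / (22 * 2.84e-3),
                      hr_mean_bpm = 60, hr_sd_bpm = 2, resp_freq_hz = 0.25,
                      rsa_gain_bpm = 0,
                      n_positions = 16, n_coils = 4, noise_sd = 0.5,
                      modulation_amplitude = 0.3,
                      ecg_missing_rate = 0.02, ecg_extrasystole_rate = 0.01,
                      ecg_jitter_sd_ms = 2,
                      methods = c("PCA", "SOBI"), n_components = 10,
                      resp_band_hz = c(0.1, 0.7),
                      cardiac_band_hz = c(0.5, 2.0),
                      bin_width_ms = 50, n_resp_phases = 4, seed = 1L) {
  methods <- match.arg(methods, c("PCA", "SOBI", "ICA"), several.ok = TRUE)
  cfg <- as.list(environment())
  if (any(c(resp_band_hz, cardiac_band_hz) <= 0) ||
      any(c(resp_band_hz, cardiac_band_hz) >= fs_hz / 2)) {
    abort("selection bands must lie inside (0, fs/2).",
          class = "sgmotion_invalid_parameter")
  }
  structure(cfg, class = "sg_config")
}

#' Run the full motion-extraction pipeline on one simulated subject
#'
#' Simulates the subject (physiology, SI stack, defective ECG), assembles
#' and corrects the self-gating matrix, reduces it with PCA, applies each
#' requested separation method, selects the respiratory component first
#' (and removes it from the cardiac candidate pool), conditions the
#' respiratory signal, detects cardiac triggers, cleans and aligns against
#' the ECG, and computes the interval-SD precision of every method plus the
#' respiratory binning of the readouts. Every defaulted design choice that
#' fires (selection fallback, polarity choice, window shrink) is appended
#' to the structured log.
#'
#' @param config An `sg_config`.
#' @return Object of class `sg_report`: `config`, `isd` (tibble: method,
#'   n, mu_ms, isd_ms, offset_ms), `methods` (per-method details incl. the
#'   trigger train and `trigger_comparison`), `ecg` (cleaned train),
#'   `resp_signal`, `rsa` (per-method [rsa_split()] rows), `binning`
#'   (a `bin_assignment` from the lowest-ISD method), `ground_truth`, and
#'   `log` (character).
#' @export
run_extraction <- function(config = sg_config()) {
  stopifnot(inherits(config, "sg_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  gt <- simulate_physio(hr_mean_bpm = config$hr_mean_bpm,
                        hr_sd_bpm = config$hr_sd_bpm,
                        resp_freq_hz = config$resp_freq_hz,
                        rsa_gain_bpm = config$rsa_gain_bpm,
                        duration_s = config$duration_s,
                        fs_hz = config$fs_hz, seed = config$seed)
  stack <- simulate_si_stack(gt, n_positions = config$n_positions,
                             n_coils = config$n_coils,
                             noise_sd = config$noise_sd,
                             modulation_amplitude = config$modulation_amplitude,
                             seed = config$seed + 1L)
  ecg_raw <- simulate_ecg_train(gt, missing_rate = config$ecg_missing_rate,
                                extrasystole_rate = config$ecg_extrasystole_rate,
                                jitter_sd_ms = config$ecg_jitter_sd_ms,
                                seed = config$seed + 2L)
  ecg <- clean_ecg(ecg_raw)
  note("clean_ecg: moving-median window 40, thresholds 1.5x/0.5x")

  m <- assemble_sg_matrix(stack)
  m <- correct_angular_dependence(m)
  note("angular correction: per-(column, segment-position) mean subtraction")
  pca <- pca_reduce(m, n_components = config$n_components, standardize = TRUE)
  note("pca_reduce: %d components, columns standardized", config$n_components)

  seg_len <- min(30, config$duration_s / 4)
  select_with_fallback <- function(ss, band, exclude = integer(), label) {
    tryCatch(
      select_component(ss, band, segment_seconds = seg_len, exclude = exclude),
      sgmotion_no_candidate = function(e) {
        note("%s selection: no in-band Gaussian peak; fell back to in-band power argmax",
             label)
        pw <- vapply(seq_len(ncol(ss$sources)), function(j) {
          if (j %in% exclude) return(-Inf)
          psd <- estimate_psd(ss$sources[, j] / sd(ss$sources[, j]),
                              ss$fs_hz, seg_len)
          sum(psd$power[psd$freq_hz >= band[1] & psd$freq_hz <= band[2]])
        }, numeric(1))
        list(index = which.max(pw), fit = NULL, candidates = NULL)
      })
  }

  method_results <- list()
  for (method in config$methods) {
    ss <- switch(method,
                 PCA = pca,
                 SOBI = sobi(pca),
                 ICA = fastica(pca, seed = config$seed + 3L))
    if (!isTRUE(ss$converged)) note("%s: iteration did not converge; best iterate used", method)

    resp_sel <- select_with_fallback(ss, config$resp_band_hz, label = paste(method, "respiratory"))
    resp_sig <- condition_respiratory(ss$sources[, resp_sel$index], ss$fs_hz)
    card_sel <- select_with_fallback(ss, config$cardiac_band_hz,
                                     exclude = resp_sel$index,
                                     label = paste(method, "cardiac"))
    note("%s: respiratory component %d excluded from cardiac candidacy (cardiac -> %d)",
         method, resp_sel$index, card_sel$index)

    sg_train <- detect_triggers(ss$sources[, card_sel$index], ss$fs_hz,
                                band_hz = config$cardiac_band_hz,
                                source = paste0("SG-", method))
    note("%s: zero-crossing polarity '%s'", method, attr(sg_train, "polarity"))
    al <- align_triggers(sg_train, ecg)
    cmp <- compute_isd(al$train, ecg)
    cmp$offset_ms <- al$offset_ms
    rsa <- tryCatch(rsa_split(al$train, resp_sig, ss$fs_hz),
                    error = function(e) NULL)

    method_results[[method]] <- list(
      source_set = ss, resp_index = resp_sel$index,
      cardiac_index = card_sel$index, resp_signal = resp_sig,
      triggers = al$train, offset_ms = al$offset_ms,
      comparison = cmp, rsa = rsa)
  }

  isd_tbl <- dplyr::bind_rows(lapply(names(method_results), function(nm) {
    cmp <- method_results[[nm]]$comparison
    tibble(method = nm, n = cmp$n, mu_ms = cmp$mu_ms, isd_ms = cmp$isd_ms,
           offset_ms = method_results[[nm]]$offset_ms)
  }))
  rsa_tbl <- dplyr::bind_rows(lapply(names(method_results), function(nm) {
    r <- method_results[[nm]]$rsa
    if (is.null(r)) return(NULL)
    dplyr::mutate(r, method = nm, .before = 1)
  }))

  # bin the readouts with the most precise method's triggers
  best <- isd_tbl$method[which.min(isd_tbl$isd_ms)]
  note("binning uses '%s' triggers (lowest ISD)", best)
  read_t <- gt$time_s * 1000
  rb <- bin_respiratory(method_results[[best]]$resp_signal,
                        n_phases = config$n_resp_phases)
  cb <- bin_cardiac(method_results[[best]]$triggers, read_t,
                    width_ms = config$bin_width_ms)
  binning <- bin_assignment(rb, cb)
  note("cardiac binning: %d bins of ~%g ms; readouts outside the trigger span rejected",
       attr(binning, "n_cardiac_bins"), config$bin_width_ms)

  structure(list(config = config, isd = isd_tbl, methods = method_results,
                 ecg = ecg, rsa = rsa_tbl, binning = binning,
                 ground_truth = gt, best_method = best, log = log),
            class = "sg_report")
}

#' @export
print.sg_report <- function(x, ...) {
  cat("<sg_report>\n")
  print(x$isd)
  invisible(x)
}

#' Compare motion-extraction methods across subjects
#'
#' Pools the paired SG-ECG interval differences of each method across
#' subjects (pairing across methods through the shared ECG intervals), and
#' reports per-method Bland-Altman and regression agreement plus pairwise
#' one-sided Bonett-Seier dispersion tests (alternative: the first method
#' of the pair is less dispersed, i.e. more precise). With a single report
#' the pairwise tests are skipped with a warning and descriptive rows are
#' still returned.
#'
#' @param reports List of `sg_report`s (one per subject).
#' @return List with `per_subject` (method x subject ISD tibble),
#'   `agreement` (per-method pooled Bland-Altman/regression tibble), and
#'   `pairwise` (Bonett-Seier tibble, or NULL for a single subject).
#' @export
compare_methods <- function(reports) {
  if (inherits(reports, "sg_report")) reports <- list(reports)
  methods <- names(reports[[1]]$methods)
  for (r in reports) {
    if (!identical(names(r$methods), methods)) {
      abort("all reports must contain the same method set.",
            class = "sgmotion_invalid_parameter")
    }
  }
  per_subject <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(reports[[i]]$isd, subject = i, .before = 1)
  }))

  # pooled per-interval signed differences, keyed by subject and ECG interval
  pooled <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::bind_rows(lapply(methods, function(nm) {
      p <- reports[[i]]$methods[[nm]]$comparison$pairs
      tibble(subject = i, method = nm,
             ecg_interval_index = p$ecg_interval_index,
             sg_interval_ms = p$sg_interval_ms,
             ecg_interval_ms = p$ecg_interval_ms,
             diff_ms = p$sg_interval_ms - p$ecg_interval_ms)
    }))
  }))

  agreement <- pooled |>
    dplyr::group_by(.data$method) |>
    dplyr::group_map(function(df, key) {
      dplyr::mutate(bland_altman(df$sg_interval_ms, df$ecg_interval_ms),
                    method = key$method, .before = 1)
    }) |>
    dplyr::bind_rows()

  pairwise <- NULL
  if (length(reports) < 2L) {
    warn("single subject: pairwise Bonett-Seier tests skipped.")
  } else if (length(methods) >= 2L) {
    combos <- utils::combn(methods, 2, simplify = FALSE)
    pairwise <- dplyr::bind_rows(lapply(combos, function(pr) {
      a <- pooled[pooled$method == pr[1],
                  c("subject", "ecg_interval_index", "diff_ms")]
      b <- pooled[pooled$method == pr[2],
                  c("subject", "ecg_interval_index", "diff_ms")]
      j <- dplyr::inner_join(a, b, by = c("subject", "ecg_interval_index"),
                             suffix = c("_1", "_2"))
      bs <- bonett_seier_paired(j$diff_ms_1, j$diff_ms_2, "less")
      dplyr::mutate(bs, method_1 = pr[1], method_2 = pr[2], .before = 1)
    }))
  }
  list(per_subject = per_subject, agreement = agreement, pairwise = pairwise)
}

#' Write a pipeline report to disk
#'
#' Emits one trigger CSV per method, the ISD comparison CSV, the bin
#' assignment CSV, and a machine-readable JSON summary.
#'
#' @param report An `sg_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sg_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$methods)) {
    write_trigger_csv(report$methods[[nm]]$triggers,
                      file.path(dir, sprintf("triggers_%s.csv", nm)))
  }
  write_trigger_csv(report$ecg, file.path(dir, "triggers_ECG.csv"))
  write.csv(as.data.frame(report$isd), file.path(dir, "isd.csv"),
            row.names = FALSE)
  write_bin_csv(report$binning, file.path(dir, "bin_assignment.csv"))
  summ <- list(
    seed = report$config$seed,
    best_method = report$best_method,
    isd = report$isd,
    rsa = report$rsa,
    n_cardiac_bins = attr(report$binning, "n_cardiac_bins"),
    log = report$log)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
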