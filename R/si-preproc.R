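#' Assemble the 2D self-gating matrix from an SI readout stack
#'
#' For every readout and coil, the 1D discrete Fourier transform along the
#' readout dimension is computed (DC centred), its magnitude taken, and the
#' per-coil position profiles concatenated column-wise. Row order preserves
#' acquisition time, so each column is the time series of one
#' (SI position, coil) pair.
#'
#' @param stack An `si_stack`.
#' @return Object of class `sg_matrix`: list with real `values`
#'   (time x n_positions*n_coils), `fs_hz`, `segment_index` per row, and
#'   `col_meta` tibble (`column`, `position`, `coil`).
#' @export
assemble_sg_matrix <- function(stack) {
  if (!inherits(stack, "si_stack")) {
    abort("`stack` must be an si_stack.", class = "sgmotion_invalid_parameter")
  }
  d <- dim(stack$readouts)
  if (any(d == 0)) abort("empty stack.", class = "sgmotion_invalid_parameter")
  n_t <- d[1]; n_pos <- d[2]; n_coil <- d[3]

  values <- matrix(0, n_t, n_pos * n_coil)
  for (c in seq_len(n_coil)) {
    ft <- t(apply(stack$readouts[, , c], 1L, function(v) fftshift(fft(v))))
    values[, (c - 1L) * n_pos + seq_len(n_pos)] <- Mod(ft)
  }
  col_meta <- tibble(column = seq_len(n_pos * n_coil),
                     position = rep(seq_len(n_pos), n_coil),
                     coil = rep(seq_len(n_coil), each = n_pos))
  structure(list(values = values, fs_hz = stack$fs_hz,
                 segment_index = stack$segment_index, col_meta = col_meta,
                 corrected = FALSE),
            class = "sg_matrix")
}

#' Remove trajectory-angle-dependent modulation from a self-gating matrix
#'
#' The pseudo-periodic sampling trajectory adds a component to each column
#' that depends only on the position of the readout within the repeating
#' segment pattern. For each column and each segment-position group the
#' group's temporal mean is subtracted, which exactly cancels any purely
#' angle-dependent additive term and leaves physiological variation intact
#' (up to per-group mean removal). The operation is idempotent.
#'
#' @param m An `sg_matrix` with a `segment_index`.
#' @return The corrected `sg_matrix` (`corrected = TRUE`).
#' @export
correct_angular_dependence <- function(m) {
  if (!inherits(m, "sg_matrix")) {
    abort("`m` must be an sg_matrix.", class = "sgmotion_invalid_parameter")
  }
  seg <- m$segment_index
  if (is.null(seg)) {
    abort("segment_position_index is required for angular correction.",
          class = "sgmotion_invalid_parameter")
  }
  groups <- split(seq_along(seg), seg)
  small <- vapply(groups, length, integer(1)) < 2L
  if (any(small)) {
    warn(sprintf("%d segment-position group(s) have < 2 readouts; left unchanged.",
                 sum(small)))
  }
  values <- m$values
  for (g in groups[!small]) {
    mu <- colMeans(values[g, , drop = FALSE])
    values[g, ] <- sweep(values[g, , drop = FALSE], 2L, mu)
  }
  m$values <- values
  m$corrected <- TRUE
  m
}

#' @export
print.sg_matrix <- function(x, ...) {
  cat("<sg_matrix>\n")
  cat(sprintf("  %d time points x %d columns (%d positions x %d coils), fs %.3f Hz\n",
              nrow(x$values), ncol(x$values), max(x$col_meta$position),
              max(x$col_meta$coil), x$fs_hz))
  cat(sprintf("  angular correction applied: %s\n", x$corrected))
  invisible(x)
}

#' Save / load a self-gating matrix
#'
#' @param m An `sg_matrix`.
#' @param path File path (conventionally `.rds`).
#' @return `save_sg_matrix` returns `path` invisibly; `load_sg_matrix`
#'   restores the object.
#' @export
save_sg_matrix <- function(m, path) {
  stopifnot(inherits(m, "sg_matrix"))
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_sg_matrix
#' @export
load_sg_matrix <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "sg_matrix"))
  x
}
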