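#' Define a toy motion-resolved reconstruction problem
#'
#' Collects the per-bin k-space data and trajectories, coil sensitivities
#' and regularization weights for [admm_recon()]. The scale is deliberately
#' small (image <= 64 x 64, at most 4 respiratory x 8 cardiac bins, <= 4
#' coils) so the forward model can be an explicit non-uniform DFT matrix
#' per bin.
#'
#' @param y_bins List indexed `[[resp]][[card]]`, each element a list with
#'   `kx`, `ky` (cycles/pixel) and `y` (complex matrix, samples x coils).
#' @param nx Image size (square).
#' @param coil_sens Complex/numeric array `nx x nx x n_coils`; default a
#'   single uniform coil.
#' @param lambda_r,lambda_c Respiratory/cardiac l1 regularization weights,
#'   interpreted relative to unit-normalized data (the measured k-space is
#'   scaled to unit peak magnitude internally; the image is scaled back).
#' @param iterations ADMM iterations (default 10).
#' @param rho ADMM penalty parameter (default 1).
#' @return Object of class `recon_problem`.
#' @export
recon_problem <- function(y_bins, nx, coil_sens = NULL,
                          lambda_r = 0.001, lambda_c = 0.001,
                          iterations = 10, rho = 1) {
  check_non_negative(lambda_r, "lambda_r")
  check_non_negative(lambda_c, "lambda_c")
  check_positive(rho, "rho")
  if (nx > 64) abort("toy scale: image must be <= 64 x 64.",
                     class = "sgmotion_invalid_parameter")
  n_resp <- length(y_bins)
  n_card <- length(y_bins[[1]])
  if (n_resp > 4 || n_card > 8) {
    abort("toy scale: at most 4 respiratory x 8 cardiac bins.",
          class = "sgmotion_invalid_parameter")
  }
  if (is.null(coil_sens)) coil_sens <- array(1, dim = c(nx, nx, 1L))
  n_coils <- dim(coil_sens)[3]
  if (n_coils > 4) abort("toy scale: at most 4 coils.",
                         class = "sgmotion_invalid_parameter")
  for (r in seq_len(n_resp)) {
    if (length(y_bins[[r]]) != n_card) {
      abort("ragged bin grid.", class = "sgmotion_invalid_parameter")
    }
    for (c in seq_len(n_card)) {
      b <- y_bins[[r]][[c]]
      if (is.null(b) || length(b$kx) == 0L) {
        abort(sprintf("bin (resp %d, cardiac %d) has no k-space samples.", r, c),
              class = "sgmotion_empty_bin")
      }
      if (nrow(as.matrix(b$y)) != length(b$kx)) {
        abort("sample count mismatch between trajectory and data.",
              class = "sgmotion_invalid_parameter")
      }
    }
  }
  structure(list(y_bins = y_bins, nx = nx, coil_sens = coil_sens,
                 lambda_r = lambda_r, lambda_c = lambda_c,
                 iterations = iterations, rho = rho,
                 n_resp = n_resp, n_card = n_card, n_coils = n_coils),
            class = "recon_problem")
}

#' Motion-resolved compressed-sensing reconstruction by ADMM
#'
#' Solves, per respiratory and cardiac bin,
#' \deqn{\hat x = \arg\min_x \|FCx - y\|_2^2
#'   + \lambda_r \|\nabla_r x\|_1 + \lambda_c \|\nabla_c x\|_1}
#' with F the (explicit, toy-scale) non-uniform Fourier operator of each
#' bin's trajectory, C the coil sensitivities, and first-difference
#' operators along the respiratory (non-cyclic) and cardiac (cyclic) bin
#' axes. The two l1 terms are split with scaled-dual ADMM
#' (complex soft-thresholding for the z-updates, conjugate gradients for
#' the quadratic x-update). With both weights zero the solver reduces to
#' plain conjugate-gradient least squares.
#'
#' @param p A `recon_problem`.
#' @param cg_iter Conjugate-gradient iterations per x-update.
#' @return Object of class `recon_result`: `images` (complex array
#'   `nx x nx x n_card x n_resp`), `objective` (tibble per ADMM iteration
#'   with data-fidelity and the two regularizer values), plus problem
#'   metadata.
#' @export
admm_recon <- function(p, cg_iter = 15) {
  stopifnot(inherits(p, "recon_problem"))
  nx <- p$nx; npix <- nx * nx
  n_resp <- p$n_resp; n_card <- p$n_card; n_coils <- p$n_coils
  sens <- matrix(p$coil_sens, npix, n_coils)

  # unit-normalize the measured data; rescale the image at the end
  ymax <- max(vapply(unlist(p$y_bins, recursive = FALSE),
                     function(b) max(Mod(b$y)), numeric(1)))
  if (ymax == 0) ymax <- 1

  A <- vector("list", n_resp * n_card)     # forward matrices per bin
  yb <- vector("list", n_resp * n_card)    # stacked (coil-wise) data
  bid <- function(r, c) (r - 1L) * n_card + c
  for (r in seq_len(n_resp)) for (c in seq_len(n_card)) {
    b <- p$y_bins[[r]][[c]]
    A[[bid(r, c)]] <- nudft_matrix(b$kx, b$ky, nx)
    yb[[bid(r, c)]] <- as.matrix(b$y) / ymax
  }

  # forward/adjoint over the full stack x: [pixel, cardiac, respiratory]
  forward <- function(x) {
    out <- vector("list", n_resp * n_card)
    for (r in seq_len(n_resp)) for (c in seq_len(n_card)) {
      xb <- x[, c, r]
      out[[bid(r, c)]] <- A[[bid(r, c)]] %*% (sens * xb)  # samples x coils
    }
    out
  }
  adjoint <- function(res) {
    x <- array(0+0i, dim = c(npix, n_card, n_resp))
    for (r in seq_len(n_resp)) for (c in seq_len(n_card)) {
      ah <- Conj(t(A[[bid(r, c)]])) %*% res[[bid(r, c)]]
      x[, c, r] <- rowSums(Conj(sens) * ah)
    }
    x
  }
  aty <- adjoint(yb)

  lam_r <- p$lambda_r; lam_c <- p$lambda_c; rho <- p$rho
  use_split <- lam_r > 0 || lam_c > 0

  normal_op <- function(x) {
    ax <- adjoint(forward(x))
    if (use_split) {
      ax <- ax + rho * finite_difference_adjoint(finite_difference(x, "cardiac"),
                                                 "cardiac") +
        rho * finite_difference_adjoint(finite_difference(x, "respiratory"),
                                        "respiratory")
    }
    ax
  }
  cg <- function(b, x0, iters) {
    x <- x0
    rr <- b - normal_op(x)
    pdir <- rr
    rs <- sum(Mod(rr)^2)
    for (i in seq_len(iters)) {
      if (rs < 1e-24) break
      Ap <- normal_op(pdir)
      alpha <- rs / Re(sum(Conj(pdir) * Ap))
      x <- x + alpha * pdir
      rr <- rr - alpha * Ap
      rs_new <- sum(Mod(rr)^2)
      pdir <- rr + (rs_new / rs) * pdir
      rs <- rs_new
    }
    x
  }
  soft <- function(z, thr) {
    mz <- Mod(z)
    sc <- pmax(mz - thr, 0) / pmax(mz, 1e-300)
    z * sc
  }
  objective <- function(x) {
    fw <- forward(x)
    fid <- sum(vapply(seq_len(n_resp * n_card), function(i) {
      sum(Mod(fw[[i]] - yb[[i]])^2)
    }, numeric(1)))
    reg_c <- sum(Mod(finite_difference(x, "cardiac")))
    reg_r <- sum(Mod(finite_difference(x, "respiratory")))
    c(fid = fid, reg_r = lam_r * reg_r, reg_c = lam_c * reg_c)
  }

  x <- array(0+0i, dim = c(npix, n_card, n_resp))
  if (!use_split) {
    hist <- matrix(0, p$iterations, 3,
                   dimnames = list(NULL, c("fid", "reg_r", "reg_c")))
    for (it in seq_len(p$iterations)) {
      x <- cg(aty, x, cg_iter)
      hist[it, ] <- objective(x)
    }
  } else {
    zc <- finite_difference(x, "cardiac"); uc <- zc
    zr <- finite_difference(x, "respiratory"); ur <- zr
    hist <- matrix(0, p$iterations, 3,
                   dimnames = list(NULL, c("fid", "reg_r", "reg_c")))
    for (it in seq_len(p$iterations)) {
      b <- aty + rho * finite_difference_adjoint(zc - uc, "cardiac") +
        rho * finite_difference_adjoint(zr - ur, "respiratory")
      x <- cg(b, x, cg_iter)
      dc <- finite_difference(x, "cardiac")
      dr <- finite_difference(x, "respiratory")
      zc <- soft(dc + uc, lam_c / rho)
      zr <- soft(dr + ur, lam_r / rho)
      uc <- uc + dc - zc
      ur <- ur + dr - zr
      hist[it, ] <- objective(x)
    }
  }

  images <- array(x * ymax, dim = c(nx, nx, n_card, n_resp))
  structure(
    list(images = images,
         objective = tibble(iteration = seq_len(p$iterations),
                            fidelity = hist[, "fid"],
                            reg_resp = hist[, "reg_r"],
                            reg_card = hist[, "reg_c"],
                            total = rowSums(hist)),
         nx = nx, n_card = n_card, n_resp = n_resp,
         lambda_r = lam_r, lambda_c = lam_c, scale = ymax),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  cat("<recon_result>\n")
  cat(sprintf("  %d x %d image, %d cardiac x %d respiratory bins\n",
              x$nx, x$nx, x$n_card, x$n_resp))
  cat(sprintf("  lambda_r %g, lambda_c %g; final objective %.4g\n",
              x$lambda_r, x$lambda_c, tail(x$objective$total, 1)))
  invisible(x)
}
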