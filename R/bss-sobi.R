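#' Second-order blind identification (SOBI)
#'
#' Separates temporally correlated sources with distinct spectral content by
#' jointly diagonalizing a set of symmetrized time-lagged covariance matrices
#' of the whitened components. A single orthogonal transform minimizing the
#' sum of squared off-diagonal entries over all lags is found by Jacobi-style
#' sweeps of Givens rotations; the off-diagonal criterion is non-increasing
#' across sweeps.
#'
#' @param ss A `source_set` (whitened internally if needed), >= 2 components.
#' @param lags Integer lags (samples) of the covariance set; the default
#'   1--20 spans at least one cardiac period at a 16 Hz self-gating rate.
#' @param max_sweeps Maximum Jacobi sweeps.
#' @param tol Rotation-angle tolerance declaring convergence.
#' @return A `source_set` with `method = "SOBI"`, unit-variance sources
#'   (sign fixed so skewness >= 0), composite `unmixing` back to the original
#'   matrix columns when the input came from [pca_reduce()], the rotation
#'   `rotation`, per-sweep `criterion` history and a `converged` flag
#'   (non-convergence returns the best iterate flagged, not an error).
#' @export
sobi <- function(ss, lags = 1:20, max_sweeps = 100, tol = 1e-8) {
  if (!inherits(ss, "source_set")) {
    abort("`ss` must be a source_set.", class = "sgmotion_invalid_parameter")
  }
  ss <- ensure_whitened(ss)
  Z <- ss$whitened
  k <- ncol(Z)
  if (k < 2L) abort("need >= 2 components.", class = "sgmotion_invalid_parameter")
  lags <- as.integer(lags)
  if (any(lags < 1L) || any(lags >= nrow(Z))) {
    abort("lags must be >= 1 and smaller than the series length.",
          class = "sgmotion_invalid_parameter")
  }

  # symmetrized lagged covariances
  n <- nrow(Z)
  Rs <- lapply(lags, function(l) {
    C <- crossprod(Z[seq_len(n - l), , drop = FALSE],
                   Z[seq(l + 1L, n), , drop = FALSE]) / (n - l)
    (C + t(C)) / 2
  })

  jd <- joint_diagonalize(Rs, max_sweeps = max_sweeps, tol = tol)
  V <- jd$rotation

  sources <- Z %*% V
  # unit variance and skewness-positive sign
  sv <- apply(sources, 2L, sd)
  sv[sv < 1e-300] <- 1
  sources <- sweep(sources, 2L, sv, "/")
  sgn <- vapply(seq_len(k), function(j) {
    s <- skewness(sources[, j]); if (s < 0) -1 else 1
  }, numeric(1))
  sources <- sweep(sources, 2L, sgn, "*")

  unmixing <- if (!is.null(ss$whitening)) {
    diag(sgn / sv, k) %*% t(V) %*% ss$whitening
  } else NULL

  structure(
    list(sources = sources, whitened = sources,
         unmixing = unmixing,
         mixing = if (!is.null(unmixing)) pseudo_inverse(unmixing) else NULL,
         rotation = V, criterion = jd$criterion,
         explained_variance = NULL,
         method = "SOBI", fs_hz = ss$fs_hz, converged = jd$converged,
         lags = lags),
    class = "source_set"
  )
}

# Joint approximate diagonalization of a list of real symmetric matrices by
# Givens rotations (Jacobi sweeps minimizing the summed squared off-diagonal).
joint_diagonalize <- function(mats, max_sweeps = 100, tol = 1e-8) {
  k <- nrow(mats[[1]])
  V <- diag(k)
  off2 <- function(ms) sum(vapply(ms, function(A) sum(A^2) - sum(diag(A)^2),
                                  numeric(1)))
  crit <- off2(mats)
  history <- crit
  converged <- FALSE
  for (sweep_i in seq_len(max_sweeps)) {
    max_sin <- 0
    for (p in seq_len(k - 1L)) {
      for (q in seq(p + 1L, k)) {
        # closed-form optimal Givens angle for the (p, q) plane
        G <- matrix(0, 2, 2)
        for (A in mats) {
          h <- c(A[p, p] - A[q, q], 2 * A[p, q])
          G <- G + tcrossprod(h)
        }
        r <- sqrt((G[1, 1] - G[2, 2])^2 + 4 * G[1, 2]^2)
        if (r < 1e-300) next
        # principal eigenvector (x, y) of G with x >= 0
        x <- (G[1, 1] - G[2, 2] + r) / 2
        y <- G[1, 2]
        nv <- sqrt(x^2 + y^2)
        if (nv < 1e-300) next
        x <- x / nv; y <- y / nv
        cth <- sqrt((x + 1) / 2)
        sth <- y / (2 * cth)
        if (abs(sth) <= .Machine$double.eps) next
        max_sin <- max(max_sin, abs(sth))
        # rotate every matrix and the accumulator
        for (i in seq_along(mats)) {
          A <- mats[[i]]
          rp <- cth * A[p, ] + sth * A[q, ]
          rq <- -sth * A[p, ] + cth * A[q, ]
          A[p, ] <- rp; A[q, ] <- rq
          cp <- cth * A[, p] + sth * A[, q]
          cq <- -sth * A[, p] + cth * A[, q]
          A[, p] <- cp; A[, q] <- cq
          mats[[i]] <- A
        }
        vp <- cth * V[, p] + sth * V[, q]
        vq <- -sth * V[, p] + cth * V[, q]
        V[, p] <- vp; V[, q] <- vq
      }
    }
    history <- c(history, off2(mats))
    if (max_sin < tol) { converged <- TRUE; break }
  }
  list(rotation = V, diagonalized = mats, criterion = history,
       converged = converged)
}

pseudo_inverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}
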