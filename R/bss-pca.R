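#' Reduce a self-gating matrix to its leading principal components
#'
#' Column-centres (and by default z-scores) the self-gating matrix and
#' projects it onto the top eigenvectors of the covariance. The component
#' time series are mutually uncorrelated; a whitened (unit-variance) copy is
#' retained for the downstream blind source separation steps. Ten components
#' are kept by default, which for this class of data consistently carries
#' more than 90% of the total variance.
#'
#' @param m An `sg_matrix` (ideally after [correct_angular_dependence()]).
#' @param n_components Number of components to keep (default 10).
#' @param standardize Z-score columns before the eigendecomposition
#'   (default `TRUE`).
#' @return Object of class `source_set` with `sources` (time x k scores),
#'   `whitened` (unit-variance copy), `unmixing` (k x n_inputs),
#'   `mixing` (pseudo-inverse), `explained_variance` (fractions of total
#'   variance, non-increasing), `method = "PCA"`, `fs_hz`.
#' @export
pca_reduce <- function(m, n_components = 10, standardize = TRUE) {
  if (!inherits(m, "sg_matrix")) {
    abort("`m` must be an sg_matrix.", class = "sgmotion_invalid_parameter")
  }
  X <- m$values
  if (n_components > ncol(X)) {
    abort("`n_components` exceeds the number of input columns.",
          class = "sgmotion_invalid_parameter")
  }
  if (nrow(X) <= n_components) {
    abort("need more time points than components.",
          class = "sgmotion_invalid_parameter")
  }
  ctr <- colMeans(X)
  scl <- if (standardize) {
    s <- apply(X, 2L, sd)
    s[s < 1e-12] <- 1  # constant columns left unscaled
    s
  } else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  total_var <- sum(pc$sdev^2)
  explained <- sdev^2 / total_var

  # whitened copy; numerically dead directions are zeroed, not inflated
  tol <- max(pc$sdev) * 1e-10
  inv_sd <- ifelse(sdev > tol, 1 / sdev, 0)
  whitened <- sweep(scores, 2L, inv_sd, "*")

  # sign convention: skewness of each component >= 0
  sgn <- vapply(seq_len(k), function(j) {
    s <- skewness(scores[, j]); if (s < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(scores, 2L, sgn, "*")
  whitened <- sweep(whitened, 2L, sgn, "*")
  rot <- sweep(rot, 2L, sgn, "*")

  unmixing <- t(rot)                       # sources = Xc %*% t(unmixing)
  structure(
    list(sources = scores, whitened = whitened,
         unmixing = unmixing, mixing = rot,
         whitening = sweep(t(rot), 1L, inv_sd, "*"),
         explained_variance = explained,
         center = ctr, scale = scl, standardize = standardize,
         method = "PCA", fs_hz = m$fs_hz, converged = TRUE,
         inputs = Xc),
    class = "source_set"
  )
}

#' @export
print.source_set <- function(x, ...) {
  cat("<source_set>\n")
  cat(sprintf("  method %s: %d sources x %d time points, fs %.3f Hz\n",
              x$method, ncol(x$sources), nrow(x$sources), x$fs_hz))
  if (!is.null(x$explained_variance)) {
    cat(sprintf("  explained variance: %.1f%% (cumulative)\n",
                100 * sum(x$explained_variance)))
  }
  cat(sprintf("  converged: %s\n", isTRUE(x$converged)))
  invisible(x)
}

# Ensure a source_set carries a whitened copy (identity-covariance sources).
ensure_whitened <- function(ss) {
  if (!is.null(ss$whitened)) return(ss)
  S <- ss$sources
  S <- sweep(S, 2L, colMeans(S))
  eg <- eigen(stats::cov(S), symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  inv_sd <- ifelse(eg$values > tol, 1 / sqrt(eg$values), 0)
  ss$whitened <- S %*% eg$vectors %*% diag(inv_sd, length(inv_sd))
  ss
}

#' Amari separation-performance index
#'
#' Scale- and permutation-invariant distance between an estimated unmixing
#' map and the true mixing; 0 means perfect separation up to permutation and
#' scaling.
#'
#' @param unmixing Estimated unmixing matrix (k x p).
#' @param mixing True mixing matrix (p x k).
#' @return Non-negative scalar.
#' @export
amari_index <- function(unmixing, mixing) {
  P <- abs(unmixing %*% mixing)
  k <- nrow(P)
  rowterm <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  colterm <- sum(colSums(sweep(P, 2L, apply(P, 2L, max), "/")) - 1)
  (rowterm + colterm) / (2 * k * (k - 1))
}
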