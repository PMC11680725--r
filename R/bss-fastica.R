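#' FastICA by symmetric fixed-point iteration
#'
#' Estimates maximally non-Gaussian sources from the whitened components
#' using the negentropy-approximation fixed point with symmetric
#' (simultaneous) decorrelation. The log-cosh contrast is the default robust
#' choice. Because the iteration starts from a random orthonormal matrix, the
#' seed is a required argument: identical seeds give identical output, and
#' run-to-run variability across seeds is an inherent property of the
#' algorithm.
#'
#' @param ss A `source_set` (whitened internally if needed).
#' @param nonlinearity Contrast function: `"logcosh"` (default), `"exp"`, or
#'   `"cube"`.
#' @param seed Integer seed for the random orthonormal initialization
#'   (required).
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the update (1 - |<w_new, w_old>|).
#' @return A `source_set` with `method = "ICA"`, unit-variance sources (sign
#'   fixed so skewness >= 0), composite `unmixing` when available, iteration
#'   count, and a `converged` flag; non-convergence returns the best iterate
#'   flagged (e.g. for Gaussian sources, which are not identifiable).
#' @export
fastica <- function(ss, nonlinearity = c("logcosh", "exp", "cube"),
                    seed, max_iter = 500, tol = 1e-5) {
  if (missing(seed)) {
    abort("`seed` is required: FastICA is randomly initialized.",
          class = "sgmotion_invalid_parameter")
  }
  nonlinearity <- match.arg(nonlinearity)
  if (!inherits(ss, "source_set")) {
    abort("`ss` must be a source_set.", class = "sgmotion_invalid_parameter")
  }
  ss <- ensure_whitened(ss)
  Z <- ss$whitened
  n <- nrow(Z); k <- ncol(Z)
  if (k < 2L) abort("need >= 2 components.", class = "sgmotion_invalid_parameter")

  g <- switch(nonlinearity,
    logcosh = list(f = function(u) tanh(u), df = function(u) 1 - tanh(u)^2),
    exp = list(f = function(u) u * exp(-u^2 / 2),
               df = function(u) (1 - u^2) * exp(-u^2 / 2)),
    cube = list(f = function(u) u^3, df = function(u) 3 * u^2))

  sym_decorrelate <- function(W) {
    eg <- eigen(W %*% t(W), symmetric = TRUE)
    vals <- pmax(eg$values, 1e-300)
    eg$vectors %*% diag(1 / sqrt(vals), k) %*% t(eg$vectors) %*% W
  }

  W <- with_seed(seed, {
    qr.Q(qr(matrix(rnorm(k * k), k, k)))
  })
  W <- sym_decorrelate(W)

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    U <- Z %*% t(W)                 # n x k projections
    GU <- g$f(U)
    dG <- colMeans(g$df(U))
    W_new <- crossprod(GU, Z) / n - diag(dG, k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }

  sources <- Z %*% t(W)
  sv <- apply(sources, 2L, sd)
  sv[sv < 1e-300] <- 1
  sources <- sweep(sources, 2L, sv, "/")
  sgn <- vapply(seq_len(k), function(j) {
    s <- skewness(sources[, j]); if (s < 0) -1 else 1
  }, numeric(1))
  sources <- sweep(sources, 2L, sgn, "*")

  unmixing <- if (!is.null(ss$whitening)) {
    diag(sgn / sv, k) %*% W %*% ss$whitening
  } else NULL

  structure(
    list(sources = sources, whitened = sources,
         unmixing = unmixing,
         mixing = if (!is.null(unmixing)) pseudo_inverse(unmixing) else NULL,
         rotation = t(W),
         explained_variance = NULL,
         method = "ICA", fs_hz = ss$fs_hz, converged = converged,
         iterations = iter, nonlinearity = nonlinearity, seed = seed),
    class = "source_set"
  )
}
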