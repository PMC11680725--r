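# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# standard RSA-coupled subject used by several files (2 min keeps tests fast;
# durations are scaled up only where a check needs the full 5-min run)
default_gt <- function() {
  cached("gt_default", simulate_physio(hr_mean_bpm = 60, hr_sd_bpm = 2,
                                       rsa_gain_bpm = 6, duration_s = 120,
                                       seed = 42))
}

default_stack <- function() {
  cached("stack_default", simulate_si_stack(default_gt(), seed = 43))
}

default_sg_matrix <- function() {
  cached("sgm_default",
         correct_angular_dependence(assemble_sg_matrix(default_stack())))
}

default_pca <- function() {
  cached("pca_default", pca_reduce(default_sg_matrix()))
}

# wrap a plain matrix as an sg_matrix for unit tests of the BSS layer
as_sg_matrix <- function(values, fs_hz = 16, segment_index = NULL) {
  structure(list(values = values, fs_hz = fs_hz,
                 segment_index = segment_index %||%
                   (seq_len(nrow(values)) - 1L) %% 22L,
                 col_meta = tibble::tibble(column = seq_len(ncol(values)),
                                           position = seq_len(ncol(values)),
                                           coil = 1L),
                 corrected = FALSE),
            class = "sg_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force interval-SD oracle: explicit loops, no shared code with the
# implementation
isd_brute_force <- function(s_times, e_times) {
  n_int <- length(s_times) - 1
  d <- numeric(n_int)
  for (i in seq_len(n_int)) {
    ds <- s_times[i + 1] - s_times[i]
    de <- e_times[i + 1] - e_times[i]
    d[i] <- abs(ds - de)
  }
  mu <- 0
  for (i in seq_len(n_int)) mu <- mu + d[i]
  mu <- mu / n_int
  ss <- 0
  for (i in seq_len(n_int)) ss <- ss + (d[i] - mu)^2
  sqrt(ss / (n_int - 1))
}

# 2x2 Amari-style separation score from the best-matching correlation rows
amari_from_sources <- function(est, truth) {
  C <- abs(stats::cor(est, truth))
  rows <- order(apply(C, 1, max), decreasing = TRUE)[1:2]
  amari_index(C[rows, , drop = FALSE], diag(2))
}

# One binning-fidelity reconstruction experiment: a 60 s beating-disk
# acquisition sampled at the self-gating readout density, reconstructed once
# with ground-truth cardiac binning and once with triggers jittered by a
# uniform +/-100 ms; returns the two RMSEs against the bin-centre phantoms.
binning_fidelity_rmse <- function(seed, nx = 16, n_read = 480, n_bins = 8) {
  phase_of <- function(trig, t) {
    i <- findInterval(t, trig)
    ok <- i >= 1 & t < max(trig)
    ph <- rep(NA_real_, length(t))
    ph[ok] <- (t[ok] - trig[i[ok]]) / (trig[i[ok] + 1] - trig[i[ok]])
    ph
  }
  gt <- simulate_physio(hr_mean_bpm = 65, hr_sd_bpm = 3, duration_s = 60,
                        seed = seed)
  read_t <- seq(0, 59900, length.out = n_read)
  true_ph <- phase_of(gt$trigger_times_ms, read_t)
  keep <- !is.na(true_ph)
  read_t <- read_t[keep]; true_ph <- true_ph[keep]
  angles <- (seq_along(read_t) - 1) * pi * (3 - sqrt(5)) %% pi
  sim <- simulate_cine_radial(true_ph, angles, nx = nx, n_samples = nx,
                              noise_sd = 0.02, seed = seed + 1)
  jit <- withr::with_seed(seed + 2,
                          runif(length(gt$trigger_times_ms), -100, 100))
  bad_ph <- phase_of(sort(gt$trigger_times_ms + jit), read_t)
  rmse_of <- function(ph) {
    cb <- ifelse(is.na(ph), NA_integer_, pmin(floor(ph * n_bins), n_bins - 1L))
    res <- admm_recon(recon_problem(group_kspace_by_bins(sim, cb), nx,
                                    iterations = 10))
    ref <- vapply(seq_len(n_bins), function(b) {
      as.vector(disk_phantom(nx, (b - 0.5) / n_bins))
    }, numeric(nx * nx))
    sqrt(mean((Mod(array(res$images, c(nx * nx, n_bins))) - ref)^2))
  }
  c(truth = rmse_of(true_ph), jitter = rmse_of(bad_ph))
}

# simple separable Gaussian blur used by the sharpness monotonicity checks
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  img <- apply(img, 2, pad_conv)
  t(apply(img, 1, pad_conv))
}
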