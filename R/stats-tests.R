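#' Bonett-Seier test for paired dispersions
#'
#' One-sided z-test comparing the dispersions (mean absolute deviations,
#' MAD) of two paired samples. The statistic is the log ratio of the two
#' sample MADs divided by its delta-method standard error, which includes
#' the covariance term induced by the pairing:
#'
#' \deqn{z = \frac{\ln(\hat\tau_1 / \hat\tau_2)}{\sqrt{v_1 + v_2 - 2 v_{12}}}}
#'
#' with \eqn{\hat\tau_j} the mean of \eqn{|x_{ij} - \bar x_j|},
#' \eqn{v_j = (\hat\sigma_j^2/\hat\tau_j^2 - 1)/n} and \eqn{v_{12}} the
#' analogous covariance of the two log MAD estimates. `alternative =
#' "less"` tests whether the first sample is *less* dispersed. Identical
#' samples give statistic 0 and one-sided p = 0.5; swapping the samples
#' negates the statistic.
#'
#' @param d1,d2 Equal-length paired numeric samples, n >= 5.
#' @param alternative `"less"` (default), `"greater"`, or `"two.sided"`,
#'   about the dispersion of `d1` relative to `d2`.
#' @return One-row tibble: `statistic`, `p_value`, `mad1`, `mad2`,
#'   `ratio`, `n`.
#' @export
bonett_seier_paired <- function(d1, d2,
                                alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(d1) != length(d2)) {
    abort("paired samples must have equal length.",
          class = "sgmotion_invalid_parameter")
  }
  keep <- is.finite(d1) & is.finite(d2)
  d1 <- d1[keep]; d2 <- d2[keep]
  n <- length(d1)
  if (n < 5L) abort("need n >= 5 pairs.", class = "sgmotion_invalid_parameter")

  a <- abs(d1 - mean(d1))
  b <- abs(d2 - mean(d2))
  tau1 <- mean(a); tau2 <- mean(b)
  if (tau1 == 0 || tau2 == 0) {
    abort("zero mean absolute deviation in a sample.",
          class = "sgmotion_invalid_parameter")
  }
  v1 <- (mean(a^2) / tau1^2 - 1) / n
  v2 <- (mean(b^2) / tau2^2 - 1) / n
  v12 <- mean((a - tau1) * (b - tau2)) / (n * tau1 * tau2)
  se2 <- v1 + v2 - 2 * v12
  z <- if (se2 <= 0) 0 else log(tau1 / tau2) / sqrt(se2)
  p <- switch(alternative,
              less = pnorm(z),
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(-abs(z)))
  tibble(statistic = z, p_value = p, mad1 = tau1, mad2 = tau2,
         ratio = tau1 / tau2, n = n)
}

#' Bland-Altman agreement analysis of paired intervals
#'
#' Mean difference with 95% limits of agreement (mean +/- 1.96 SD of the
#' differences), plus the paired linear fit of the first sample on the
#' second (slope, intercept, R squared).
#'
#' @param int_sg,int_ecg Paired numeric interval samples (ms), n >= 3.
#' @return One-row tibble: `mean_diff`, `lower_loa`, `upper_loa`, `sd_diff`,
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
bland_altman <- function(int_sg, int_ecg) {
  if (length(int_sg) != length(int_ecg)) {
    abort("paired samples must have equal length.",
          class = "sgmotion_invalid_parameter")
  }
  keep <- is.finite(int_sg) & is.finite(int_ecg)
  int_sg <- int_sg[keep]; int_ecg <- int_ecg[keep]
  n <- length(int_sg)
  if (n < 3L) abort("need n >= 3 pairs.", class = "sgmotion_invalid_parameter")
  d <- int_sg - int_ecg
  md <- mean(d); sdd <- sd(d)
  if (var(int_ecg) == 0) {
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  } else {
    fit <- lm(int_sg ~ int_ecg)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    # manual R^2: summary.lm warns on essentially perfect fits
    sst <- sum((int_sg - mean(int_sg))^2)
    r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  }
  tibble(mean_diff = md,
         lower_loa = md - 1.96 * sdd,
         upper_loa = md + 1.96 * sdd,
         sd_diff = sdd,
         slope = slope, intercept = intercept, r_squared = r2,
         n = n)
}
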