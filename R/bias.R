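# Publication-bias (small-study effect) diagnostics: Egger's weighted
# regression test and Begg's rank correlation test. Both need at least
# three studies to say anything.

#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Ordinary least-squares regression of the standardized effect
#' \eqn{log OR_i / se_i} on precision \eqn{1/se_i}. In an unbiased
#' meta-analysis the intercept is zero; it is tested with a t reference on
#' k - 2 df, two-sided.
#'
#' @param x List (length at least 3) of `contrast_table` or `effect_estimate`
#'   objects.
#' @return List of class `egger_test`: `intercept`, `se`, `t`, `df`, `p`, `k`.
#' @export
egger_test <- function(x) {
  e <- as_effects(x)
  k <- length(e$y)
  if (k < 3) stop("Egger's test needs at least 3 studies", call. = FALSE)
  fit <- stats::lm(I(e$y / e$se) ~ I(1 / e$se))
  ct <- summary(fit)$coefficients
  intercept <- ct[1, 1]
  se <- ct[1, 2]
  tval <- intercept / se
  structure(list(intercept = intercept, se = se, t = tval, df = k - 2L,
                 p = 2 * stats::pt(-abs(tval), df = k - 2), k = k),
            class = "egger_test")
}

#' Begg and Mazumdar's rank correlation test
#'
#' Kendall rank correlation between variance-stabilized deviations of study
#' effects from the inverse-variance fixed pooled mean,
#' \eqn{t_i = (\theta_i - \bar\theta) / \sqrt{v_i - 1/\sum 1/v_j}}, and the
#' sampling variances \eqn{v_i}. The normal approximation of the tau statistic
#' uses the continuity correction \eqn{z = (|P - D| - 1)/\sqrt{k(k-1)(2k+5)/18}}
#' (concordant pairs P, discordant pairs D), two-sided.
#'
#' @param x List (length at least 3) of `contrast_table` or `effect_estimate`
#'   objects.
#' @return List of class `begg_test`: `kendall_tau`, `z`, `p`, `k`.
#' @export
begg_test <- function(x) {
  e <- as_effects(x)
  k <- length(e$y)
  if (k < 3) stop("Begg's test needs at least 3 studies", call. = FALSE)
  v <- e$se^2
  w <- 1 / v
  mu <- sum(w * e$y) / sum(w)
  vstar <- v - 1 / sum(w)
  ti <- (e$y - mu) / sqrt(vstar)
  concordant <- 0L
  discordant <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- sign(ti[j] - ti[i]) * sign(v[j] - v[i])
      if (s > 0) concordant <- concordant + 1L
      if (s < 0) discordant <- discordant + 1L
    }
  }
  tau <- (concordant - discordant) / (k * (k - 1) / 2)
  denom <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  diff <- concordant - discordant
  z <- if (diff == 0) 0 else sign(diff) * (abs(diff) - 1) / denom
  structure(list(kendall_tau = tau, z = z, p = 2 * stats::pnorm(-abs(z)), k = k),
            class = "begg_test")
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger's test (k = %d): intercept %.3f (se %.3f), t(%d) = %.3f, p = %.4f\n",
              x$k, x$intercept, x$se, x$df, x$t, x$p))
  invisible(x)
}

#' @export
print.begg_test <- function(x, ...) {
  cat(sprintf("Begg's test (k = %d): Kendall tau = %.3f, z = %.3f, p = %.4f\n",
              x$k, x$kendall_tau, x$z, x$p))
  invisible(x)
}
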