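# Effect estimation and pooling.
#
# Per-study effects are Woolf log odds ratios with the Haldane-Anscombe 0.5
# correction for zero cells. Fixed-effect pooling is Mantel-Haenszel with the
# Robins-Breslow-Greenland variance for the log pooled OR; random-effects
# pooling is DerSimonian-Laird, with tau^2 estimated by the moment method
# from inverse-variance fixed weights. Heterogeneity is Cochran's Q about the
# inverse-variance fixed pooled mean, summarised as I^2 = (Q - df)/Q.

Z95 <- stats::qnorm(0.975)

#' Per-study odds ratio (Woolf method)
#'
#' @param t A `contrast_table` from [build_contrast()].
#' @return An `effect_estimate`: list with `study_id`, `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high` (95\%), and `corrected` -- `TRUE` when a zero cell
#'   forced the Haldane-Anscombe correction (0.5 added to all four cells).
#' @details The standard error is \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}. A table
#'   with an empty case or control margin, or with both cells of a column
#'   zero, has no defined odds ratio and is an error.
#' @examples
#' estimate_effect(build_contrast(c(8, 29, 13), c(46, 68, 28), "allele"))
#' @export
estimate_effect <- function(t) {
  stopifnot(inherits(t, "contrast_table"))
  if (t$a + t$b == 0 || t$c + t$d == 0) {
    stop("undefined effect: empty case or control margin", call. = FALSE)
  }
  if (t$a + t$c == 0 && t$b + t$d == 0) {
    stop("undefined effect: both table columns are empty", call. = FALSE)
  }
  corrected <- any(c(t$a, t$b, t$c, t$d) == 0)
  cc <- if (corrected) 0.5 else 0
  a <- t$a + cc; b <- t$b + cc; c <- t$c + cc; d <- t$d + cc
  log_or <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(study_id = t$study_id, log_or = log_or, se = se,
                 or = exp(log_or),
                 ci_low = exp(log_or - Z95 * se),
                 ci_high = exp(log_or + Z95 * se),
                 corrected = corrected),
            class = "effect_estimate")
}

# Accept a list of contrast tables or of effect estimates and return the
# per-study log-ORs/SEs plus the tables when available (MH needs raw cells).
as_effects <- function(x) {
  stopifnot(is.list(x), length(x) >= 1)
  if (inherits(x, c("contrast_table", "effect_estimate"))) x <- list(x)
  if (all(vapply(x, inherits, logical(1), "contrast_table"))) {
    est <- lapply(x, estimate_effect)
    tables <- x
  } else if (all(vapply(x, inherits, logical(1), "effect_estimate"))) {
    est <- x
    tables <- NULL
  } else {
    stop("expected a list of contrast_table or effect_estimate objects",
         call. = FALSE)
  }
  list(estimates = est,
       y = vapply(est, `[[`, numeric(1), "log_or"),
       se = vapply(est, `[[`, numeric(1), "se"),
       ids = vapply(est, function(e) as.character(e$study_id), character(1)),
       tables = tables,
       model = if (is.null(tables)) NA_character_ else tables[[1]]$model)
}

#' Cochran's Q, I-squared and DerSimonian-Laird tau-squared
#'
#' Q is the weighted sum of squared deviations of study log-ORs from the
#' inverse-variance fixed pooled mean, with weights \eqn{w_i = 1/se_i^2};
#' its reference distribution is chi-square on k-1 df.
#' \eqn{I^2 = \max(0, 100 (Q - df)/Q)} percent, and the moment estimator
#' \eqn{\tau^2 = \max(0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum w_i))}.
#'
#' @param x List of `contrast_table` or `effect_estimate` objects.
#' @return A `heterogeneity` list: `k`, `q_stat`, `df`, `p_het`, `i2`
#'   (percent), `tau2`, and `degenerate` (`TRUE` when k < 2, in which case
#'   Q = 0, p = 1, I^2 = 0 by convention).
#' @export
heterogeneity <- function(x) {
  e <- as_effects(x)
  k <- length(e$y)
  if (k < 2) {
    return(structure(list(k = k, q_stat = 0, df = 0L, p_het = 1, i2 = 0,
                          tau2 = 0, degenerate = TRUE),
                     class = "heterogeneity"))
  }
  w <- 1 / e$se^2
  mu <- sum(w * e$y) / sum(w)
  q <- sum(w * (e$y - mu)^2)
  df <- k - 1L
  p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(list(k = k, q_stat = q, df = df, p_het = p, i2 = i2, tau2 = tau2,
                 degenerate = FALSE),
            class = "heterogeneity")
}

#' Choose between fixed- and random-effects pooling
#'
#' Random effects are used when the between-study variation dominates:
#' I-squared at or above the threshold selects DerSimonian-Laird, otherwise
#' Mantel-Haenszel fixed effects. I-squared alone drives the choice because,
#' unlike the heterogeneity p-value, it does not conflate extent of
#' heterogeneity with the number of studies.
#'
#' @param het A `heterogeneity` object (or a bare I-squared percentage).
#' @param i2_threshold Threshold in percent (default 50).
#' @return `"fixed"` or `"random"`.
#' @export
select_method <- function(het, i2_threshold = 50) {
  i2 <- if (inherits(het, "heterogeneity")) het$i2 else as.numeric(het)
  if (i2 >= i2_threshold) "random" else "fixed"
}

new_pooled_result <- function(model, method, e, mu, se, het, tau2, weights) {
  z <- mu / se
  structure(list(model = model, method = method, k = length(e$y),
                 or = exp(mu),
                 ci_low = exp(mu - Z95 * se), ci_high = exp(mu + Z95 * se),
                 z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 q_stat = het$q_stat, df = het$df, p_het = het$p_het,
                 i2 = het$i2, tau2 = tau2,
                 weights = stats::setNames(weights / sum(weights), e$ids),
                 estimates = e$estimates),
            class = "pooled_result")
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' Pooled OR \eqn{\sum_i a_i d_i / n_i \,/\, \sum_i b_i c_i / n_i} over the
#' uncorrected cells (Mantel-Haenszel tolerates zero cells), with the
#' Robins-Breslow-Greenland variance of the log pooled OR. Heterogeneity
#' statistics from [heterogeneity()] are attached.
#'
#' @param tables List of `contrast_table`, all built under the same model.
#' @return A `pooled_result` with `method = "fixed"`, normalized
#'   Mantel-Haenszel weights, and `tau2 = 0`.
#' @export
pool_fixed_mh <- function(tables) {
  if (length(tables) == 0) stop("no tables to pool", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "contrast_table")))
  models <- unique(vapply(tables, `[[`, character(1), "model"))
  if (length(models) != 1) {
    stop("all tables must share one genetic model", call. = FALSE)
  }
  e <- as_effects(tables)
  a <- vapply(tables, `[[`, numeric(1), "a")
  b <- vapply(tables, `[[`, numeric(1), "b")
  cc <- vapply(tables, `[[`, numeric(1), "c")
  d <- vapply(tables, `[[`, numeric(1), "d")
  n <- a + b + cc + d
  R <- sum(a * d / n)
  S <- sum(b * cc / n)
  if (R == 0 || S == 0) {
    stop("Mantel-Haenszel pooled odds ratio undefined (all-zero diagonal)",
         call. = FALSE)
  }
  P <- (a + d) / n
  Q <- (b + cc) / n
  Ri <- a * d / n
  Si <- b * cc / n
  v <- sum(P * Ri) / (2 * R^2) +
       sum(P * Si + Q * Ri) / (2 * R * S) +
       sum(Q * Si) / (2 * S^2)
  new_pooled_result(models, "fixed", e, log(R / S), sqrt(v),
                    heterogeneity(tables), tau2 = 0, weights = Si)
}

#' Inverse-variance fixed-effect pooled odds ratio
#'
#' The weighted mean of Woolf log-ORs with weights \eqn{1/se_i^2}. Used
#' internally by the Q and tau-squared machinery; exported because it is the
#' natural cross-check for the Mantel-Haenszel estimate (the two agree
#' closely whenever counts are large and no cell is empty).
#'
#' @param x List of `contrast_table` or `effect_estimate` objects.
#' @return A `pooled_result` with `method = "fixed"`.
#' @export
pool_fixed_iv <- function(x) {
  e <- as_effects(x)
  w <- 1 / e$se^2
  mu <- sum(w * e$y) / sum(w)
  new_pooled_result(e$model, "fixed", e, mu, sqrt(1 / sum(w)),
                    heterogeneity(x), tau2 = 0, weights = w)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Inverse-variance pooling with weights \eqn{1/(se_i^2 + \tau^2)}, where
#' tau-squared is the DerSimonian-Laird moment estimate from
#' [heterogeneity()]. When studies are homogeneous (Q at or below its df)
#' tau-squared is zero and the result coincides with inverse-variance fixed
#' pooling.
#'
#' @param x List (length at least 2) of `contrast_table` or `effect_estimate`
#'   objects.
#' @return A `pooled_result` with `method = "random"`.
#' @export
pool_random_dl <- function(x) {
  e <- as_effects(x)
  if (length(e$y) < 2) {
    stop("random-effects pooling needs at least 2 studies", call. = FALSE)
  }
  het <- heterogeneity(x)
  w <- 1 / (e$se^2 + het$tau2)
  mu <- sum(w * e$y) / sum(w)
  new_pooled_result(e$model, "random", e, mu, sqrt(1 / sum(w)),
                    het, tau2 = het$tau2, weights = w)
}

#' Pool with heterogeneity-driven method selection
#'
#' Computes heterogeneity, applies [select_method()], and pools with
#' [pool_fixed_mh()] or [pool_random_dl()] accordingly. A single study is
#' passed through as its own estimate (`method = "single"`).
#'
#' @param tables List of `contrast_table`.
#' @param method `"auto"` (default), or force `"fixed"` / `"random"`.
#' @param i2_threshold I-squared threshold in percent for `"auto"`.
#' @return A `pooled_result`.
#' @export
pool_auto <- function(tables, method = c("auto", "fixed", "random"),
                      i2_threshold = 50) {
  method <- match.arg(method)
  if (length(tables) == 0) stop("no tables to pool", call. = FALSE)
  if (length(tables) == 1) {
    e <- as_effects(tables)
    est <- e$estimates[[1]]
    return(new_pooled_result(e$model, "single", e, est$log_or, est$se,
                             heterogeneity(tables), tau2 = 0, weights = 1))
  }
  if (method == "auto") method <- select_method(heterogeneity(tables), i2_threshold)
  if (method == "fixed") pool_fixed_mh(tables) else pool_random_dl(tables)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s OR %.3f (95%% CI %.3f-%.3f)%s\n",
              if (is.na(x$study_id)) "study" else x$study_id,
              x$or, x$ci_low, x$ci_high,
              if (x$corrected) " [0.5 continuity correction]" else ""))
  invisible(x)
}

#' @export
print.pooled_result <- function(x, ...) {
  lab <- switch(x$method, fixed = "fixed (Mantel-Haenszel)",
                random = "random (DerSimonian-Laird)",
                single = "single study (not pooled)", x$method)
  cat(sprintf("Pooled OR, %s model, %s, k = %d\n", x$model, lab, x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), z = %.3f, p = %.4g\n",
              x$or, x$ci_low, x$ci_high, x$z, x$p_value))
  cat(sprintf("  heterogeneity: Q(%d) = %.3f, p = %.4g, I2 = %.1f%%, tau2 = %.4f\n",
              x$df, x$q_stat, x$p_het, x$i2, x$tau2))
  invisible(x)
}
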