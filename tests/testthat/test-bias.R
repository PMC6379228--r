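test_that("Egger's intercept matches a closed-form least-squares oracle", {
  tables <- list(tab2x2(18, 12, 10, 20, "a"), tab2x2(40, 35, 30, 45, "b"),
                 tab2x2(9, 6, 8, 7, "c"), tab2x2(60, 45, 50, 55, "d"))
  w <- woolf_oracle(tables)
  yy <- w$y / w$se           # standardized effect
  xx <- 1 / w$se             # precision
  k <- length(xx)
  slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  intercept <- mean(yy) - slope * mean(xx)
  rss <- sum((yy - intercept - slope * xx)^2)
  se_int <- sqrt(rss / (k - 2) * (1 / k + mean(xx)^2 / sum((xx - mean(xx))^2)))

  e <- egger_test(tables)
  expect_equal(e$intercept, intercept, tolerance = 1e-12)
  expect_equal(e$se, se_int, tolerance = 1e-12)
  expect_equal(e$df, 2L)
  expect_equal(e$p, 2 * pt(-abs(intercept / se_int), 2), tolerance = 1e-12)
})

test_that("Egger's test agrees with metafor's standard-error regression", {
  skip_if_not_installed("metafor")
  tables <- contrast_tables(fixture(), "-670 A/G", "allele")
  w <- woolf_oracle(tables)
  ref <- metafor::regtest(w$y, sei = w$se, model = "lm", predictor = "sei")
  e <- egger_test(tables)
  expect_equal(e$t, unname(ref$zval), tolerance = 1e-8)
  expect_equal(e$p, unname(ref$pval), tolerance = 1e-8)
})

test_that("a symmetric funnel has a near-zero Egger intercept", {
  # matched pairs +delta/-delta at identical standard errors
  y <- c(0.4, -0.4, 0.25, -0.25, 0.1, -0.1)
  se <- rep(c(0.2, 0.35, 0.5), each = 2)
  est <- lapply(seq_along(y), function(i) {
    structure(list(study_id = paste0("s", i), log_or = y[i], se = se[i],
                   or = exp(y[i]), ci_low = NA, ci_high = NA, corrected = FALSE),
              class = "effect_estimate")
  })
  expect_equal(egger_test(est)$intercept, 0, tolerance = 1e-10)
})

test_that("Begg's tau matches rank-correlation oracles", {
  tables <- list(tab2x2(18, 12, 10, 20, "a"), tab2x2(40, 35, 30, 45, "b"),
                 tab2x2(9, 6, 8, 7, "c"), tab2x2(60, 45, 50, 55, "d"),
                 tab2x2(25, 31, 28, 26, "e"))
  w <- woolf_oracle(tables)
  v <- w$se^2
  wt <- 1 / v
  mu <- sum(wt * w$y) / sum(wt)
  ti <- (w$y - mu) / sqrt(v - 1 / sum(wt))
  expect_equal(begg_test(tables)$kendall_tau,
               unname(cor(ti, v, method = "kendall")), tolerance = 1e-12)

  skip_if_not_installed("metafor")
  ref <- metafor::ranktest(w$y, vi = v, exact = FALSE)
  expect_equal(begg_test(tables)$kendall_tau, unname(ref$tau), tolerance = 1e-10)
})

test_that("Begg's tau vanishes when effects do not depend on variance", {
  # identical effects: every pair ties on the effect axis
  est <- lapply(1:4, function(i) {
    structure(list(study_id = paste0("s", i), log_or = 0.3, se = 0.1 * i,
                   or = exp(0.3), ci_low = NA, ci_high = NA, corrected = FALSE),
              class = "effect_estimate")
  })
  b <- begg_test(est)
  expect_equal(b$kendall_tau, 0)
  expect_equal(b$z, 0)
  expect_equal(b$p, 1)
})

test_that("Begg's tau only sees the ranks of the variances", {
  tables <- contrast_tables(fixture(), "-670 A/G", "allele")
  w <- woolf_oracle(tables)
  v <- w$se^2
  wt <- 1 / v
  ti <- (w$y - sum(wt * w$y) / sum(wt)) / sqrt(v - 1 / sum(wt))
  # with the standardized deviations held fixed, any monotone transform of
  # the variances leaves the rank correlation unchanged
  expect_equal(unname(cor(ti, v, method = "kendall")),
               unname(cor(ti, log(v), method = "kendall")))
  expect_equal(begg_test(tables)$kendall_tau,
               unname(cor(ti, rank(v), method = "kendall")), tolerance = 1e-12)
})

test_that("both tests are invariant under study relabelling and need k >= 3", {
  tables <- contrast_tables(fixture(), "-670 A/G", "allele")
  perm <- sample(length(tables))
  expect_equal(egger_test(tables)$p, egger_test(tables[perm])$p, tolerance = 1e-12)
  expect_equal(begg_test(tables)$kendall_tau,
               begg_test(tables[perm])$kendall_tau, tolerance = 1e-12)
  expect_error(egger_test(tables[1:2]), "at least 3")
  expect_error(begg_test(tables[1:2]), "at least 3")
})
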