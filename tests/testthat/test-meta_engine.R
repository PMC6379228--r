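test_that("per-study Woolf effects match direct arithmetic", {
  balanced <- estimate_effect(tab2x2(10, 10, 10, 10))
  expect_equal(balanced$or, 1)
  expect_equal(balanced$log_or, 0)
  expect_false(balanced$corrected)

  # Haldane-Anscombe correction fires only on zero cells
  z <- estimate_effect(tab2x2(0, 10, 5, 15))
  expect_true(z$corrected)
  expect_equal(z$or, (0.5 * 15.5) / (10.5 * 5.5), tolerance = 1e-12)

  # all case subjects heterozygous: the homozygote contrast has an empty
  # case margin and no defined odds ratio
  expect_error(estimate_effect(build_contrast(c(0, 5, 0), c(15, 0, 5), "homozygote")),
               "empty case")
})

test_that("confidence limits bracket the estimate symmetrically on the log scale", {
  e <- estimate_effect(tab2x2(55, 45, 124, 160))
  expect_equal(e$or, exp(e$log_or))
  expect_lt(e$ci_low, e$or)
  expect_gt(e$ci_high, e$or)
  expect_equal(e$ci_low * e$ci_high, exp(2 * e$log_or), tolerance = 1e-12)
})

test_that("Mantel-Haenszel pooling reduces correctly in degenerate cases", {
  t1 <- tab2x2(55, 45, 124, 160, id = "s1")
  single <- pool_fixed_mh(list(t1))
  expect_equal(single$or, estimate_effect(t1)$or, tolerance = 1e-12)

  dup <- pool_fixed_mh(list(t1, tab2x2(55, 45, 124, 160, id = "s2")))
  expect_equal(dup$or, estimate_effect(t1)$or, tolerance = 1e-12)
  expect_equal(dup$q_stat, 0, tolerance = 1e-12)
  expect_equal(dup$i2, 0)
  expect_equal(sum(dup$weights), 1)

  expect_error(pool_fixed_mh(list()), "no tables")
  expect_error(
    pool_fixed_mh(list(build_contrast(c(1, 2, 3), c(3, 2, 1), "allele"),
                       build_contrast(c(1, 2, 3), c(3, 2, 1), "dominant"))),
    "share one genetic model")
})

test_that("MH and DL pooling agree with metafor on the packaged data", {
  skip_if_not_installed("metafor")
  ds <- fixture()
  for (snp in c("-670 A/G", "124 A/G", "-844 C/T")) {
    for (model in genetic_models()) {
      tables <- contrast_tables(ds, snp, model)
      a <- sapply(tables, `[[`, "a"); b <- sapply(tables, `[[`, "b")
      cc <- sapply(tables, `[[`, "c"); d <- sapply(tables, `[[`, "d")

      mh <- pool_fixed_mh(tables)
      ref <- metafor::rma.mh(ai = a, bi = b, ci = cc, di = d,
                             measure = "OR", correct = FALSE)
      expect_equal(log(mh$or), as.numeric(ref$beta), tolerance = 1e-10)
      expect_equal(mh$ci_low, exp(as.numeric(ref$ci.lb)), tolerance = 1e-8)
      expect_equal(mh$ci_high, exp(as.numeric(ref$ci.ub)), tolerance = 1e-8)

      w <- woolf_oracle(tables)
      dl <- pool_random_dl(tables)
      ref2 <- metafor::rma(yi = w$y, sei = w$se, method = "DL")
      expect_equal(log(dl$or), as.numeric(ref2$beta), tolerance = 1e-10)
      expect_equal(dl$tau2, ref2$tau2, tolerance = 1e-10)
      expect_equal(dl$q_stat, ref2$QE, tolerance = 1e-10)
      expect_equal(dl$p_het, ref2$QEp, tolerance = 1e-10)
    }
  }
})

test_that("heterogeneity matches a brute-force direct summation", {
  tables <- list(tab2x2(20, 30, 25, 25, "a"), tab2x2(35, 15, 30, 20, "b"),
                 tab2x2(12, 40, 22, 30, "c"))
  w <- woolf_oracle(tables)
  wt <- 1 / w$se^2
  mu <- sum(wt * w$y) / sum(wt)
  q <- sum(wt * (w$y - mu)^2)
  tau2 <- max(0, (q - 2) / (sum(wt) - sum(wt^2) / sum(wt)))

  h <- heterogeneity(tables)
  expect_equal(h$q_stat, q, tolerance = 1e-12)
  expect_equal(h$df, 2L)
  expect_equal(h$p_het, pchisq(q, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(h$i2, max(0, 100 * (q - 2) / q), tolerance = 1e-12)
  expect_equal(h$tau2, tau2, tolerance = 1e-12)

  wr <- 1 / (w$se^2 + tau2)
  expect_equal(log(pool_random_dl(tables)$or), sum(wr * w$y) / sum(wr),
               tolerance = 1e-12)

  # identical studies are perfectly homogeneous
  same <- list(tab2x2(20, 30, 25, 25, "a"), tab2x2(20, 30, 25, 25, "b"))
  h0 <- heterogeneity(same)
  expect_equal(h0$q_stat, 0, tolerance = 1e-12)
  expect_equal(h0$p_het, 1)
  expect_equal(h0$i2, 0)

  # a single study has no heterogeneity to measure; flagged degenerate
  h1 <- heterogeneity(list(tab2x2(20, 30, 25, 25)))
  expect_true(h1$degenerate)
  expect_equal(c(h1$q_stat, h1$df, h1$i2), c(0, 0, 0))
})

test_that("homogeneous studies make DL collapse onto fixed inverse-variance", {
  tables <- list(tab2x2(20, 30, 25, 25, "a"), tab2x2(21, 29, 24, 26, "b"),
                 tab2x2(19, 31, 26, 24, "c"))
  h <- heterogeneity(tables)
  expect_lte(h$q_stat, h$df)
  expect_equal(h$tau2, 0)
  expect_equal(pool_random_dl(tables)$or, pool_fixed_iv(tables)$or,
               tolerance = 1e-12)
  expect_error(pool_random_dl(list(tab2x2(1, 2, 3, 4))), "at least 2")
})

test_that("method selection is driven by the I-squared threshold", {
  expect_equal(select_method(49.999), "fixed")
  expect_equal(select_method(50), "random")
  expect_equal(select_method(0), "fixed")
  ds <- fixture()
  expect_equal(select_method(heterogeneity(contrast_tables(ds, "-670 A/G", "allele"))),
               "fixed")
  expect_equal(select_method(heterogeneity(contrast_tables(ds, "-670 A/G", "dominant"))),
               "random")
})

test_that("fixed pooling stays inside the per-study range and respects reciprocity", {
  ds <- fixture()
  for (snp in c("-670 A/G", "124 A/G", "-844 C/T")) {
    for (model in genetic_models()) {
      tables <- contrast_tables(ds, snp, model)
      ors <- sapply(lapply(tables, estimate_effect), `[[`, "or")
      p <- pool_fixed_mh(tables)
      expect_gte(p$or, min(ors))
      expect_lte(p$or, max(ors))
      # swapping case and control arms inverts the pooled OR exactly
      swapped <- pool_fixed_mh(lapply(tables, swap_arms))
      expect_equal(p$or * swapped$or, 1, tolerance = 1e-12)
      # MH and inverse-variance fixed agree closely; the 9-study SNP with
      # its larger cells agrees to 1%, the 2-3 study SNPs (single-digit
      # homozygote cells) to 3%
      tol <- if (snp == "-670 A/G") 0.01 else 0.03
      expect_equal(p$or / pool_fixed_iv(tables)$or, 1, tolerance = tol)
    }
  }
})
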