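# Hardy-Weinberg equilibrium screening of control genotype counts.
# Deviation from HWE in controls flags genotyping error or non-random
# sampling; flagged studies are reported, not excluded from pooling.

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts against the proportions
#' \eqn{(1-q)^2, 2q(1-q), q^2} expected under random mating at the observed
#' allele-2 frequency \eqn{q}. Plain Pearson chi-square on 1 df (3 classes
#' minus 1 estimated allele frequency minus 1), no continuity correction.
#'
#' @param g [genotype_counts] (or a length-3 count vector), normally a control
#'   arm.
#' @param alpha Significance level for the `in_hwe` flag (default 0.05).
#' @return An `hwe_result`: list with `allele2_freq`, `chi2`, `df`, `p_value`,
#'   `in_hwe`, and `monomorphic`. A monomorphic arm (q of 0 or 1) has no
#'   degrees of freedom to test; it is returned as `chi2 = 0`, `in_hwe = TRUE`
#'   with `monomorphic = TRUE` and a warning.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE: chi2 = 0, p = 1
#' @export
hwe_test <- function(g, alpha = 0.05) {
  g <- as_genotype_counts(g)
  n <- sum(g)
  q <- (2 * g[["n22"]] + g[["n12"]]) / (2 * n)
  monomorphic <- q == 0 || q == 1
  if (monomorphic) {
    warning("monomorphic arm: Hardy-Weinberg test is degenerate", call. = FALSE)
    chi2 <- 0
    p <- 1
  } else {
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((as.numeric(g) - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(allele2_freq = q, chi2 = chi2, df = 1L, p_value = p,
                 in_hwe = p >= alpha, monomorphic = monomorphic),
            class = "hwe_result")
}

#' Hardy-Weinberg screen of every control arm in a dataset
#'
#' @param ds A `snp_dataset`.
#' @param alpha Significance level passed to [hwe_test()].
#' @return A data.frame with one row per record: `snp`, `study_id`,
#'   `allele2_freq`, `chi2`, `p_value`, `in_hwe`.
#' @export
hwe_screen <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "snp_dataset"))
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    h <- hwe_test(arm_counts(ds, i, "ctrl"), alpha = alpha)
    data.frame(snp = ds$snp[i], study_id = ds$study_id[i],
               allele2_freq = h$allele2_freq, chi2 = h$chi2,
               p_value = h$p_value, in_hwe = h$in_hwe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE: q = %.3f, chi2(1) = %.3f, p = %.4f -> %s%s\n",
              x$allele2_freq, x$chi2, x$p_value,
              if (x$in_hwe) "in HWE" else "NOT in HWE",
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}
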