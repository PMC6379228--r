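# End-to-end driver: HWE screen -> contrasts -> per-study effects ->
# heterogeneity -> method selection -> pooling -> subgroups -> leave-one-out
# -> publication bias, collected into one report object with TSV/JSON/
# markdown writers and a forest-plot data table.

pooled_row <- function(snp, model, stratum, p, egger = NULL, begg = NULL) {
  data.frame(
    snp = snp, model = model, stratum = stratum, k = p$k, method = p$method,
    or = p$or, ci_low = p$ci_low, ci_high = p$ci_high, z = p$z,
    p_value = p$p_value, q_stat = p$q_stat, df = p$df, p_het = p$p_het,
    i2 = p$i2, tau2 = p$tau2,
    egger_p = if (is.null(egger)) NA_real_ else egger$p,
    begg_p = if (is.null(begg)) NA_real_ else begg$p,
    stringsAsFactors = FALSE
  )
}

effect_rows <- function(snp, model, p) {
  do.call(rbind, lapply(p$estimates, function(e) {
    data.frame(snp = snp, model = model, study_id = e$study_id,
               or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
               log_or = e$log_or, se = e$se, corrected = e$corrected,
               weight = unname(p$weights[e$study_id]),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full meta-analysis pipeline
#'
#' For every requested SNP and genetic model: Hardy-Weinberg screen of the
#' control arms, per-study odds ratios, Cochran's Q / I-squared,
#' I-squared-driven choice of Mantel-Haenszel fixed or DerSimonian-Laird
#' random pooling, subgroup analyses, leave-one-out sensitivity, and Egger +
#' Begg publication-bias tests (when at least 3 studies are available).
#' A SNP with a single study is passed through as its own estimate, flagged
#' `method = "single"` and never pooled.
#'
#' @param x A `snp_dataset` or a path readable by [read_study_table()].
#' @param snps SNP labels to analyse (default: all in the data).
#' @param models Genetic models to analyse (default: all five).
#' @param subgroup_by Zero or more of `"soc"`, `"method"`.
#' @param i2_threshold I-squared threshold (percent) for method selection.
#' @param subgroup_method Pooling method inside subgroups, as in
#'   [subgroup_analysis()].
#' @return An `analysis_report`: list with `results` (one row per
#'   snp/model/stratum; strata are `"total"`, `"soc:HB"`, ...), `effects`
#'   (per-study ORs and pooled weights for the total analyses), `hwe`
#'   (control-arm screen), `sensitivity` (leave-one-out rows), and `meta`
#'   (package version, record counts). Deterministic for a fixed input.
#' @examples
#' rep <- run_analysis(fas_fasl_preeclampsia(), snps = "-670 A/G",
#'                     models = "allele")
#' rep$results[, c("stratum", "k", "method", "or", "ci_low", "ci_high")]
#' @export
run_analysis <- function(x, snps = NULL, models = genetic_models(),
                         subgroup_by = c("soc", "method"), i2_threshold = 50,
                         subgroup_method = "auto") {
  ds <- if (inherits(x, "snp_dataset")) x else read_study_table(x)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  subgroup_by <- if (length(subgroup_by)) {
    match.arg(subgroup_by, c("soc", "method"), several.ok = TRUE)
  } else {
    character(0)
  }
  if (is.null(snps)) snps <- unique(ds$snp)
  missing_snps <- setdiff(snps, ds$snp)
  if (length(missing_snps) > 0) {
    stop(sprintf("no records for SNP(s): %s", paste(missing_snps, collapse = ", ")),
         call. = FALSE)
  }
  results <- list()
  effects <- list()
  sens <- list()
  for (snp in snps) {
    sub <- ds[ds$snp == snp, , drop = FALSE]
    k <- nrow(sub)
    for (model in models) {
      tables <- contrast_tables(sub, model = model)
      total <- pool_auto(tables, i2_threshold = i2_threshold)
      egger <- if (k >= 3) egger_test(tables) else NULL
      begg <- if (k >= 3) begg_test(tables) else NULL
      results[[length(results) + 1]] <-
        pooled_row(snp, model, "total", total, egger, begg)
      effects[[length(effects) + 1]] <- effect_rows(snp, model, total)
      if (k >= 2) {
        for (by in subgroup_by) {
          sg <- subgroup_analysis(sub, snp, model, by = by,
                                  method = subgroup_method,
                                  i2_threshold = i2_threshold)
          for (lv in names(sg)) {
            results[[length(results) + 1]] <-
              pooled_row(snp, model, paste(by, lv, sep = ":"), sg[[lv]])
          }
        }
        loo <- sensitivity_loo(sub, snp, model, i2_threshold = i2_threshold)
        loo <- cbind(data.frame(snp = snp, model = model,
                                stringsAsFactors = FALSE), loo)
        sens[[length(sens) + 1]] <- loo
      }
    }
  }
  tot <- total_sample_sizes(ds[ds$snp %in% snps, , drop = FALSE])
  structure(list(
    results = do.call(rbind, results),
    effects = do.call(rbind, effects),
    hwe = hwe_screen(ds[ds$snp %in% snps, , drop = FALSE]),
    sensitivity = if (length(sens)) do.call(rbind, sens) else NULL,
    meta = list(package = "genemeta",
                version = as.character(utils::packageVersion("genemeta")),
                schema = 1L, n_records = nrow(ds[ds$snp %in% snps, ]),
                n_cases = unname(tot["cases"]),
                n_controls = unname(tot["controls"]),
                i2_threshold = i2_threshold)
  ), class = "analysis_report")
}

fmt_p <- function(p) ifelse(is.na(p), "-",
                     ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))

#' Write an analysis report
#'
#' `"tsv"` writes the `results` table at full precision; `"json"` serializes
#' the whole report (versioned schema, full precision) and round-trips through
#' [read_report()]; `"md"` renders a human-readable table with odds ratios to
#' 2 decimals and p-values to 3 (values below 0.001 shown as `<0.001`).
#'
#' @param r An `analysis_report`.
#' @param path Output file.
#' @param format `"tsv"`, `"json"`, or `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(r, path, format = c("tsv", "json", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(r, "analysis_report"))
  if (format == "tsv") {
    utils::write.table(r$results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "json") {
    jsonlite::write_json(unclass(r), path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  } else {
    res <- r$results
    lines <- c(
      "| SNP | Model | Stratum | k | Method | OR (95% CI) | P | P het | I2 |",
      "|---|---|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %d | %s | %.2f (%.2f, %.2f) | %s | %s | %.0f%% |",
              res$snp, res$model, res$stratum, res$k, res$method,
              res$or, res$ci_low, res$ci_high,
              fmt_p(res$p_value),
              ifelse(res$method == "single", "-", fmt_p(res$p_het)),
              res$i2))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path A file written by [write_report()] with `format = "json"`.
#' @return An `analysis_report` equal (up to numeric serialization precision)
#'   to the one written.
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (tab in c("results", "effects", "hwe", "sensitivity")) {
    if (!is.null(r[[tab]])) r[[tab]] <- as.data.frame(r[[tab]])
  }
  structure(r, class = "analysis_report")
}

#' Forest-plot data table
#'
#' Per-study odds ratios, confidence limits and normalized pooled weights for
#' one SNP/model, followed by the pooled summary row (`study_id = "pooled"`),
#' ready for external plotting.
#'
#' @param r An `analysis_report` containing the requested analysis.
#' @param snp SNP label.
#' @param model Genetic model.
#' @return A data.frame with columns `study_id`, `or`, `ci_low`, `ci_high`,
#'   `weight`.
#' @export
forest_data <- function(r, snp, model) {
  stopifnot(inherits(r, "analysis_report"))
  eff <- r$effects[r$effects$snp == snp & r$effects$model == model, , drop = FALSE]
  tot <- r$results[r$results$snp == snp & r$results$model == model &
                   r$results$stratum == "total", , drop = FALSE]
  if (nrow(tot) != 1) {
    stop(sprintf("analysis for %s / %s not in this report", snp, model),
         call. = FALSE)
  }
  out <- rbind(
    data.frame(study_id = eff$study_id, or = eff$or, ci_low = eff$ci_low,
               ci_high = eff$ci_high, weight = eff$weight,
               stringsAsFactors = FALSE),
    data.frame(study_id = "pooled", or = tot$or, ci_low = tot$ci_low,
               ci_high = tot$ci_high, weight = 1, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> genemeta %s: %d record(s), %d analysis row(s)\n",
              x$meta$version, x$meta$n_records, nrow(x$results)))
  tot <- x$results[x$results$stratum == "total", , drop = FALSE]
  cat(sprintf("  %s | %s model | k=%d | %s | OR %.2f (%.2f, %.2f) | p %s | p_het %s\n",
              tot$snp, tot$model, tot$k, tot$method, tot$or, tot$ci_low,
              tot$ci_high, fmt_p(tot$p_value),
              ifelse(tot$method == "single", "-", fmt_p(tot$p_het))), sep = "")
  invisible(x)
}
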