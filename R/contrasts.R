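# Genetic-model contrasts: collapse three genotype classes into the 2x2
# exposed/unexposed x case/control table each model implies. Exposure is
# always defined with respect to allele 2 (the risk allele), so odds ratios
# above 1 mean risk from the variant.

#' The five genetic models
#'
#' @return Character vector of the model names understood by
#'   [build_contrast()]: `"allele"` (allele 2 vs allele 1, each subject
#'   contributing two alleles), `"dominant"` (carriers 22+12 vs 11),
#'   `"recessive"` (22 vs 12+11), `"homozygote"` (22 vs 11, heterozygotes
#'   dropped) and `"heterozygote"` (12 vs 11, variant homozygotes dropped).
#' @export
genetic_models <- function() {
  c("allele", "dominant", "recessive", "homozygote", "heterozygote")
}

#' Build the 2x2 contrast table for one genetic model
#'
#' @param case,control [genotype_counts] (or length-3 count vectors) for the
#'   case and control arms.
#' @param model One of [genetic_models()].
#' @param study_id Optional label carried through to downstream results.
#' @return A `contrast_table`: list with exposed cases `a`, unexposed cases
#'   `b`, exposed controls `c`, unexposed controls `d`, plus `model` and
#'   `study_id`. Zero cells are legal here; they are handled when effects are
#'   estimated.
#' @examples
#' build_contrast(c(8, 29, 13), c(46, 68, 28), "allele")  # (55, 45, 124, 160)
#' @export
build_contrast <- function(case, control,
                           model = genetic_models(), study_id = NA_character_) {
  model <- match.arg(model)
  case <- as_genotype_counts(case)
  control <- as_genotype_counts(control)
  split2 <- function(g) {
    switch(model,
      allele       = c(2 * g[["n22"]] + g[["n12"]], 2 * g[["n11"]] + g[["n12"]]),
      dominant     = c(g[["n22"]] + g[["n12"]], g[["n11"]]),
      recessive    = c(g[["n22"]], g[["n12"]] + g[["n11"]]),
      homozygote   = c(g[["n22"]], g[["n11"]]),
      heterozygote = c(g[["n12"]], g[["n11"]])
    )
  }
  ca <- split2(case)
  co <- split2(control)
  structure(list(a = ca[1], b = ca[2], c = co[1], d = co[2],
                 model = model, study_id = study_id),
            class = "contrast_table")
}

#' Contrast tables for every record of one SNP
#'
#' @param ds A `snp_dataset`.
#' @param snp SNP label to select (`NULL` keeps all records).
#' @param model One of [genetic_models()].
#' @return List of `contrast_table`, one per record, in dataset order.
#' @export
contrast_tables <- function(ds, snp = NULL, model = genetic_models()) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "snp_dataset"))
  if (!is.null(snp)) ds <- ds[ds$snp == snp, , drop = FALSE]
  lapply(seq_len(nrow(ds)), function(i) {
    build_contrast(arm_counts(ds, i, "case"), arm_counts(ds, i, "ctrl"),
                   model, study_id = ds$study_id[i])
  })
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("2x2 contrast (%s model%s)\n", x$model,
              if (is.na(x$study_id)) "" else paste0(", ", x$study_id)))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"), c("exposed", "unexposed")))
  print(m)
  invisible(x)
}
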