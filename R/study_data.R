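# Study tables: one row per study x SNP, case and control genotype counts
# plus the metadata used for subgrouping and quality bookkeeping.

STUDY_TABLE_COLS <- c(
  "study_id", "author", "year", "nationality", "gene", "snp",
  "allele1", "allele2", "method", "soc", "ethnicity",
  "case_11", "case_12", "case_22", "ctrl_11", "ctrl_12", "ctrl_22",
  "nos_sel", "nos_comp", "nos_exp"
)
COUNT_COLS <- c("case_11", "case_12", "case_22", "ctrl_11", "ctrl_12", "ctrl_22")
SOC_LEVELS <- c("HB", "PB")
METHOD_LEVELS <- c("PCR-RFLP", "PCR")

#' Genotype counts for one arm of one study
#'
#' A validated triple of genotype counts: `n11` homozygotes for allele 1
#' (reference), `n12` heterozygotes, `n22` homozygotes for allele 2 (the risk
#' allele under test).
#'
#' @param n11,n12,n22 Non-negative integer counts; their sum (the arm's sample
#'   size) must be at least 1.
#' @return An object of class `genotype_counts`: a named integer vector with
#'   elements `n11`, `n12`, `n22`.
#' @examples
#' genotype_counts(8, 30, 12)  # the 50 preeclampsia cases of one study
#' @export
genotype_counts <- function(n11, n12, n22) {
  g <- c(n11 = n11, n12 = n12, n22 = n22)
  if (length(g) != 3L || anyNA(g) || !is.numeric(g)) {
    stop("genotype counts must be three numbers (n11, n12, n22)", call. = FALSE)
  }
  if (any(g < 0) || any(g != round(g))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  if (sum(g) < 1) {
    stop("genotype counts must total at least 1", call. = FALSE)
  }
  structure(as.integer(round(g)), names = names(g), class = "genotype_counts")
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  x <- unname(unlist(x))
  genotype_counts(x[1], x[2], x[3])
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts: 11=%d 12=%d 22=%d (n=%d)\n",
              x[["n11"]], x[["n12"]], x[["n22"]], sum(x)))
  invisible(x)
}

validate_study_table <- function(df, file = "<data.frame>") {
  missing_cols <- setdiff(STUDY_TABLE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("study table %s is missing required column(s): %s",
                 file, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[STUDY_TABLE_COLS]
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("row %s: %s", paste(rows, collapse = ","), what))
    }
  }
  for (col in COUNT_COLS) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    note(which(is.na(v) | v < 0 | v != round(v)),
         sprintf("%s must be a non-negative integer", col))
    df[[col]] <- as.integer(round(v))
  }
  if (nrow(df) > 0) {
    note(which(df$case_11 + df$case_12 + df$case_22 < 1), "empty case arm")
    note(which(df$ctrl_11 + df$ctrl_12 + df$ctrl_22 < 1), "empty control arm")
    note(which(!df$soc %in% SOC_LEVELS),
         sprintf("soc must be one of %s", paste(SOC_LEVELS, collapse = "/")))
    note(which(!df$method %in% METHOD_LEVELS),
         sprintf("method must be one of %s", paste(METHOD_LEVELS, collapse = "/")))
    note(which(df$allele1 == df$allele2), "allele1 and allele2 must differ")
    note(which(df$nos_sel < 0 | df$nos_sel > 4), "nos_sel outside [0,4]")
    note(which(df$nos_comp < 0 | df$nos_comp > 2), "nos_comp outside [0,2]")
    note(which(df$nos_exp < 0 | df$nos_exp > 3), "nos_exp outside [0,3]")
    dup <- duplicated(paste(df$snp, df$study_id, sep = "\r"))
    note(which(dup), "duplicate study_id within one SNP")
  }
  if (length(problems) > 0) {
    stop(sprintf("invalid study table %s:\n  %s", file,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  df$year <- as.integer(df$year)
  rownames(df) <- NULL
  class(df) <- c("snp_dataset", "data.frame")
  df
}

#' Read a study table of genotype counts
#'
#' Reads a comma- (default) or tab-separated table with one row per study
#' x SNP and validates it. Required columns: `study_id`, `author`, `year`,
#' `nationality`, `gene`, `snp`, `allele1`, `allele2`, `method` (`PCR-RFLP`
#' or `PCR`), `soc` (`HB` hospital-based or `PB` population-based),
#' `ethnicity`, the six genotype counts `case_11`, `case_12`, `case_22`,
#' `ctrl_11`, `ctrl_12`, `ctrl_22`, and the Newcastle-Ottawa quality
#' components `nos_sel` (0-4), `nos_comp` (0-2), `nos_exp` (0-3).
#'
#' @param path Path to the table.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return A validated `snp_dataset` (a `data.frame` with the columns above,
#'   row order preserved).
#' @seealso [write_study_table()], [fas_fasl_preeclampsia()]
#' @export
read_study_table <- function(path, sep = c(",", "\t")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = TRUE,
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  validate_study_table(df, file = path)
}

#' Write a study table
#'
#' Writes a dataset back in the same dialect [read_study_table()] reads, so a
#' round trip reproduces every count and label exactly.
#'
#' @param ds A `snp_dataset`.
#' @param path Output path.
#' @param sep Field separator, as in [read_study_table()].
#' @return `path`, invisibly.
#' @export
write_study_table <- function(ds, path, sep = c(",", "\t")) {
  sep <- match.arg(sep)
  stopifnot(inherits(ds, "snp_dataset"))
  utils::write.table(as.data.frame(ds)[STUDY_TABLE_COLS], path, sep = sep,
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged Fas/FasL preeclampsia dataset
#'
#' Genotype counts and study metadata for the published case-control studies
#' of four Fas and FasL promoter polymorphisms in preeclampsia: 9 study arms
#' for Fas -670 A/G (834 cases, 1072 controls), 3 for FasL 124 A/G, 2 for
#' FasL -844 C/T, and 1 for Fas -1377 G/A. The two Sziller case arms share a
#' single control series, stored duplicated because each arm is its own unit
#' of analysis. The `method` column carries the genotyping-method
#' stratification used in the pooled analysis.
#'
#' @return A validated `snp_dataset` with 15 rows.
#' @examples
#' ds <- fas_fasl_preeclampsia()
#' total_sample_sizes(ds, snp = "-670 A/G")
#' @export
fas_fasl_preeclampsia <- function() {
  read_study_table(system.file("extdata", "fas_fasl_preeclampsia.csv",
                               package = "genemeta", mustWork = TRUE))
}

#' Total case and control sample sizes
#'
#' Sums genotype counts over all records (optionally restricted to one SNP).
#' Each record contributes both of its arms, so a control series shared by two
#' case arms is counted once per record -- the convention used when study arms
#' are the unit of analysis.
#'
#' @param ds A `snp_dataset`.
#' @param snp Optional SNP label to filter on.
#' @return Named integer vector `c(cases = ..., controls = ...)`.
#' @export
total_sample_sizes <- function(ds, snp = NULL) {
  stopifnot(inherits(ds, "snp_dataset"))
  if (!is.null(snp)) ds <- ds[ds$snp == snp, , drop = FALSE]
  c(cases = sum(ds$case_11 + ds$case_12 + ds$case_22),
    controls = sum(ds$ctrl_11 + ds$ctrl_12 + ds$ctrl_22))
}

#' Extract one arm's genotype counts from a dataset row
#'
#' @param ds A `snp_dataset`.
#' @param i Row index.
#' @param arm `"case"` or `"ctrl"`.
#' @return A [genotype_counts] object.
#' @export
arm_counts <- function(ds, i, arm = c("case", "ctrl")) {
  arm <- match.arg(arm)
  cols <- paste0(arm, c("_11", "_12", "_22"))
  genotype_counts(ds[[cols[1]]][i], ds[[cols[2]]][i], ds[[cols[3]]][i])
}

#' @export
print.snp_dataset <- function(x, ...) {
  tot <- total_sample_sizes(x)
  cat(sprintf("<snp_dataset> %d record(s), %d SNP(s), %d cases / %d controls\n",
              nrow(x), length(unique(x$snp)), tot[["cases"]], tot[["controls"]]))
  print(as.data.frame(x), ...)
  invisible(x)
}
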