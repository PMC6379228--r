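# Synthetic multi-study genotype data with known truth, for estimator
# validation (coverage, bias, type-I error of the Q test).

#' Configuration for the genotype-data simulator
#'
#' Defines the truth a simulated meta-analysis is drawn from. The defaults
#' mirror a realistic promoter-SNP meta-analysis: nine balanced studies of
#' 150 cases / 150 controls, control risk-allele frequency 0.30, allelic odds
#' ratio 1.5, and no between-study heterogeneity.
#'
#' @param k Number of studies.
#' @param n_case,n_control Per-study sample sizes; scalars are recycled to
#'   length `k`.
#' @param q0 Control risk-allele frequency, strictly inside (0, 1).
#' @param true_allelic_or True allelic odds ratio (> 0); injected on the
#'   allele-odds scale, so dominant/recessive truths are implied by it.
#' @param tau Between-study standard deviation of the study log-OR (>= 0).
#' @param seed Optional integer seed; identical seeds give identical datasets.
#' @param soc_probs,method_probs Named probabilities used to assign the
#'   `soc` (`HB`/`PB`) and `method` (`PCR-RFLP`/`PCR`) metadata.
#' @param snp,gene,allele1,allele2 Labels for the simulated SNP.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k = 9, n_case = 150, n_control = 150, q0 = 0.3,
                       true_allelic_or = 1.5, tau = 0, seed = NULL,
                       soc_probs = c(HB = 8 / 9, PB = 1 / 9),
                       method_probs = c("PCR-RFLP" = 2 / 3, "PCR" = 1 / 3),
                       snp = "sim A/G", gene = "simGene",
                       allele1 = "A", allele2 = "G") {
  stopifnot(k >= 1, q0 > 0, q0 < 1, true_allelic_or > 0, tau >= 0)
  n_case <- rep_len(as.integer(n_case), k)
  n_control <- rep_len(as.integer(n_control), k)
  stopifnot(all(n_case >= 1), all(n_control >= 1))
  for (p in list(soc_probs, method_probs)) {
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("soc_probs and method_probs must be named and sum to 1", call. = FALSE)
    }
  }
  if (!setequal(names(soc_probs), SOC_LEVELS) ||
      !setequal(names(method_probs), METHOD_LEVELS)) {
    stop("soc_probs must name HB/PB and method_probs PCR-RFLP/PCR", call. = FALSE)
  }
  structure(list(k = k, n_case = n_case, n_control = n_control, q0 = q0,
                 true_allelic_or = true_allelic_or, tau = tau, seed = seed,
                 soc_probs = soc_probs, method_probs = method_probs,
                 snp = snp, gene = gene, allele1 = allele1, allele2 = allele2),
            class = "sim_config")
}

#' Simulate a multi-study case-control genotype dataset
#'
#' For each study i the log odds ratio is drawn as
#' \eqn{\theta_i = \log(OR) + N(0, \tau^2)}; the case allele frequency follows
#' on the odds scale, \eqn{q_{1i} = q_0 e^{\theta_i} / (1 - q_0 + q_0
#' e^{\theta_i})}, which keeps it inside (0, 1) for any finite \eqn{\theta_i}.
#' Genotype counts are multinomial under Hardy-Weinberg proportions at
#' \eqn{q_0} (controls) and \eqn{q_{1i}} (cases). All draws come from one
#' seeded stream in fixed study order, so a seed pins down the whole dataset.
#'
#' @param cfg A [sim_config()].
#' @return A validated `snp_dataset` with `k` records for one simulated SNP.
#' @examples
#' ds <- simulate_dataset(sim_config(k = 3, seed = 1))
#' pool_auto(contrast_tables(ds, model = "allele"))
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  theta <- log(cfg$true_allelic_or) + stats::rnorm(cfg$k, 0, cfg$tau)
  odds0 <- cfg$q0 / (1 - cfg$q0)
  q1 <- odds0 * exp(theta) / (1 + odds0 * exp(theta))
  if (any(!is.finite(q1)) || any(q1 <= 0) || any(q1 >= 1)) {
    stop("degenerate case allele frequency; check q0/true_allelic_or/tau",
         call. = FALSE)
  }
  case <- vapply(seq_len(cfg$k),
                 function(i) stats::rmultinom(1, cfg$n_case[i], hwe_probs(q1[i]))[, 1],
                 numeric(3))
  ctrl <- vapply(seq_len(cfg$k),
                 function(i) stats::rmultinom(1, cfg$n_control[i], hwe_probs(cfg$q0))[, 1],
                 numeric(3))
  soc <- sample(names(cfg$soc_probs), cfg$k, replace = TRUE, prob = cfg$soc_probs)
  method <- sample(names(cfg$method_probs), cfg$k, replace = TRUE,
                   prob = cfg$method_probs)
  df <- data.frame(
    study_id = sprintf("sim_%02d", seq_len(cfg$k)),
    author = sprintf("Simulated %02d", seq_len(cfg$k)),
    year = 2020L, nationality = "simulated", gene = cfg$gene, snp = cfg$snp,
    allele1 = cfg$allele1, allele2 = cfg$allele2,
    method = method, soc = soc, ethnicity = "simulated",
    case_11 = case[1, ], case_12 = case[2, ], case_22 = case[3, ],
    ctrl_11 = ctrl[1, ], ctrl_12 = ctrl[2, ], ctrl_22 = ctrl[3, ],
    nos_sel = 3L, nos_comp = 1L, nos_exp = 2L,
    stringsAsFactors = FALSE
  )
  validate_study_table(df, file = "<simulated>")
}
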