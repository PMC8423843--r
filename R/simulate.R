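#' Configuration for the GWAS summary-statistic generator
#'
#' Defines the generative truth for a two-sample MR simulation: per-SNP
#' exposure effects and allele frequencies, non-overlapping exposure and
#' outcome samples, a true causal effect, and an optional horizontal
#' pleiotropy regime. Defaults emulate the study design the estimators are
#' aimed at: ~50 strong instruments measured in GWA studies of about 100,000
#' participants each.
#'
#' @param n_snps number of instruments; default 50.
#' @param n_exposure,n_outcome GWA sample sizes; default 1e5 each.
#' @param true_effect causal effect of exposure on outcome (log-odds per
#'   exposure unit when `binary_outcome`); default 0.
#' @param pleiotropy_mode one of "none", "balanced" (zero-mean direct SNP
#'   effects on the outcome for every SNP), "directional" (mean-shifted
#'   effects on an invalid fraction) or "correlated" (invalid-fraction
#'   effects proportional to instrument strength, violating InSIDE).
#' @param pleiotropy_sd,pleiotropy_mean scale and location of the pleiotropic
#'   effects; defaults 0.01 and 0.
#' @param prop_invalid fraction of instruments carrying pleiotropy under the
#'   directional/correlated modes; default 0.3.
#' @param var_explained_range range of per-SNP variance in the exposure
#'   explained by an instrument (uniform); default c(0.003, 0.006),
#'   matching the roughly 0.3-0.6% per instrument that consortium-scale
#'   GWA instruments for anthropometric and metabolic traits explain
#'   (per-SNP F around 300-600 at the default sample sizes). True effect
#'   sizes follow as beta = sqrt(v / (2 p (1 - p))).
#' @param eaf_range range of effect allele frequencies (uniform);
#'   default c(0.1, 0.9).
#' @param mediation optional list(beta_em, beta_mo, beta_direct,
#'   n_mediator) describing an exposure -> mediator -> outcome chain.
#' @param binary_outcome simulate a binary outcome (log-odds effects)?
#' @param case_fraction case fraction for a binary outcome; default 0.05.
#' @param seed RNG seed; mandatory.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, n_exposure = 1e5, n_outcome = 1e5,
                       true_effect = 0,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "correlated"),
                       pleiotropy_sd = 0.01, pleiotropy_mean = 0,
                       prop_invalid = 0.3,
                       var_explained_range = c(0.003, 0.006),
                       eaf_range = c(0.1, 0.9),
                       mediation = NULL, binary_outcome = FALSE,
                       case_fraction = 0.05, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, n_exposure > 0, n_outcome > 0,
            prop_invalid >= 0, prop_invalid <= 1,
            case_fraction > 0, case_fraction < 1)
  if (!is.null(mediation)) {
    need <- c("beta_em", "beta_mo", "beta_direct")
    if (!all(need %in% names(mediation))) {
      stop("mediation config needs beta_em, beta_mo, beta_direct",
           call. = FALSE)
    }
    mediation$n_mediator <- mediation$n_mediator %||% n_exposure
  }
  structure(list(n_snps = n_snps, n_exposure = n_exposure,
                 n_outcome = n_outcome, true_effect = true_effect,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 prop_invalid = prop_invalid,
                 var_explained_range = var_explained_range,
                 eaf_range = eaf_range,
                 mediation = mediation,
                 binary_outcome = isTRUE(binary_outcome),
                 case_fraction = case_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# Standard-error model: continuous traits on a standardized scale have
# se = sqrt(1 / (2 p (1-p) n)); binary traits on the log-odds scale pick up
# the 1 / (v (1 - v)) variance inflation for case fraction v.
se_model <- function(eaf, n, binary = FALSE, case_fraction = 0.05) {
  base <- 1 / (2 * eaf * (1 - eaf) * n)
  if (binary) base <- base / (case_fraction * (1 - case_fraction))
  sqrt(base)
}

# Non-palindromic allele pairs only, so harmonization never drops simulated
# instruments by strand ambiguity.
draw_alleles <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
}

assoc_from_draws <- function(ids, alleles, eaf, beta_hat, se, n, trait,
                             is_binary = FALSE, n_cases = NULL) {
  association_set(data.frame(variant_id = ids,
                             effect_allele = alleles[, 1],
                             other_allele = alleles[, 2],
                             eaf = eaf, beta = beta_hat, se = se,
                             pval = 2 * stats::pnorm(-abs(beta_hat / se)),
                             n = n, stringsAsFactors = FALSE),
                  trait = trait, is_binary = is_binary, sample_size = n,
                  n_cases = n_cases)
}

#' Simulate a two-sample MR dataset
#'
#' Draws per-SNP true exposure effects and allele frequencies, adds sampling
#' noise at the exposure study's size, then builds the outcome study's
#' effects as true_effect * beta + alpha (alpha per the pleiotropy mode)
#' plus sampling noise at the outcome study's size. The two samples are
#' non-overlapping by construction (independent noise draws).
#'
#' @param cfg a [sim_config()].
#' @param truth optional truth table from a previous run (columns `eaf`,
#'   `beta_true`, `alpha`, `alleles.1`, `alleles.2`), reused so that only
#'   the sampling noise is redrawn.
#' @return List with `exposure` and `outcome` [association_set()]s and the
#'   `truth` data frame.
#' @export
simulate_two_sample <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    k <- cfg$n_snps
    ids <- sprintf("rs%05d", seq_len(k))
    if (is.null(truth)) {
      eaf <- stats::runif(k, cfg$eaf_range[1], cfg$eaf_range[2])
      v <- stats::runif(k, cfg$var_explained_range[1],
                        cfg$var_explained_range[2])
      beta_true <- sqrt(v / (2 * eaf * (1 - eaf)))
      alleles <- draw_alleles(k)
      alpha <- numeric(k)
      if (cfg$pleiotropy_mode == "balanced") {
        alpha <- stats::rnorm(k, 0, cfg$pleiotropy_sd)
      } else if (cfg$pleiotropy_mode == "directional") {
        invalid <- sample.int(k, round(cfg$prop_invalid * k))
        alpha[invalid] <- stats::rnorm(length(invalid), cfg$pleiotropy_mean,
                                       cfg$pleiotropy_sd)
      } else if (cfg$pleiotropy_mode == "correlated") {
        invalid <- sample.int(k, round(cfg$prop_invalid * k))
        scaled <- beta_true[invalid] / mean(beta_true)
        alpha[invalid] <- cfg$pleiotropy_mean * scaled +
          stats::rnorm(length(invalid), 0, cfg$pleiotropy_sd)
      }
      truth <- data.frame(variant_id = ids, eaf = eaf, beta_true = beta_true,
                          alpha = alpha, ea = alleles[, 1], oa = alleles[, 2],
                          stringsAsFactors = FALSE)
    }
    alleles <- cbind(truth$ea, truth$oa)
    se_exp <- se_model(truth$eaf, cfg$n_exposure)
    beta_hat_exp <- truth$beta_true + stats::rnorm(k, 0, se_exp)
    se_out <- se_model(truth$eaf, cfg$n_outcome, cfg$binary_outcome,
                       cfg$case_fraction)
    beta_out_true <- cfg$true_effect * truth$beta_true + truth$alpha
    beta_hat_out <- beta_out_true + stats::rnorm(k, 0, se_out)
    n_cases <- if (cfg$binary_outcome) {
      as.integer(round(cfg$case_fraction * cfg$n_outcome))
    } else NULL
    list(exposure = assoc_from_draws(truth$variant_id, alleles, truth$eaf,
                                     beta_hat_exp, se_exp, cfg$n_exposure,
                                     "simulated exposure"),
         outcome = assoc_from_draws(truth$variant_id, alleles, truth$eaf,
                                    beta_hat_out, se_out, cfg$n_outcome,
                                    "simulated outcome",
                                    is_binary = cfg$binary_outcome,
                                    n_cases = n_cases),
         truth = truth)
  })
}

#' Simulate a mediation system: exposure, mediator and outcome studies
#'
#' Generates three consistent summary-statistic sets from the path model
#' exposure -> mediator (beta_em), mediator -> outcome (beta_mo) and a
#' residual direct path exposure -> outcome (beta_direct). Instruments for
#' the exposure and for the mediator are disjoint SNP sets (half of
#' `n_snps` each by default); every SNP's effect on every trait follows the
#' path algebra, so the total effect is beta_direct + beta_em * beta_mo by
#' construction.
#'
#' @param cfg a [sim_config()] with a `mediation` component.
#' @return List with `exposure`, `mediator`, `outcome`
#'   [association_set()]s and the `truth` table.
#' @export
simulate_mediation_system <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  med <- cfg$mediation
  if (is.null(med)) stop("cfg$mediation is absent", call. = FALSE)
  with_seed(cfg$seed, {
    k_e <- ceiling(cfg$n_snps / 2)
    k_m <- cfg$n_snps - k_e
    k <- k_e + k_m
    ids <- sprintf("rs%05d", seq_len(k))
    is_e <- seq_len(k) <= k_e
    eaf <- stats::runif(k, cfg$eaf_range[1], cfg$eaf_range[2])
    v <- stats::runif(k, cfg$var_explained_range[1],
                      cfg$var_explained_range[2])
    gamma <- sqrt(v / (2 * eaf * (1 - eaf)))
    alleles <- draw_alleles(k)

    # Path algebra: exposure instruments act on E directly; mediator
    # instruments act on M directly and are assumed not to feed back on E.
    beta_e <- ifelse(is_e, gamma, 0)
    beta_m <- ifelse(is_e, med$beta_em * gamma, gamma)
    beta_o <- med$beta_direct * beta_e + med$beta_mo * beta_m

    se_e <- se_model(eaf, cfg$n_exposure)
    se_m <- se_model(eaf, med$n_mediator)
    se_o <- se_model(eaf, cfg$n_outcome, cfg$binary_outcome,
                     cfg$case_fraction)
    hat_e <- beta_e + stats::rnorm(k, 0, se_e)
    hat_m <- beta_m + stats::rnorm(k, 0, se_m)
    hat_o <- beta_o + stats::rnorm(k, 0, se_o)
    n_cases <- if (cfg$binary_outcome) {
      as.integer(round(cfg$case_fraction * cfg$n_outcome))
    } else NULL
    truth <- data.frame(variant_id = ids, instrument_for =
                          ifelse(is_e, "exposure", "mediator"),
                        eaf = eaf, beta_e = beta_e, beta_m = beta_m,
                        beta_o = beta_o, stringsAsFactors = FALSE)
    list(exposure = assoc_from_draws(ids, alleles, eaf, hat_e, se_e,
                                     cfg$n_exposure, "simulated exposure"),
         mediator = assoc_from_draws(ids, alleles, eaf, hat_m, se_m,
                                     med$n_mediator, "simulated mediator"),
         outcome = assoc_from_draws(ids, alleles, eaf, hat_o, se_o,
                                    cfg$n_outcome, "simulated outcome",
                                    is_binary = cfg$binary_outcome,
                                    n_cases = n_cases),
         truth = truth)
  })
}

#' Simulate an LD-score panel with two genetically correlated traits
#'
#' Draws right-skewed LD scores (1 + gamma), per-SNP joint true effects from
#' a bivariate normal with covariance proportional to the SNP's LD score
#' (variances h2 * l / m, covariance rg * sqrt(h2_1 h2_2) * l / m) and
#' z-scores sqrt(n) * effect + standard normal noise, independent between
#' traits (non-overlapping samples). The implied regression structure is
#' E[chi2] = 1 + n h2 l / m.
#'
#' @param m_snps number of SNPs; default 20000.
#' @param h2_1,h2_2 SNP heritabilities in [0, 1]; default 0.17 each.
#' @param rg_true genetic correlation, |rg| <= 1; default 0.25.
#' @param n1,n2 GWA sample sizes; default 1e5.
#' @param seed RNG seed; mandatory.
#' @return List with `panel` ([ld_score_panel()]), `z1`, `z2`.
#' @export
simulate_ldsc_panel <- function(m_snps = 20000, h2_1 = 0.17, h2_2 = 0.17,
                                rg_true = 0.25, n1 = 1e5, n2 = 1e5, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1, abs(rg_true) <= 1)
  with_seed(seed, {
    l <- 1 + stats::rgamma(m_snps, shape = 1.5, scale = 40)
    gencov <- rg_true * sqrt(h2_1 * h2_2)
    # Per-SNP bivariate true effects via the Cholesky factor of the 2x2
    # covariance, scaled by sqrt(l / m) per SNP.
    a11 <- sqrt(h2_1)
    a21 <- if (h2_1 > 0) gencov / a11 else 0
    a22 <- sqrt(max(h2_2 - a21^2, 0))
    s <- sqrt(l / m_snps)
    e1 <- stats::rnorm(m_snps)
    e2 <- stats::rnorm(m_snps)
    u1 <- s * a11 * e1
    u2 <- s * (a21 * e1 + a22 * e2)
    z1 <- sqrt(n1) * u1 + stats::rnorm(m_snps)
    z2 <- sqrt(n2) * u2 + stats::rnorm(m_snps)
    list(panel = ld_score_panel(sprintf("rs%06d", seq_len(m_snps)), l),
         z1 = z1, z2 = z2)
  })
}
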