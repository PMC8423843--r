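# Shared fixture builders for the test suite. Everything is constructed in
# code; no data files.

make_assoc <- function(ids, ea, oa, beta, se, eaf = NA_real_,
                       pval = 2 * pnorm(-abs(beta / se)),
                       trait = "trait", is_binary = FALSE,
                       sample_size = 1e5) {
  association_set(data.frame(variant_id = ids, effect_allele = ea,
                             other_allele = oa, eaf = eaf, beta = beta,
                             se = se, pval = pval,
                             stringsAsFactors = FALSE),
                  trait = trait, is_binary = is_binary,
                  sample_size = sample_size)
}

# A harmonized fixture with exact, hand-chosen Wald ratios.
make_harmonized <- function(ratio, se_wald, beta_exp = NULL, se_exp = 0.005,
                            binary = FALSE) {
  n <- length(ratio)
  if (is.null(beta_exp)) beta_exp <- rep(0.1, n)
  harmonized_set(variant_id = sprintf("snp%02d", seq_len(n)),
                 beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
                 beta_out = ratio * beta_exp,
                 se_out = se_wald * abs(beta_exp),
                 outcome_binary = binary)
}

# Independent weighted-least-squares oracle for IVW (regression of beta_out
# on beta_exp through the origin, weights se_out^-2), via stats::lm.
ivw_wls_oracle <- function(h) {
  r <- harmonized_rows(h)
  fit <- lm(beta_out ~ 0 + beta_exp, data = r, weights = r$se_out^-2)
  s <- summary(fit)
  sigma <- s$sigma
  se_unscaled <- s$coefficients[1, 2] / sigma
  q <- sigma^2 * fit$df.residual
  list(beta = unname(coef(fit)[1]), se_fixed = se_unscaled, q = q,
       df = fit$df.residual)
}

subset_assoc_ids <- function(x, ids) {
  association_set(as.data.frame(x)[x$variant_id %in% ids, , drop = FALSE],
                  trait = attr(x, "trait"),
                  is_binary = attr(x, "is_binary"),
                  sample_size = attr(x, "sample_size"))
}
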