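#' Construct an MR estimate
#'
#' Wraps a point estimate with its standard error, 95% confidence interval
#' and p-value. Confidence bounds are beta -/+ 1.96 se; the p-value reference
#' is normal except where a method's convention is Student t (MR-Egger, with
#' n - 2 degrees of freedom). For a binary outcome the estimate is on the
#' log-odds scale and odds-ratio fields are populated by exponentiation.
#'
#' @param method method label.
#' @param beta point estimate (log-odds for binary outcomes).
#' @param se standard error, > 0.
#' @param n_snps number of instruments behind the estimate.
#' @param binary is the outcome binary?
#' @param dist reference distribution for the p-value.
#' @param df degrees of freedom when `dist = "t"`.
#' @return List of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, n_snps, binary = FALSE,
                        dist = c("normal", "t"), df = NULL) {
  dist <- match.arg(dist)
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  crit <- stats::qnorm(0.975)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  z <- beta / se
  pval <- if (dist == "t") 2 * stats::pt(-abs(z), df = df)
          else 2 * stats::pnorm(-abs(z))
  out <- list(method = method, beta = beta, se = se,
              ci_low = ci_low, ci_high = ci_high, pval = pval,
              n_snps = as.integer(n_snps), binary = isTRUE(binary))
  if (out$binary) {
    out$odds_ratio <- exp(beta)
    out$or_ci_low <- exp(ci_low)
    out$or_ci_high <- exp(ci_high)
  }
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (isTRUE(x$binary)) {
    cat(sprintf("%s: OR %.3f (95%% CI %.3f, %.3f), p = %.3g [%d SNPs]\n",
                x$method, x$odds_ratio, x$or_ci_low, x$or_ci_high, x$pval,
                x$n_snps))
  } else {
    cat(sprintf("%s: beta %.4f (95%% CI %.4f, %.4f), p = %.3g [%d SNPs]\n",
                x$method, x$beta, x$ci_low, x$ci_high, x$pval,
                x$n_snps))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             odds_ratio = if (isTRUE(x$binary)) x$odds_ratio else NA_real_,
             or_ci_low = if (isTRUE(x$binary)) x$or_ci_low else NA_real_,
             or_ci_high = if (isTRUE(x$binary)) x$or_ci_high else NA_real_,
             stringsAsFactors = FALSE)
}

# Heterogeneity container: Cochran's Q with its chi-square p-value, plus the
# I2GX regression-dilution diagnostic where computed.
heterogeneity_stats <- function(q, df, i_squared_gx = NA_real_) {
  df <- as.integer(df)
  pval <- if (df > 0) stats::pchisq(q, df = df, lower.tail = FALSE)
          else NA_real_
  structure(list(q = q, df = df, pval = pval, i_squared_gx = i_squared_gx),
            class = "heterogeneity_stats")
}

#' @export
print.heterogeneity_stats <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g)", x$q, x$df, x$pval))
  if (!is.na(x$i_squared_gx)) cat(sprintf("; I2GX = %.3f", x$i_squared_gx))
  cat("\n")
  invisible(x)
}
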