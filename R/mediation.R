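#' Indirect effect by the product of coefficients, with delta-method SE
#'
#' Multiplies the exposure-to-mediator effect by the mediator-to-outcome
#' effect. The standard error is the first-order delta approximation
#' sqrt(beta_em^2 se_mo^2 + beta_mo^2 se_em^2); the two legs come from
#' non-overlapping samples, so their covariance is taken as zero, and the
#' second-order se_em^2 se_mo^2 term is omitted. For a binary outcome both
#' the mediator-outcome effect and the product live on the log-odds scale
#' and odds ratios are obtained by exponentiation.
#'
#' @param beta_em,se_em exposure -> mediator effect and its SE.
#' @param beta_mo,se_mo mediator -> outcome effect (log-odds if the outcome
#'   is binary) and its SE.
#' @param binary is the outcome binary?
#' @return [mr_estimate()] with method "indirect (product of coefficients)".
#' @export
product_of_coefficients <- function(beta_em, se_em, beta_mo, se_mo,
                                    binary = FALSE) {
  stopifnot(se_em > 0, se_mo > 0)
  beta <- beta_em * beta_mo
  se <- sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)
  if (se == 0) se <- .Machine$double.eps     # both legs exactly null
  mr_estimate("indirect (product of coefficients)", beta, se, NA_integer_,
              binary = binary)
}

#' Total/direct/indirect decomposition with consistency classification
#'
#' Combines the total effect (univariable MR of exposure on outcome), the
#' direct effect (multivariable MR of the exposure adjusting for the
#' mediator) and the indirect effect (product of coefficients). Mediation is
#' "consistent" when direct and indirect effects share a sign (an exactly
#' zero effect counts as consistent); only then is a proportion mediated
#' (indirect / total) reported. Opposite signs are "inconsistent mediation"
#' and the proportion is left undefined.
#'
#' @param total,direct,indirect [mr_estimate()]s on a common scale
#'   (all log-odds or all linear).
#' @return List of class `mediation_result` with the three estimates, the
#'   `consistent` flag, `proportion_mediated` (NA when undefined) and a
#'   human-readable `classification`.
#' @export
mediate <- function(total, direct, indirect) {
  for (e in list(total, direct, indirect)) {
    stopifnot(inherits(e, "mr_estimate"))
  }
  scales <- c(total$binary, direct$binary, indirect$binary)
  if (length(unique(scales)) != 1) {
    stop("scale mismatch: total, direct and indirect effects must all be ",
         "log-odds or all linear", call. = FALSE)
  }
  consistent <- sign(direct$beta) * sign(indirect$beta) >= 0
  proportion <- NA_real_
  note <- NULL
  if (consistent) {
    if (abs(total$beta) > 0) {
      proportion <- indirect$beta / total$beta
    } else {
      note <- "total effect is exactly zero; proportion mediated undefined"
    }
  }
  classification <- if (!consistent) {
    "inconsistent mediation (direct and indirect effects of opposite sign); proportion mediated not calculated"
  } else if (is.na(proportion)) {
    note
  } else {
    sprintf("consistent mediation; proportion mediated = %.3f", proportion)
  }
  structure(list(total = total, direct = direct, indirect = indirect,
                 consistent = consistent, proportion_mediated = proportion,
                 classification = classification),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation decomposition\n")
  for (nm in c("total", "direct", "indirect")) {
    cat("  ", nm, ": ", sep = "")
    print(x[[nm]])
  }
  cat("  ", x$classification, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  out <- rbind(as.data.frame(x$total), as.data.frame(x$direct),
               as.data.frame(x$indirect))
  out$effect <- c("total", "direct", "indirect")
  out[, c("effect", setdiff(names(out), "effect"))]
}

#' End-to-end MR mediation analysis from three summary-statistic sets
#'
#' Runs the full decomposition for one exposure -> mediator -> outcome
#' chain: the total effect by univariable IVW of the exposure's instruments
#' on the outcome; the exposure -> mediator and mediator -> outcome legs by
#' univariable IVW (each trait instrumented by its own genome-wide
#' significant SNPs); the direct effect by multivariable IVW of exposure and
#' mediator jointly on the outcome; the indirect effect by the product of
#' coefficients. Radial outlier filtering is applied to each univariable leg
#' when it has enough instruments.
#'
#' @param exposure,mediator,outcome [association_set()]s.
#' @param p_threshold instrument significance threshold; default 5e-8.
#' @param ld optional [ld_matrix()] for clumping.
#' @param radial_alpha outlier threshold passed to [radial_outliers()];
#'   `NULL` disables filtering.
#' @return A [mediate()] result; the leg estimates and MVMR fit are attached
#'   as attributes `legs` and `mvmr`.
#' @export
mediation_analysis <- function(exposure, mediator, outcome,
                               p_threshold = 5e-8, ld = NULL,
                               radial_alpha = 0.05) {
  uni_leg <- function(exp_set, out_set) {
    ids <- suppressWarnings(select_instruments(exp_set, p_threshold, ld))
    h <- harmonize(subset_association(exp_set, ids), out_set)
    if (!is.null(radial_alpha) && nrow(harmonized_rows(h)) >= 3) {
      flt <- radial_outliers(h, alpha = radial_alpha)
      h <- flt$retained
    }
    mr_ivw(wald_ratios(h))$estimate
  }
  total <- uni_leg(exposure, outcome)
  em <- uni_leg(exposure, mediator)
  mo <- uni_leg(mediator, outcome)
  binary <- isTRUE(attr(outcome, "is_binary"))
  indirect <- product_of_coefficients(em$beta, em$se, mo$beta, mo$se,
                                      binary = binary)
  inp <- suppressWarnings(mvmr_input(list(exposure, mediator), outcome,
                                     p_threshold = p_threshold, ld = ld))
  mv <- mvmr_ivw(inp)
  direct <- mv$estimates[[1]]
  res <- mediate(total, direct, indirect)
  attr(res, "legs") <- list(exposure_mediator = em, mediator_outcome = mo)
  attr(res, "mvmr") <- mv
  res
}
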