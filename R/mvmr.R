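#' Assemble the instrument table for multivariable MR
#'
#' Builds the per-variant table of K exposure effects plus the outcome
#' effect, all expressed on one effect allele. The instrument list defaults
#' to the union of each exposure's genome-wide-significant clumped SNPs,
#' restricted to SNPs available in every dataset (missing exposure effects
#' drop the SNP rather than being imputed as zero). Alignment reuses the
#' pairwise harmonization rules, anchored on the first exposure.
#'
#' @param exposures named list of K >= 2 [association_set()]s.
#' @param outcome an [association_set()].
#' @param instruments optional character vector of variant ids; when `NULL`,
#'   the union of per-exposure selections via [select_instruments()].
#' @param p_threshold,ld,r2_threshold,window_kb passed to
#'   [select_instruments()] when `instruments` is `NULL`.
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @return Data frame of class `mvmr_input`: columns `variant_id`,
#'   `beta_exp.<name>`, `se_exp.<name>` for each exposure, `beta_out`,
#'   `se_out`.
#' @export
mvmr_input <- function(exposures, outcome, instruments = NULL,
                       p_threshold = 5e-8, ld = NULL, r2_threshold = 0.001,
                       window_kb = 10000, palindrome_eaf_limit = 0.3) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, attr, "", "trait")
  }
  if (is.null(instruments)) {
    instruments <- unique(unlist(lapply(exposures, function(e) {
      select_instruments(e, p_threshold = p_threshold, ld = ld,
                         r2_threshold = r2_threshold, window_kb = window_kb)
    })))
  }
  anchor <- exposures[[1]]
  sub_anchor <- subset_association(anchor, instruments)
  # Align every other dataset to the anchor's effect alleles.
  harm_out <- harmonized_rows(harmonize(sub_anchor, outcome,
                                        palindrome_eaf_limit))
  tab <- data.frame(variant_id = harm_out$variant_id,
                    stringsAsFactors = FALSE)
  tab[[paste0("beta_exp.", names(exposures)[1])]] <- harm_out$beta_exp
  tab[[paste0("se_exp.", names(exposures)[1])]] <- harm_out$se_exp
  for (k in seq_along(exposures)[-1]) {
    hk <- harmonized_rows(harmonize(sub_anchor, exposures[[k]],
                                    palindrome_eaf_limit))
    idx <- match(tab$variant_id, hk$variant_id)
    tab[[paste0("beta_exp.", names(exposures)[k])]] <- hk$beta_out[idx]
    tab[[paste0("se_exp.", names(exposures)[k])]] <- hk$se_out[idx]
  }
  tab$beta_out <- harm_out$beta_out
  tab$se_out <- harm_out$se_out
  complete <- stats::complete.cases(tab)
  dropped <- sum(!complete)
  tab <- tab[complete, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("mvmr_input", "data.frame"),
            exposure_names = names(exposures),
            outcome_trait = attr(outcome, "trait"),
            outcome_binary = isTRUE(attr(outcome, "is_binary")),
            n_dropped_incomplete = dropped)
}

subset_association <- function(x, ids) {
  out <- as.data.frame(x)[x$variant_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  association_set(out, trait = attr(x, "trait"),
                  is_binary = attr(x, "is_binary"),
                  sample_size = attr(x, "sample_size"),
                  n_cases = attr(x, "n_cases"))
}

#' Multivariable IVW: joint direct effects of several exposures
#'
#' Weighted multiple regression of the outcome effects on the K exposure
#' effect columns without intercept, weights se_out^-2. Coefficient k is the
#' direct effect of exposure k holding the others fixed. Standard errors
#' carry multiplicative inflation max(1, sqrt(Q / (n - K))); p-values are
#' normal.
#'
#' @param inp an [mvmr_input()].
#' @return List of class `mvmr_result`: `estimates` (named list of
#'   [mr_estimate()]s, one per exposure), `n_snps`, `heterogeneity`.
#' @export
mvmr_ivw <- function(inp) {
  stopifnot(inherits(inp, "mvmr_input"))
  ex_names <- attr(inp, "exposure_names")
  K <- length(ex_names)
  n <- nrow(inp)
  if (n <= K) {
    stop("underdetermined: ", n, " instruments for ", K, " exposures",
         call. = FALSE)
  }
  X <- as.matrix(inp[, paste0("beta_exp.", ex_names), drop = FALSE])
  w <- inp$se_out^-2
  fit <- tryCatch(wls_origin(X, inp$beta_out, w), error = function(e) {
    cors <- stats::cor(X)
    culprit <- which(abs(cors) > 0.999 & upper.tri(cors), arr.ind = TRUE)
    extra <- if (nrow(culprit) > 0) {
      paste0(" (collinear exposures: ",
             paste(ex_names[culprit[1, ]], collapse = " ~ "), ")")
    } else ""
    stop("rank-deficient exposure design", extra, call. = FALSE)
  })
  infl <- max(1, sqrt(fit$q / fit$df))
  binary <- isTRUE(attr(inp, "outcome_binary"))
  ests <- lapply(seq_len(K), function(k) {
    mr_estimate(paste0("MVMR-IVW: ", ex_names[k]), fit$beta[k],
                fit$se[k] * infl, n, binary = binary)
  })
  names(ests) <- ex_names
  structure(list(estimates = ests, n_snps = n,
                 heterogeneity = heterogeneity_stats(fit$q, fit$df)),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW on %d instruments\n", x$n_snps))
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, as.data.frame))
}
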