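#' Radial-MR outlier detection by per-variant Cochran's Q
#'
#' In the radial formulation the IVW estimate is the no-intercept regression
#' of ratio_j * sqrt(w_j) on sqrt(w_j) with first-order weights w_j, and
#' Cochran's Q decomposes exactly into per-variant contributions
#' q_j = w_j (ratio_j - slope)^2. Each q_j is referred to chi-square(1);
#' variants with p below `alpha` are flagged as outliers. With
#' `iterate = TRUE` (default) flagged variants are removed and the test
#' repeated until none are flagged (capped at `max_iter` rounds); per-SNP
#' p-values are deliberately not multiplicity-corrected (flat threshold).
#'
#' @param h a `harmonized_set` with at least 3 retained variants.
#' @param alpha per-variant significance threshold; default 0.05.
#' @param iterate repeat removal until no variant is flagged? Default TRUE.
#' @param max_iter cap on removal rounds; default 10.
#' @return List of class `radial_result`: `outliers` (variant ids, in
#'   removal order), `retained` (`harmonized_set` without them), `q_table`
#'   (final per-variant q contribution and p), `global_q`, `estimate`
#'   (radial IVW slope on the retained set) and `iterations`.
#' @export
radial_outliers <- function(h, alpha = 0.05, iterate = TRUE, max_iter = 10) {
  r <- harmonized_rows(h)
  if (nrow(r) < 3) stop("radial filter needs >= 3 instruments", call. = FALSE)
  outliers <- character(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    keep <- !(r$variant_id %in% outliers)
    if (sum(keep) < 3) {
      stop("fewer than 3 instruments remain after outlier removal; ",
           "fall back to per-variant Wald ratios", call. = FALSE)
    }
    cur <- r[keep, , drop = FALSE]
    wj <- cur$beta_exp^2 / cur$se_out^2        # first-order Wald weights
    ratio <- cur$beta_out / cur$beta_exp
    slope <- sum(wj * ratio) / sum(wj)         # radial no-intercept slope
    qj <- wj * (ratio - slope)^2
    pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
    flagged <- cur$variant_id[pj < alpha]
    done <- length(flagged) == 0 || !iterate || iterations >= max_iter
    if (length(flagged) > 0 && iterate && iterations < max_iter) {
      outliers <- c(outliers, flagged)
      next
    }
    if (!iterate && length(flagged) > 0) outliers <- c(outliers, flagged)
    q_table <- data.frame(variant_id = cur$variant_id, q_contribution = qj,
                          pval = pj, flagged = cur$variant_id %in% outliers,
                          stringsAsFactors = FALSE)
    retained_ids <- setdiff(cur$variant_id, outliers)
    retained <- as.data.frame(h)[h$variant_id %in% retained_ids &
                                   h$action %in% c("kept", "flipped"), ,
                                 drop = FALSE]
    rownames(retained) <- NULL
    for (a in c("exposure_trait", "outcome_trait", "outcome_binary")) {
      attr(retained, a) <- attr(h, a)
    }
    attr(retained, "counts") <- attr(h, "counts")
    class(retained) <- c("harmonized_set", "data.frame")
    return(structure(list(outliers = outliers, retained = retained,
                          q_table = q_table, global_q = sum(qj),
                          estimate = slope, iterations = iterations),
                     class = "radial_result"))
  }
}

#' @export
print.radial_result <- function(x, ...) {
  cat(sprintf("Radial MR filter: %d outlier(s) removed in %d round(s); Q = %.3f on %d variants\n",
              length(x$outliers), x$iterations, x$global_q,
              nrow(x$q_table)))
  if (length(x$outliers) > 0) {
    cat("  removed:", paste(x$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}
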