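#' Per-variant Wald ratios with first-order standard errors
#'
#' Each instrument's causal estimate is the ratio of its outcome and exposure
#' associations; its standard error uses first-order weights, se_out over
#' |beta_exp|, which ignores exposure-side sampling noise (adequate for
#' strong instruments, diagnosed downstream by I2GX).
#'
#' @param h a `harmonized_set`; only retained rows are used.
#' @return Data frame of class `wald_ratio_set` with columns `variant_id`,
#'   `ratio`, `se` and `weight` (= se^-2), one row per retained variant.
#' @export
wald_ratios <- function(h) {
  r <- harmonized_rows(h)
  if (nrow(r) == 0) stop("empty harmonized set", call. = FALSE)
  zero <- r$beta_exp == 0
  if (any(zero)) {
    stop("beta_exp is zero for variant(s): ",
         paste(r$variant_id[zero], collapse = ", "),
         "; Wald ratio undefined", call. = FALSE)
  }
  out <- data.frame(variant_id = r$variant_id,
                    ratio = r$beta_out / r$beta_exp,
                    se = r$se_out / abs(r$beta_exp),
                    stringsAsFactors = FALSE)
  out$weight <- out$se^-2
  structure(out, class = c("wald_ratio_set", "data.frame"),
            outcome_binary = isTRUE(attr(h, "outcome_binary")))
}

#' Inverse-variance weighted meta-analysis of Wald ratios
#'
#' Fixed-effect IVW pooling, algebraically identical to weighted least
#' squares of beta_out on beta_exp through the origin with weights se_out^-2.
#' When Cochran's Q exceeds its degrees of freedom the standard error is
#' inflated by sqrt(Q / df) (multiplicative random effects); it is never
#' deflated below the fixed-effect value. A single variant degrades to its
#' Wald ratio with a message.
#'
#' @param w a `wald_ratio_set`.
#' @return List with elements `estimate` ([mr_estimate()], method "IVW") and
#'   `heterogeneity` (Q, df, p).
#' @export
mr_ivw <- function(w) {
  stopifnot(inherits(w, "wald_ratio_set"))
  n <- nrow(w)
  if (n == 0) stop("empty Wald ratio set", call. = FALSE)
  binary <- isTRUE(attr(w, "outcome_binary"))
  if (n == 1) {
    message("single instrument: IVW degrades to the Wald ratio")
    est <- mr_estimate("Wald", w$ratio, w$se, 1L, binary = binary)
    return(list(estimate = est, heterogeneity = heterogeneity_stats(0, 0L)))
  }
  sw <- sum(w$weight)
  beta <- sum(w$weight * w$ratio) / sw
  se_fixed <- sqrt(1 / sw)
  q <- sum(w$weight * (w$ratio - beta)^2)
  df <- n - 1L
  se <- se_fixed * max(1, sqrt(q / df))
  list(estimate = mr_estimate("IVW", beta, se, n, binary = binary),
       heterogeneity = heterogeneity_stats(q, df))
}

# Orient exposure effects positive (flipping outcome effects jointly), the
# convention MR-Egger needs so that its intercept is identified.
orient_positive <- function(r) {
  flip <- r$beta_exp < 0
  r$beta_out[flip] <- -r$beta_out[flip]
  r$beta_exp[flip] <- -r$beta_exp[flip]
  r
}

# I2GX: proportion of variance in the observed SNP-exposure effects not
# attributable to their sampling error; values well below 1 flag regression
# dilution of the Egger slope.
i_squared_gx <- function(beta_exp, se_exp) {
  wx <- se_exp^-2
  xbar <- sum(wx * beta_exp) / sum(wx)
  q_gx <- sum(wx * (beta_exp - xbar)^2)
  if (q_gx <= 0) return(0)
  max(0, (q_gx - (length(beta_exp) - 1)) / q_gx)
}

#' MR-Egger regression with intercept test and I2GX
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept, weights se_out^-2, exposure effects oriented positive. The
#' slope is the pleiotropy-robust causal estimate; the intercept estimates
#' average directional pleiotropy (its test: intercept consistent with zero).
#' Standard errors carry the multiplicative residual inflation
#' max(1, sqrt(Q / (n - 2))) and p-values use Student t on n - 2 degrees of
#' freedom, the method's convention.
#'
#' @param h a `harmonized_set` with at least 3 retained variants.
#' @return List with `slope` and `intercept` ([mr_estimate()]s) and
#'   `heterogeneity` (Q on n - 2 df, plus I2GX).
#' @export
mr_egger <- function(h) {
  r <- orient_positive(harmonized_rows(h))
  n <- nrow(r)
  if (n < 3) stop("insufficient instruments for Egger regression (need >= 3)",
                  call. = FALSE)
  binary <- isTRUE(attr(h, "outcome_binary"))
  w <- r$se_out^-2
  fit <- wls_line(r$beta_exp, r$beta_out, w)
  infl <- max(1, sqrt(fit$q / fit$df))
  slope <- mr_estimate("MR-Egger", fit$slope, fit$se_slope * infl, n,
                       binary = binary, dist = "t", df = fit$df)
  intercept <- mr_estimate("Egger-intercept", fit$intercept,
                           fit$se_intercept * infl, n,
                           dist = "t", df = fit$df)
  het <- heterogeneity_stats(fit$q, fit$df,
                             i_squared_gx(r$beta_exp, r$se_exp))
  list(slope = slope, intercept = intercept, heterogeneity = het)
}

#' SIMEX correction of the MR-Egger slope
#'
#' Simulation extrapolation for the regression dilution that measurement
#' error in the SNP-exposure effects induces in the Egger slope: noise of
#' variance lambda * se_exp^2 is added to the exposure effects at each
#' inflation factor lambda, the Egger slope re-estimated over `b_reps`
#' replicates, a quadratic in lambda fitted through the mean slopes (the
#' naive fit serving as lambda = 0), and the fit extrapolated to lambda = -1.
#' The standard error comes from a delete-one jackknife over replicates.
#'
#' @param h a `harmonized_set`.
#' @param lambdas noise inflation factors; default c(0, 0.5, 1, 1.5, 2).
#' @param b_reps simulation replicates per lambda; default 1000, refuse
#'   below 50 (extrapolation too unstable).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return [mr_estimate()] with method "MR-Egger (SIMEX)"; the per-lambda
#'   mean slopes in `attr(, "lambda_fit")`.
#' @export
mr_simex_egger <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2), b_reps = 1000,
                           seed) {
  if (b_reps < 50) stop("b_reps < 50: SIMEX extrapolation would be unstable",
                        call. = FALSE)
  if (missing(seed)) stop("seed is mandatory for SIMEX", call. = FALSE)
  lambdas <- sort(unique(c(0, lambdas)))
  r <- orient_positive(harmonized_rows(h))
  n <- nrow(r)
  if (n < 3) stop("insufficient instruments for Egger regression (need >= 3)",
                  call. = FALSE)
  binary <- isTRUE(attr(h, "outcome_binary"))
  w <- r$se_out^-2
  naive <- wls_line(r$beta_exp, r$beta_out, w)$slope

  egger_slope <- function(bx) {
    flip <- bx < 0
    wls_line(abs(bx), ifelse(flip, -r$beta_out, r$beta_out), w)$slope
  }
  pos <- lambdas[lambdas > 0]
  slopes <- with_seed(seed, {
    vapply(pos, function(l) {
      vapply(seq_len(b_reps), function(b) {
        egger_slope(r$beta_exp + stats::rnorm(n, 0, sqrt(l) * r$se_exp))
      }, numeric(1))
    }, numeric(b_reps))
  })                                         # b_reps x length(pos)
  slopes <- cbind(`0` = rep(naive, b_reps), slopes)
  colnames(slopes) <- as.character(lambdas)

  extrapolate <- function(means) {
    fit <- stats::lm.fit(cbind(1, lambdas, lambdas^2), means)
    sum(fit$coefficients * c(1, -1, 1))      # evaluate at lambda = -1
  }
  theta <- extrapolate(colMeans(slopes))
  # Delete-one jackknife over paired replicates.
  colsums <- colSums(slopes)
  theta_b <- vapply(seq_len(b_reps), function(b) {
    extrapolate((colsums - slopes[b, ]) / (b_reps - 1))
  }, numeric(1))
  se <- sqrt((b_reps - 1) / b_reps * sum((theta_b - mean(theta_b))^2))
  se <- max(se, .Machine$double.eps)
  est <- mr_estimate("MR-Egger (SIMEX)", theta, se, n, binary = binary,
                     dist = "t", df = n - 2)
  attr(est, "lambda_fit") <- data.frame(lambda = lambdas,
                                        mean_slope = colMeans(slopes))
  est
}

# Interpolated weighted median of ratios at cumulative probability 0.5.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' The interpolated weighted median of the Wald ratios: consistent as long
#' as less than half the total weight comes from invalid instruments. The
#' standard error comes from a parametric bootstrap that redraws each ratio
#' from Normal(ratio_j, se_j) and recomputes the median.
#'
#' @param w a `wald_ratio_set` with at least 3 variants.
#' @param boot_reps bootstrap replicates; default 1000. `0` skips the
#'   bootstrap and returns only the point estimate (se = NA).
#' @param seed RNG seed (mandatory when bootstrapping).
#' @return [mr_estimate()] with method "weighted-median".
#' @export
mr_weighted_median <- function(w, boot_reps = 1000, seed) {
  stopifnot(inherits(w, "wald_ratio_set"))
  n <- nrow(w)
  if (n < 3) stop("weighted median needs >= 3 instruments", call. = FALSE)
  if (all(w$weight == 0)) stop("all weights are zero", call. = FALSE)
  binary <- isTRUE(attr(w, "outcome_binary"))
  est <- weighted_median_point(w$ratio, w$weight)
  if (boot_reps == 0) {
    out <- list(method = "weighted-median", beta = est, se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                n_snps = n, binary = binary)
    if (binary) out$odds_ratio <- exp(est)
    return(structure(out, class = "mr_estimate"))
  }
  if (missing(seed)) stop("seed is mandatory for the bootstrap", call. = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(boot_reps), function(b) {
      weighted_median_point(stats::rnorm(n, w$ratio, w$se), w$weight)
    }, numeric(1))
  })
  mr_estimate("weighted-median", est, stats::sd(boots), n, binary = binary)
}

# Kernel-smoothed weighted density mode of the ratios.
weighted_mode_point <- function(ratio, weight, phi = 1, grid_n = 512) {
  n <- length(ratio)
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.349
  bw <- phi * 0.9 * min(s, iqr) * n^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(NULL)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = grid_n)
  wn <- weight / sum(weight)
  dens <- vapply(grid, function(g) {
    sum(wn * stats::dnorm((g - ratio) / bw))
  }, numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode MR estimate
#'
#' The mode of the inverse-variance-weighted, kernel-smoothed empirical
#' density of the Wald ratios (normal kernel, modified Silverman bandwidth
#' phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)): consistent when the largest
#' group of instruments sharing one ratio is valid. Standard error by the
#' same parametric bootstrap as the weighted median. If every ratio is
#' identical the bandwidth degenerates and the common ratio is returned with
#' the IVW standard error (logged).
#'
#' @param w a `wald_ratio_set` with at least 3 variants.
#' @param phi bandwidth multiplier; default 1.
#' @param boot_reps bootstrap replicates; default 1000 (`0` = point only).
#' @param seed RNG seed (mandatory when bootstrapping).
#' @return [mr_estimate()] with method "weighted-mode".
#' @export
mr_weighted_mode <- function(w, phi = 1, boot_reps = 1000, seed) {
  stopifnot(inherits(w, "wald_ratio_set"), phi > 0)
  n <- nrow(w)
  if (n < 3) stop("weighted mode needs >= 3 instruments", call. = FALSE)
  binary <- isTRUE(attr(w, "outcome_binary"))
  est <- weighted_mode_point(w$ratio, w$weight, phi)
  if (is.null(est)) {
    message("all ratios identical: returning the common ratio with IVW se")
    ivw <- mr_ivw(w)
    return(mr_estimate("weighted-mode", w$ratio[1], ivw$estimate$se, n,
                       binary = binary))
  }
  if (boot_reps == 0) {
    out <- list(method = "weighted-mode", beta = est, se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                n_snps = n, binary = binary)
    if (binary) out$odds_ratio <- exp(est)
    return(structure(out, class = "mr_estimate"))
  }
  if (missing(seed)) stop("seed is mandatory for the bootstrap", call. = FALSE)
  boots <- with_seed(seed, {
    vapply(seq_len(boot_reps), function(b) {
      m <- weighted_mode_point(stats::rnorm(n, w$ratio, w$se), w$weight, phi)
      if (is.null(m)) w$ratio[1] else m
    }, numeric(1))
  })
  mr_estimate("weighted-mode", est, stats::sd(boots), n, binary = binary)
}
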