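#' LD-score panel
#'
#' Holds the regressor side of LD-score regression: one LD score per SNP
#' (the sum of squared correlations with nearby SNPs, hence >= 1 from the
#' self term) and the total SNP count `m_total` used as the heritability
#' denominator.
#'
#' @param variant_ids character vector of M SNP ids.
#' @param ld_scores numeric vector of per-SNP LD scores, all >= 1.
#' @param m_total denominator SNP count; defaults to M.
#' @return List of class `ld_score_panel`.
#' @export
ld_score_panel <- function(variant_ids, ld_scores, m_total = length(ld_scores)) {
  stopifnot(length(variant_ids) == length(ld_scores))
  if (any(ld_scores < 1)) {
    stop("LD scores must be >= 1 (each SNP tags itself)", call. = FALSE)
  }
  structure(list(variant_ids = as.character(variant_ids),
                 ld_scores = as.numeric(ld_scores),
                 m_total = m_total),
            class = "ld_score_panel")
}

# Delete-one-block jackknife machinery for OLS slopes of y on x with
# intercept, shared by the univariate and cross-trait regressions. Returns
# the full-sample slope and the vector of leave-one-block-out slopes.
block_jackknife_slopes <- function(x, ys, n_blocks) {
  m <- length(x)
  block <- cut(seq_len(m), breaks = n_blocks, labels = FALSE)
  sums <- function(v) vapply(split(v, block), sum, numeric(1))
  bx <- sums(x); bxx <- sums(x^2); bn <- tabulate(block, n_blocks)
  tx <- sum(bx); txx <- sum(bxx)
  lapply(ys, function(y) {
    by <- sums(y); bxy <- sums(x * y)
    ty <- sum(by); txy <- sum(bxy)
    slope_from <- function(n, sx, sy, sxx, sxy) {
      (sxy - sx * sy / n) / (sxx - sx^2 / n)
    }
    full <- slope_from(m, tx, ty, txx, txy)
    loo <- slope_from(m - bn, tx - bx, ty - by, txx - bxx, txy - bxy)
    list(full = full, loo = loo)
  })
}

jackknife_se <- function(loo) {
  g <- length(loo)
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

resolve_blocks <- function(m, n_blocks) {
  if (m < 50) stop("too few SNPs for LD-score regression (need >= 50)",
                   call. = FALSE)
  if (m < 2 * n_blocks) {
    n_blocks <- floor(m / 2)
    warning("fewer than 2 SNPs per jackknife block; reducing to ",
            n_blocks, " blocks", call. = FALSE)
  }
  n_blocks
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP chi-square statistics (z^2) on LD scores with a free
#' intercept; the slope times m_total / n is the observed-scale SNP
#' heritability. Uncertainty by delete-one block jackknife over contiguous
#' SNP blocks. Homoskedastic OLS is used throughout (no heteroskedasticity
#' weights), a documented simplification.
#'
#' @param z per-SNP z-scores, aligned with the panel.
#' @param panel an [ld_score_panel()].
#' @param n GWA study sample size.
#' @param n_blocks jackknife blocks; default 200, reduced (with a warning)
#'   when the panel is small.
#' @return List with `h2`, `se`, `intercept`, `n_blocks`.
#' @export
estimate_h2 <- function(z, panel, n, n_blocks = 200) {
  stopifnot(inherits(panel, "ld_score_panel"), n > 0)
  m <- length(panel$ld_scores)
  if (length(z) != m) stop("z length must match the panel", call. = FALSE)
  n_blocks <- resolve_blocks(m, n_blocks)
  fit <- block_jackknife_slopes(panel$ld_scores, list(z^2), n_blocks)[[1]]
  scale <- panel$m_total / n
  chi2 <- z^2
  intercept <- mean(chi2) - fit$full * mean(panel$ld_scores)
  list(h2 = fit$full * scale, se = jackknife_se(fit$loo) * scale,
       intercept = intercept, n_blocks = n_blocks)
}

#' Cross-trait genetic correlation by LD-score regression
#'
#' Regresses the per-SNP z-score products on LD scores (free intercept,
#' expected near zero for non-overlapping samples); the slope times
#' m_total / sqrt(n1 n2) is the genetic covariance, and rg = gencov /
#' sqrt(h2_1 h2_2). The standard error and p-value jackknife the full rg
#' statistic (all three regressions recomputed per deleted block), so the
#' correlation between numerator and denominators is respected.
#'
#' @param z1,z2 per-SNP z-scores for the two traits, aligned with the panel.
#' @param panel an [ld_score_panel()].
#' @param n1,n2 the two GWA sample sizes.
#' @param n_blocks jackknife blocks; default 200.
#' @return List of class `genetic_correlation`: `h2_trait1`, `h2_trait2`
#'   (each with se), `gencov`, `gencov_se`, `rg`, `rg_se`, `pval`,
#'   `n_blocks`; `rg` is NA with a `reason` when either heritability
#'   estimate is non-positive.
#' @export
estimate_rg <- function(z1, z2, panel, n1, n2, n_blocks = 200) {
  stopifnot(inherits(panel, "ld_score_panel"), n1 > 0, n2 > 0)
  m <- length(panel$ld_scores)
  if (length(z1) != m || length(z2) != m) {
    stop("z-score lengths must match the panel", call. = FALSE)
  }
  n_blocks <- resolve_blocks(m, n_blocks)
  fits <- block_jackknife_slopes(panel$ld_scores,
                                 list(z1^2, z2^2, z1 * z2), n_blocks)
  s1 <- panel$m_total / n1
  s2 <- panel$m_total / n2
  sx <- panel$m_total / sqrt(n1 * n2)
  h2_1 <- fits[[1]]$full * s1
  h2_2 <- fits[[2]]$full * s2
  gencov <- fits[[3]]$full * sx
  out <- list(h2_trait1 = h2_1, h2_se_trait1 = jackknife_se(fits[[1]]$loo) * s1,
              h2_trait2 = h2_2, h2_se_trait2 = jackknife_se(fits[[2]]$loo) * s2,
              gencov = gencov, gencov_se = jackknife_se(fits[[3]]$loo) * sx,
              n_blocks = n_blocks)
  if (h2_1 <= 0 || h2_2 <= 0) {
    out$rg <- NA_real_
    out$rg_se <- NA_real_
    out$pval <- NA_real_
    out$reason <- "a heritability estimate is non-positive; rg undefined"
    return(structure(out, class = "genetic_correlation"))
  }
  rg_from <- function(a, b, c) c * sx / sqrt(pmax(a * s1, 1e-12) *
                                               pmax(b * s2, 1e-12))
  rg <- gencov / sqrt(h2_1 * h2_2)
  rg_loo <- rg_from(fits[[1]]$loo, fits[[2]]$loo, fits[[3]]$loo)
  rg_se <- jackknife_se(rg_loo)
  out$rg <- rg
  out$rg_se <- rg_se
  out$pval <- 2 * stats::pnorm(-abs(rg / rg_se))
  if (abs(rg) > 1) {
    warning("|rg| exceeds 1 (sampling noise in the heritability estimates)",
            call. = FALSE)
  }
  structure(out, class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("h2 (trait 1) = %.3f (se %.3f); h2 (trait 2) = %.3f (se %.3f)\n",
              x$h2_trait1, x$h2_se_trait1, x$h2_trait2, x$h2_se_trait2))
  if (is.na(x$rg)) {
    cat("rg undefined:", x$reason, "\n")
  } else {
    cat(sprintf("rg = %.3f (se %.3f), p = %.3g [%d jackknife blocks]\n",
                x$rg, x$rg_se, x$pval, x$n_blocks))
  }
  invisible(x)
}
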