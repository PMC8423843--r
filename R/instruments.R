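#' Read a square LD matrix of pairwise r-squared values
#'
#' Expects a tab-delimited file whose header row lists the variant ids and
#' whose body is the square matrix of squared correlations.
#'
#' @param path file path.
#' @return An `ld_matrix`: the numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- read_tsv_file(path)
  m <- as.matrix(raw)
  rownames(m) <- colnames(m)
  ld_matrix(m)
}

#' Validate an LD matrix
#'
#' @param r2 square numeric matrix of pairwise squared correlations with
#'   variant ids as column names; must be symmetric with unit diagonal and
#'   entries in [0, 1].
#' @return The validated matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(r2) {
  r2 <- as.matrix(r2)
  if (is.null(colnames(r2))) stop("LD matrix needs variant ids as colnames",
                                  call. = FALSE)
  rownames(r2) <- colnames(r2)
  if (nrow(r2) != ncol(r2) || !isSymmetric(unname(r2), tol = 1e-8)) {
    stop("LD matrix must be square and symmetric", call. = FALSE)
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("LD matrix diagonal must be 1",
                                          call. = FALSE)
  if (any(r2 < -1e-8 | r2 > 1 + 1e-8)) {
    stop("LD r-squared values must lie in [0, 1]", call. = FALSE)
  }
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Select independent genome-wide-significant instruments by greedy clumping
#'
#' Significant SNPs are ranked by ascending p-value (ties broken
#' lexicographically by variant id, so reruns are deterministic) and accepted
#' greedily: a SNP enters the instrument set iff its r-squared with every
#' already-accepted SNP within `window_kb` (all accepted SNPs when positions
#' are absent) stays below `r2_threshold`. Without an LD matrix all
#' significant SNPs pass, with a warning that independence is assumed (the
#' situation for LD-free simulated instruments).
#'
#' @param exposure an [association_set()].
#' @param p_threshold genome-wide significance threshold; default 5e-8.
#' @param ld an [ld_matrix()] or `NULL`.
#' @param r2_threshold maximum pairwise r-squared; default 0.001.
#' @param window_kb clumping window in kilobases; default 10000.
#' @return Character vector of selected variant ids; the per-SNP audit
#'   (p-value, decision, blocking SNP) in `attr(, "audit")`.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(exposure, "association_set"))
  sig <- as.data.frame(exposure)[exposure$pval < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    stop("no instruments: no variant reaches p < ",
         format(p_threshold), call. = FALSE)
  }
  ord <- order(sig$pval, sig$variant_id)
  sig <- sig[ord, , drop = FALSE]

  if (is.null(ld)) {
    warning("no LD matrix supplied: all ", nrow(sig),
            " significant SNPs retained, pairwise independence assumed",
            call. = FALSE)
    audit <- data.frame(variant_id = sig$variant_id, pval = sig$pval,
                        accepted = TRUE, blocked_by = NA_character_,
                        stringsAsFactors = FALSE)
    return(structure(sig$variant_id, audit = audit))
  }

  has_pos <- "pos" %in% names(sig) && !anyNA(sig$pos)
  accepted <- character(0)
  blocked_by <- rep(NA_character_, nrow(sig))
  take <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    id <- sig$variant_id[i]
    rivals <- accepted
    if (has_pos && length(rivals) > 0) {
      dist_kb <- abs(sig$pos[match(rivals, sig$variant_id)] - sig$pos[i]) / 1000
      rivals <- rivals[dist_kb <= window_kb]
    }
    rivals <- rivals[rivals %in% colnames(ld) & id %in% colnames(ld)]
    r2 <- if (length(rivals) > 0) ld[id, rivals] else numeric(0)
    if (all(r2 < r2_threshold)) {
      accepted <- c(accepted, id)
      take[i] <- TRUE
    } else {
      blocked_by[i] <- rivals[which.max(r2)]
    }
  }
  audit <- data.frame(variant_id = sig$variant_id, pval = sig$pval,
                      accepted = take, blocked_by = blocked_by,
                      stringsAsFactors = FALSE)
  structure(accepted, audit = audit)
}

#' Variance explained and F-statistic of an instrument set
#'
#' Per-SNP variance explained uses the standardized-trait approximation
#' 2 p (1 - p) beta^2 with p the effect allele frequency; the instrument
#' R-squared is their sum and the F-statistic is
#' R2 (N - k - 1) / ((1 - R2) k). F > 10 is the usual adequacy rule of
#' thumb.
#'
#' @param harmonized a `harmonized_set` (its retained rows are used).
#' @param eafs optional named numeric vector of effect allele frequencies
#'   overriding the set's `eaf_exp` column.
#' @param sample_size exposure GWA study sample size.
#' @return List of class `instrument_strength` with `r_squared`,
#'   `f_statistic`, `n_snps`, `sample_size`.
#' @export
instrument_strength <- function(harmonized, eafs = NULL, sample_size) {
  h <- harmonized_rows(harmonized)
  eaf <- h$eaf_exp
  if (!is.null(eafs)) eaf <- unname(eafs[h$variant_id])
  if (anyNA(eaf)) {
    stop("effect allele frequency missing for variant(s): ",
         paste(h$variant_id[is.na(eaf)], collapse = ", "),
         "; R-squared from standardized betas needs per-SNP eaf",
         call. = FALSE)
  }
  k <- nrow(h)
  r2 <- sum(2 * eaf * (1 - eaf) * h$beta_exp^2)
  if (r2 >= 1) {
    stop("instrument R-squared >= 1; betas are not on a standardized scale",
         call. = FALSE)
  }
  f <- r2 * (sample_size - k - 1) / ((1 - r2) * k)
  structure(list(r_squared = r2, f_statistic = f, n_snps = k,
                 sample_size = sample_size),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: R2 = %.4f, F = %.1f (%d SNPs, N = %s)\n",
              x$r_squared, x$f_statistic, x$n_snps, format(x$sample_size)))
  invisible(x)
}
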