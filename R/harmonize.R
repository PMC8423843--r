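#' Harmonize exposure and outcome summary statistics to one effect allele
#'
#' For every variant present in both studies, re-expresses the outcome
#' association on the exposure study's effect allele. Alleles that match are
#' kept; swapped alleles (outcome effect allele equals the exposure's other
#' allele, possibly on the opposite strand) flip the sign of the outcome beta
#' and mirror its allele frequency. Palindromic SNPs (A/T or C/G) carry no
#' strand information in their alleles, so they are aligned by allele
#' frequency when both frequencies are informative and dropped otherwise.
#' Irreconcilable allele pairs are dropped as incompatible. Nothing is
#' removed without being counted.
#'
#' @param exposure,outcome [association_set()] objects.
#' @param palindrome_eaf_limit palindromic SNPs with effect allele frequency
#'   inside `[limit, 1 - limit]` in either study (or missing) are considered
#'   ambiguous and dropped; default 0.3.
#' @return Data frame of class `harmonized_set` with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out` and
#'   `action` (one of kept / flipped / dropped_palindromic /
#'   dropped_incompatible). Rows with action kept or flipped form the
#'   analytic set (see [harmonized_rows()]); counts of variants absent from
#'   either study are in `attr(, "counts")`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.3) {
  stopifnot(inherits(exposure, "association_set"),
            inherits(outcome, "association_set"))
  if (palindrome_eaf_limit <= 0 || palindrome_eaf_limit >= 0.5) {
    stop("palindrome_eaf_limit must lie in (0, 0.5)", call. = FALSE)
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  n_union <- length(union(exposure$variant_id, outcome$variant_id))
  if (length(shared) == 0) {
    stop("no overlapping instruments between '", attr(exposure, "trait"),
         "' and '", attr(outcome, "trait"), "'", call. = FALSE)
  }
  e <- as.data.frame(exposure)[match(shared, exposure$variant_id), ]
  o <- as.data.frame(outcome)[match(shared, outcome$variant_id), ]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  e_pal <- comp[e$effect_allele] == e$other_allele

  # Non-palindromic resolution: direct match, swap, then the same two on the
  # complementary strand.
  o_ea_c <- unname(comp[o$effect_allele])
  o_oa_c <- unname(comp[o$other_allele])
  match_direct <- o$effect_allele == e$effect_allele &
    o$other_allele == e$other_allele
  match_swap <- o$effect_allele == e$other_allele &
    o$other_allele == e$effect_allele
  match_strand <- o_ea_c == e$effect_allele & o_oa_c == e$other_allele
  match_strand_swap <- o_ea_c == e$other_allele & o_oa_c == e$effect_allele

  # Palindromic pairs: the outcome alleles must at least be the same base
  # pair; orientation then comes from frequency alone.
  pal_same_pair <- match_direct | match_swap
  lo <- palindrome_eaf_limit
  hi <- 1 - palindrome_eaf_limit
  ambiguous <- is.na(e$eaf) | is.na(o$eaf) |
    (e$eaf >= lo & e$eaf <= hi) | (o$eaf >= lo & o$eaf <= hi)
  freq_aligned <- (e$eaf < 0.5) == (o$eaf < 0.5)

  action <- rep("dropped_incompatible", length(shared))
  action[!e_pal & (match_direct | match_strand)] <- "kept"
  action[!e_pal & (match_swap | match_strand_swap)] <- "flipped"
  action[e_pal & !pal_same_pair] <- "dropped_incompatible"
  action[e_pal & pal_same_pair & ambiguous] <- "dropped_palindromic"
  ok_pal <- e_pal & pal_same_pair & !ambiguous
  action[ok_pal & freq_aligned] <- "kept"
  action[ok_pal & !freq_aligned] <- "flipped"

  flip <- action == "flipped"
  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)

  out <- data.frame(variant_id = shared,
                    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
                    beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
                    action = action,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- c(kept = sum(action == "kept"),
              flipped = sum(flip),
              dropped_palindromic = sum(action == "dropped_palindromic"),
              dropped_incompatible = sum(action == "dropped_incompatible"),
              absent_from_either = n_union - length(shared))
  structure(out,
            class = c("harmonized_set", "data.frame"),
            exposure_trait = attr(exposure, "trait"),
            outcome_trait = attr(outcome, "trait"),
            outcome_binary = isTRUE(attr(outcome, "is_binary")),
            counts = counts)
}

#' Retained rows of a harmonized set
#'
#' @param h a `harmonized_set`.
#' @return The rows with both effects expressed on one effect allele
#'   (action kept or flipped), attributes preserved.
#' @export
harmonized_rows <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  keep <- h$action %in% c("kept", "flipped")
  out <- as.data.frame(h)[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("exposure_trait", "outcome_trait", "outcome_binary", "counts")) {
    attr(out, a) <- attr(h, a)
  }
  class(out) <- c("harmonized_set", "data.frame")
  out
}

#' Build a harmonized set directly from aligned effect pairs
#'
#' Convenience constructor for fixtures and simulated data whose exposure and
#' outcome effects are already expressed on the same effect allele.
#'
#' @param variant_id,beta_exp,se_exp,beta_out,se_out,eaf_exp,eaf_out vectors,
#'   one entry per variant.
#' @param exposure_trait,outcome_trait labels.
#' @param outcome_binary is the outcome on the log-odds scale?
#' @return A `harmonized_set` with every row `kept`.
#' @export
harmonized_set <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           exposure_trait = "exposure",
                           outcome_trait = "outcome",
                           outcome_binary = FALSE) {
  stopifnot(all(se_exp > 0), all(se_out > 0), !anyDuplicated(variant_id))
  out <- data.frame(variant_id = as.character(variant_id),
                    beta_exp = beta_exp, se_exp = se_exp,
                    eaf_exp = rep_len(eaf_exp, length(variant_id)),
                    beta_out = beta_out, se_out = se_out,
                    eaf_out = rep_len(eaf_out, length(variant_id)),
                    action = "kept",
                    stringsAsFactors = FALSE)
  counts <- c(kept = nrow(out), flipped = 0L, dropped_palindromic = 0L,
              dropped_incompatible = 0L, absent_from_either = 0L)
  structure(out, class = c("harmonized_set", "data.frame"),
            exposure_trait = exposure_trait, outcome_trait = outcome_trait,
            outcome_binary = isTRUE(outcome_binary), counts = counts)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("Harmonized set %s -> %s\n", attr(x, "exposure_trait"),
              attr(x, "outcome_trait")))
  cat("  ", paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
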