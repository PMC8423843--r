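#' Construct a validated set of per-variant GWAS associations
#'
#' An association set is the package's container for one GWA study's summary
#' statistics: one row per biallelic SNP with its effect estimate (beta, or
#' log-odds for a binary trait), standard error, p-value, alleles and effect
#' allele frequency. Rows failing validation are removed and reported, never
#' silently dropped.
#'
#' @param data data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, and optionally `eaf`, `n`,
#'   `chrom`, `pos`.
#' @param trait trait name.
#' @param is_binary is the trait binary (betas on the log-odds scale)?
#' @param sample_size total GWA study sample size.
#' @param n_cases number of cases for a binary trait (optional).
#' @return A data frame of class `association_set` with one validated row per
#'   variant; rejected rows (with reasons) in `attr(, "rejects")`.
#' @export
association_set <- function(data, trait, is_binary = FALSE,
                            sample_size = NULL, n_cases = NULL) {
  required <- c("variant_id", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(n_cases) && !is.null(sample_size) && n_cases > sample_size) {
    stop("n_cases exceeds sample_size", call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  if (!"n" %in% names(data)) data$n <- NA_integer_
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(data))
  bad_allele <- !(data$effect_allele %in% bases) |
    !(data$other_allele %in% bases)
  reason[bad_allele] <- "allele not a single base A/C/G/T"
  same_allele <- is.na(reason) & data$effect_allele == data$other_allele
  reason[same_allele] <- "effect and other allele identical"
  bad_se <- is.na(reason) & (!is.finite(data$se) | data$se <= 0)
  reason[bad_se] <- "se not strictly positive"
  bad_p <- is.na(reason) & (!is.finite(data$pval) |
                              data$pval <= 0 | data$pval > 1)
  reason[bad_p] <- "pval outside (0, 1]"
  bad_beta <- is.na(reason) & !is.finite(data$beta)
  reason[bad_beta] <- "beta not finite"
  bad_eaf <- is.na(reason) & !is.na(data$eaf) &
    (data$eaf < 0 | data$eaf > 1)
  reason[bad_eaf] <- "eaf outside [0, 1]"
  dup <- is.na(reason) & duplicated(data$variant_id)
  reason[dup] <- "duplicated variant_id"

  rejects <- data.frame(variant_id = data$variant_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  keep <- data[is.na(reason), , drop = FALSE]
  rownames(keep) <- NULL
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " row(s) rejected while building association set '",
            trait, "'")
  }
  structure(keep,
            class = c("association_set", "data.frame"),
            trait = trait,
            is_binary = isTRUE(is_binary),
            sample_size = sample_size,
            n_cases = n_cases,
            rejects = rejects)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Columns may appear under any header names via `column_map`, a named
#' character vector mapping canonical names (`variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's headers.
#'
#' @inheritParams association_set
#' @param path path to a tab-delimited table with a header row.
#' @param column_map named character vector, canonical name -> file column;
#'   `NULL` if the file already uses canonical names.
#' @return An [association_set()].
#' @export
read_summary_stats <- function(path, column_map = NULL, trait,
                               is_binary = FALSE, sample_size = NULL,
                               n_cases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read_tsv_file(path)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canonical in names(column_map)) {
      raw[[canonical]] <- raw[[column_map[[canonical]]]]
    }
  }
  association_set(raw, trait = trait, is_binary = is_binary,
                  sample_size = sample_size, n_cases = n_cases)
}

#' Write an association set as a tab-delimited summary-statistics table
#'
#' The emitted dialect is the one [read_summary_stats()] reads back without a
#' column map (round-trip tested).
#'
#' @param x an [association_set()].
#' @param path output path.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "association_set"))
  cols <- intersect(c("variant_id", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pval", "n"), names(x))
  write_tsv_file(as.data.frame(x)[, cols], path)
}

#' @export
print.association_set <- function(x, ...) {
  cat(sprintf("Association set '%s': %d variants%s\n",
              attr(x, "trait"), nrow(x),
              if (isTRUE(attr(x, "is_binary"))) " (binary trait, log-odds)"
              else ""))
  if (!is.null(attr(x, "sample_size"))) {
    cat(sprintf("  sample size %s\n", format(attr(x, "sample_size"))))
  }
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat(sprintf("  %d row(s) rejected at read time\n", nrow(rej)))
  }
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
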