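#' Define a study plan
#'
#' A study plan is an ordered list of MR tests over a registry of summary
#' statistic datasets, with Bonferroni multiplicity control across all of
#' them: the stringent threshold is alpha / n_tests exactly (0.05 / 10 =
#' 0.005 for the canonical 8 univariable + 1 multivariable + 1 mediation
#' design). IVW p-values below the stringent threshold rank "stringent",
#' below alpha "suggestive", otherwise "null".
#'
#' @param tests data frame with columns `label`, `design` (univariable /
#'   mvmr / mediation), `exposure` (comma-separated trait names for mvmr),
#'   `outcome`, and optionally `mediator` (mediation only) and `requires`
#'   (label of an earlier test that must reach the stringent tier before
#'   this one runs - the gate of two-step MR).
#' @param alpha nominal significance level; default 0.05.
#' @param n_tests number of tests charged against the Bonferroni budget;
#'   defaults to `nrow(tests)`.
#' @return List of class `study_plan`.
#' @export
study_plan <- function(tests, alpha = 0.05, n_tests = nrow(tests)) {
  stopifnot(is.data.frame(tests),
            all(c("label", "design", "exposure", "outcome") %in% names(tests)))
  if (!"mediator" %in% names(tests)) tests$mediator <- NA_character_
  if (!"requires" %in% names(tests)) tests$requires <- NA_character_
  if (anyDuplicated(tests$label)) stop("test labels must be unique",
                                       call. = FALSE)
  bad <- !tests$design %in% c("univariable", "mvmr", "mediation")
  if (any(bad)) stop("unknown design: ", tests$design[bad][1], call. = FALSE)
  structure(list(tests = tests, alpha = alpha, n_tests = n_tests,
                 bonferroni_threshold = alpha / n_tests),
            class = "study_plan")
}

significance_tier <- function(p, plan) {
  if (is.na(p)) return(NA_character_)
  if (p < plan$bonferroni_threshold) "stringent"
  else if (p < plan$alpha) "suggestive"
  else "null"
}

#' Run a study plan end to end
#'
#' For each univariable test: instrument selection, harmonization, radial
#' outlier filtering, then IVW plus the sensitivity battery (MR-Egger with
#' intercept test and I2GX, weighted median, weighted mode), with SIMEX
#' correction of the Egger slope when I2GX falls below
#' `simex_i2_threshold` (the "about 10% bias at I2 near 90%" rule) or
#' always/never by flag. Two-step gating: a test whose `requires` test did
#' not reach the stringent tier is skipped with a reason. Multivariable and
#' mediation tests run through [mvmr_ivw()] and [mediation_analysis()].
#' Errors are attached to their test; remaining tests still run. All
#' randomness derives from `seed`, so reruns are byte-identical.
#'
#' @param plan a [study_plan()].
#' @param registry named list of [association_set()]s (plus optionally
#'   `ld`, an [ld_matrix()]), keyed by the trait names the plan uses.
#' @param seed integer master seed.
#' @param p_threshold instrument significance threshold; default 5e-8.
#' @param radial_alpha radial outlier threshold; default 0.05.
#' @param simex "auto" (trigger on I2GX), "always" or "never".
#' @param simex_i2_threshold I2GX below which SIMEX runs; default 0.9.
#' @param boot_reps bootstrap replicates for median/mode standard errors;
#'   default 1000.
#' @param simex_reps SIMEX replicates per lambda; default 200.
#' @return List of class `mr_study_report` with data frames `univariable`
#'   (one row per test x estimator), `mvmr` (one row per exposure),
#'   `mediation` (3 rows per mediation test), `skipped`, `errors`, and the
#'   per-test `audit` list.
#' @export
run_study_plan <- function(plan, registry, seed = 1, p_threshold = 5e-8,
                           radial_alpha = 0.05,
                           simex = c("auto", "always", "never"),
                           simex_i2_threshold = 0.9, boot_reps = 1000,
                           simex_reps = 200) {
  stopifnot(inherits(plan, "study_plan"))
  simex <- match.arg(simex)
  ld <- registry$ld
  get_set <- function(nm) {
    x <- registry[[nm]]
    if (is.null(x)) stop("dataset '", nm, "' not in registry", call. = FALSE)
    x
  }
  uni_rows <- list()
  mvmr_rows <- list()
  med_rows <- list()
  skipped <- list()
  errors <- list()
  audit <- list()
  tiers <- character(0)

  for (i in seq_len(nrow(plan$tests))) {
    tst <- plan$tests[i, ]
    test_seed <- seed + i
    req <- tst$requires
    if (!is.na(req) && !identical(unname(tiers[req]), "stringent")) {
      skipped[[tst$label]] <- data.frame(
        label = tst$label,
        reason = sprintf("gated on '%s' (tier: %s)", req,
                         tiers[req] %||% "not run"),
        stringsAsFactors = FALSE)
      tiers[tst$label] <- NA_character_
      next
    }
    res <- tryCatch({
      switch(tst$design,
        univariable = {
          out <- run_univariable_test(tst$label, get_set(tst$exposure),
                                      get_set(tst$outcome), plan,
                                      p_threshold, ld, radial_alpha, simex,
                                      simex_i2_threshold, boot_reps,
                                      simex_reps, test_seed)
          uni_rows[[tst$label]] <- out$rows
          audit[[tst$label]] <- out$audit
          tiers[tst$label] <- out$tier
        },
        mvmr = {
          ex_names <- trimws(strsplit(tst$exposure, ",")[[1]])
          inp <- suppressWarnings(
            mvmr_input(stats::setNames(lapply(ex_names, get_set), ex_names),
                       get_set(tst$outcome), p_threshold = p_threshold,
                       ld = ld))
          fit <- mvmr_ivw(inp)
          rows <- as.data.frame(fit)
          rows$exposure <- names(fit$estimates)
          rows$label <- tst$label
          rows$tier <- vapply(rows$pval, significance_tier, "", plan = plan)
          mvmr_rows[[tst$label]] <- rows
          tiers[tst$label] <- significance_tier(min(rows$pval), plan)
        },
        mediation = {
          med <- mediation_analysis(get_set(tst$exposure),
                                    get_set(tst$mediator),
                                    get_set(tst$outcome),
                                    p_threshold = p_threshold, ld = ld,
                                    radial_alpha = radial_alpha)
          rows <- as.data.frame(med)
          rows$label <- tst$label
          rows$tier <- vapply(rows$pval, significance_tier, "", plan = plan)
          rows$classification <- med$classification
          med_rows[[tst$label]] <- rows
          audit[[tst$label]] <- list(mediation = med)
          tiers[tst$label] <- significance_tier(med$total$pval, plan)
        })
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errors[[tst$label]] <- data.frame(label = tst$label, error = res,
                                        stringsAsFactors = FALSE)
      tiers[tst$label] <- NA_character_
    }
  }
  structure(list(univariable = rbind_all(uni_rows),
                 mvmr = rbind_all(mvmr_rows),
                 mediation = rbind_all(med_rows),
                 skipped = rbind_all(skipped),
                 errors = rbind_all(errors),
                 tiers = tiers, audit = audit, plan = plan),
            class = "mr_study_report")
}

run_univariable_test <- function(label, exposure, outcome, plan, p_threshold,
                                 ld, radial_alpha, simex, simex_i2_threshold,
                                 boot_reps, simex_reps, test_seed) {
  notes <- character(0)
  ids <- withCallingHandlers(
    select_instruments(exposure, p_threshold, ld),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  h <- harmonize(subset_association(exposure, ids), outcome)
  removed <- character(0)
  if (!is.null(radial_alpha) && nrow(harmonized_rows(h)) >= 3) {
    flt <- radial_outliers(h, alpha = radial_alpha)
    removed <- flt$outliers
    h <- flt$retained
  }
  w <- wald_ratios(h)
  n <- nrow(w)
  ivw <- mr_ivw(w)
  ests <- list(ivw$estimate)
  het <- ivw$heterogeneity
  i2gx <- NA_real_
  if (n >= 3) {
    egger <- mr_egger(h)
    i2gx <- egger$heterogeneity$i_squared_gx
    ests <- c(ests, list(egger$slope, egger$intercept))
    if (simex == "always" ||
        (simex == "auto" && is.finite(i2gx) && i2gx < simex_i2_threshold)) {
      ests <- c(ests, list(mr_simex_egger(h, b_reps = simex_reps,
                                          seed = test_seed)))
    }
    ests <- c(ests,
              list(mr_weighted_median(w, boot_reps = boot_reps,
                                      seed = test_seed),
                   mr_weighted_mode(w, boot_reps = boot_reps,
                                    seed = test_seed)))
  } else {
    notes <- c(notes, "fewer than 3 instruments: sensitivity battery skipped")
  }
  rows <- do.call(rbind, lapply(ests, as.data.frame))
  rows$label <- label
  rows$q <- het$q
  rows$q_df <- het$df
  rows$q_pval <- het$pval
  rows$i_squared_gx <- i2gx
  tier <- significance_tier(ivw$estimate$pval, plan)
  rows$tier <- ifelse(rows$method == "IVW", tier, NA_character_)
  list(rows = rows, tier = tier,
       audit = list(instruments = ids, outliers_removed = removed,
                    notes = notes, seed = test_seed,
                    harmonization_counts = attr(h, "counts")))
}

#' @export
print.mr_study_report <- function(x, ...) {
  cat(sprintf("MR study report: %d test(s), Bonferroni threshold %.4g\n",
              nrow(x$plan$tests), x$plan$bonferroni_threshold))
  if (!is.null(x$univariable)) {
    ivw <- x$univariable[x$univariable$method == "IVW",
                         c("label", "n_snps", "beta", "ci_low", "ci_high",
                           "pval", "tier")]
    print(ivw, row.names = FALSE)
  }
  if (!is.null(x$skipped)) {
    cat("Skipped:\n")
    print(x$skipped, row.names = FALSE)
  }
  if (!is.null(x$errors)) {
    cat("Errors:\n")
    print(x$errors, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report as tab-delimited tables
#'
#' Emits one file per populated section (`univariable.tsv`, `mvmr.tsv`,
#' `mediation.tsv`, `skipped.tsv`, `errors.tsv`) plus a per-test audit log.
#'
#' @param report an `mr_study_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (section in c("univariable", "mvmr", "mediation", "skipped", "errors")) {
    tab <- report[[section]]
    if (!is.null(tab) && nrow(tab) > 0) {
      write_tsv_file(tab, file.path(dir, paste0(section, ".tsv")))
    }
  }
  audit_lines <- unlist(lapply(names(report$audit), function(lbl) {
    a <- report$audit[[lbl]]
    if (!is.null(a$instruments)) {
      c(sprintf("[%s] instruments: %s", lbl,
                paste(a$instruments, collapse = ",")),
        sprintf("[%s] outliers_removed: %s", lbl,
                paste(a$outliers_removed, collapse = ",")),
        sprintf("[%s] notes: %s", lbl, paste(a$notes, collapse = "; ")))
    } else {
      sprintf("[%s] %s", lbl, class(a[[1]])[1])
    }
  }))
  writeLines(audit_lines %||% character(0), file.path(dir, "audit.log"))
  invisible(dir)
}
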