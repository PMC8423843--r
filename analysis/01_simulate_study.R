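#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# Builds summary-statistic tables emulating the design of an
# obesity -> lipids/urate -> gout investigation: one two-sample dataset per
# univariable contrast (with the generative causal effect set to the kind of
# magnitude consortium GWA studies report for these trait pairs), plus a
# mediation system obesity -> urate -> gout with a binary, UK-Biobank-sized
# gout study. Everything downstream (stages 02-04) reads the tab-delimited
# files this stage writes, so the whole workflow round-trips through the
# on-disk dialect.

suppressMessages(library(mrpath))
out_dir <- "results/synthetic_data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20210907  # fixed study seed; change to regenerate a new world

# Univariable contrasts: label, true effect, exposure / outcome sample
# sizes (consortium-scale), binary outcome flag.
contrasts <- list(
  list(name = "obesity_hdl", effect = -0.083, n_exp = 98679, n_out = 187167),
  list(name = "obesity_ldl", effect = -0.011, n_exp = 98679, n_out = 173082),
  list(name = "obesity_tri", effect = 0.082, n_exp = 98679, n_out = 177861),
  list(name = "obesity_urate", effect = 0.127, n_exp = 98679, n_out = 110347),
  list(name = "hdl_urate", effect = -0.109, n_exp = 187167, n_out = 110347),
  list(name = "tri_urate", effect = 0.198, n_exp = 177861, n_out = 110347)
)

for (ct in contrasts) {
  cfg <- sim_config(n_snps = 30, true_effect = ct$effect,
                    n_exposure = ct$n_exp, n_outcome = ct$n_out,
                    seed = seed + abs(ct$effect) * 1e4)
  d <- simulate_two_sample(cfg)
  write_summary_stats(d$exposure, file.path(out_dir,
                                            paste0(ct$name, "_exposure.tsv")))
  write_summary_stats(d$outcome, file.path(out_dir,
                                           paste0(ct$name, "_outcome.tsv")))
  cat(sprintf("%-14s true effect %+.3f -> %d instruments written\n",
              ct$name, ct$effect, nrow(d$exposure)))
}

# Mediation system obesity -> urate -> gout. The exposure -> mediator path
# uses the published-scale 0.127 SD urate per unit log-odds obesity; the
# urate -> gout path is set to 1.0 log-odds per SD urate (the order of
# magnitude observational gout epidemiology reports per ~1 mg/dl), with a
# small negative residual direct path, so the generative truth is an
# inconsistent mediation: the indirect path carries all of the effect.
med_cfg <- sim_config(n_snps = 80, n_exposure = 98679, n_outcome = 462933,
                      binary_outcome = TRUE, case_fraction = 6542 / 462933,
                      mediation = list(beta_em = 0.127, beta_mo = 1.0,
                                       beta_direct = -0.01,
                                       n_mediator = 110347),
                      seed = seed)
sys <- simulate_mediation_system(med_cfg)
write_summary_stats(sys$exposure, file.path(out_dir, "med_obesity.tsv"))
write_summary_stats(sys$mediator, file.path(out_dir, "med_urate.tsv"))
write_summary_stats(sys$outcome, file.path(out_dir, "med_gout.tsv"))
write_tsv <- function(x, f) utils::write.table(x, f, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE)
write_tsv(sys$truth, file.path(out_dir, "med_truth.tsv"))
cat(sprintf("mediation system: %d obesity + %d urate instruments, gout n = %d (%.2f%% cases)\n",
            sum(sys$truth$instrument_for == "exposure"),
            sum(sys$truth$instrument_for == "mediator"),
            462933, 100 * 6542 / 462933))
cat("generative truth: total log-OR =", -0.01 + 0.127 * 1.0, "\n")
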