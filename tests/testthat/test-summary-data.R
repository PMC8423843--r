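test_that("a well-formed table reads back identically", {
  tab <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                    effect_allele = c("A", "C", "G"),
                    other_allele = c("G", "T", "A"),
                    eaf = c(0.2, 0.5, 0.8),
                    beta = c(0.1, -0.05, 0.02),
                    se = c(0.01, 0.02, 0.03),
                    pval = c(1e-20, 0.01, 0.5),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  set <- read_summary_stats(path, trait = "x", sample_size = 1000)
  expect_s3_class(set, "association_set")
  expect_equal(nrow(set), 3)
  expect_equal(set$beta, tab$beta)
  expect_equal(nrow(attr(set, "rejects")), 0)
})

test_that("invalid rows are rejected and reported, not silently dropped", {
  tab <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                    effect_allele = c("A", "C", "G"),
                    other_allele = c("G", "T", "A"),
                    beta = c(0.1, -0.05, 0.02),
                    se = c(0.01, 0, 0.03),
                    pval = c(1e-20, 0.01, 0.5),
                    stringsAsFactors = FALSE)
  expect_message(set <- association_set(tab, trait = "x"), "rejected")
  expect_equal(nrow(set), 2)
  rej <- attr(set, "rejects")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$variant_id, "rs2")
  expect_match(rej$reason, "se")
})

test_that("column_map makes shuffled column orders equivalent", {
  canonical <- data.frame(variant_id = c("rs1", "rs2"),
                          effect_allele = c("A", "C"),
                          other_allele = c("G", "T"),
                          eaf = c(0.2, 0.6),
                          beta = c(0.1, -0.05),
                          se = c(0.01, 0.02),
                          pval = c(1e-10, 0.3),
                          stringsAsFactors = FALSE)
  shuffled <- data.frame(P = canonical$pval, SNP = canonical$variant_id,
                         B = canonical$beta, A2 = canonical$other_allele,
                         SE = canonical$se, A1 = canonical$effect_allele,
                         FRQ = canonical$eaf, stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(canonical, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(shuffled, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_summary_stats(p1, trait = "x")
  b <- read_summary_stats(p2, trait = "x",
                          column_map = c(variant_id = "SNP",
                                         effect_allele = "A1",
                                         other_allele = "A2", eaf = "FRQ",
                                         beta = "B", se = "SE", pval = "P"))
  cols <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "pval")
  expect_equal(as.data.frame(b)[, cols], as.data.frame(a)[, cols])
})

test_that("rejecting indels and missing columns errors clearly", {
  expect_error(association_set(data.frame(variant_id = "rs1",
                                          effect_allele = "A",
                                          beta = 0.1, se = 0.1, pval = 0.5),
                               trait = "x"),
               "missing mandatory column")
  set <- suppressMessages(
    make_assoc("rs1", "AT", "G", 0.1, 0.01))
  expect_equal(nrow(set), 0)
  expect_match(attr(set, "rejects")$reason, "single base")
})

test_that("allele swap flips the outcome beta", {
  e <- make_assoc("rs1", "A", "G", 0.1, 0.01, eaf = 0.2)
  o <- make_assoc("rs1", "G", "A", 0.05, 0.02, eaf = 0.8)
  h <- harmonize(e, o)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
  expect_equal(h$eaf_out, 0.2)
})

test_that("strand-complement alleles are recognized", {
  e <- make_assoc("rs1", "A", "G", 0.1, 0.01)
  o_same <- make_assoc("rs1", "T", "C", 0.05, 0.02)  # A/G on other strand
  o_swap <- make_assoc("rs1", "C", "T", 0.05, 0.02)
  expect_equal(harmonize(e, o_same)$action, "kept")
  h <- harmonize(e, o_swap)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
})

test_that("ambiguous palindromic SNPs are dropped", {
  e <- make_assoc("rs1", "A", "T", 0.1, 0.01, eaf = 0.5)
  o <- make_assoc("rs1", "A", "T", 0.05, 0.02, eaf = 0.5)
  expect_equal(harmonize(e, o)$action, "dropped_palindromic")
  # missing eaf on either side is also ambiguous
  e2 <- make_assoc("rs1", "C", "G", 0.1, 0.01)
  o2 <- make_assoc("rs1", "C", "G", 0.05, 0.02, eaf = 0.1)
  expect_equal(harmonize(e2, o2)$action, "dropped_palindromic")
})

test_that("informative frequencies align palindromic SNPs", {
  # Outcome frequency matches 1 - eaf_exp: effect alleles are on opposite
  # labels, so the outcome beta must flip.
  e <- make_assoc("rs1", "A", "T", 0.1, 0.01, eaf = 0.10)
  o <- make_assoc("rs1", "A", "T", 0.05, 0.02, eaf = 0.88)
  h <- harmonize(e, o)
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_out, -0.05)
  # frequency is the only signal for palindromes: a "T" effect allele with
  # frequency matching our rare "A" is the same allele on the other strand
  o2 <- make_assoc("rs1", "T", "A", 0.05, 0.02, eaf = 0.12)
  expect_equal(harmonize(e, o2)$action, "kept")
  o3 <- make_assoc("rs1", "A", "T", 0.05, 0.02, eaf = 0.08)
  expect_equal(harmonize(e, o3)$action, "kept")
})

test_that("irreconcilable allele pairs are dropped as incompatible", {
  e <- make_assoc("rs1", "A", "G", 0.1, 0.01)
  o <- make_assoc("rs1", "A", "C", 0.05, 0.02)
  expect_equal(harmonize(e, o)$action, "dropped_incompatible")
})

test_that("disjoint variant sets raise a no-overlap error", {
  e <- make_assoc("rs1", "A", "G", 0.1, 0.01)
  o <- make_assoc("rs2", "A", "G", 0.05, 0.02)
  expect_error(harmonize(e, o), "no overlapping instruments")
})

test_that("harmonization is idempotent and conserves variants", {
  d <- simulate_two_sample(sim_config(n_snps = 20, true_effect = 0.1,
                                      seed = 101))
  extra <- make_assoc("rs99999", "A", "G", 0.2, 0.01)
  outcome_plus <- association_set(rbind(as.data.frame(d$outcome),
                                        as.data.frame(extra)),
                                  trait = "outcome")
  h1 <- harmonize(d$exposure, outcome_plus)
  cnt <- attr(h1, "counts")
  n_union <- length(union(d$exposure$variant_id, outcome_plus$variant_id))
  expect_equal(sum(cnt), n_union)
  expect_equal(unname(cnt["absent_from_either"]), 1)

  # feed the harmonized pair back through: nothing changes
  r <- harmonized_rows(h1)
  e2 <- make_assoc(r$variant_id, "A", "G", r$beta_exp, r$se_exp,
                   eaf = r$eaf_exp)
  o2 <- make_assoc(r$variant_id, "A", "G", r$beta_out, r$se_out,
                   eaf = r$eaf_out)
  h2 <- harmonize(e2, o2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_out, r$beta_out)
  expect_equal(h2$beta_exp, r$beta_exp)
})

test_that("flipping outcome allele labels is an involution on beta_out", {
  e <- make_assoc(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                  c(0.1, -0.2), c(0.01, 0.02), eaf = c(0.2, 0.7))
  o <- make_assoc(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                  c(0.05, 0.03), c(0.02, 0.01), eaf = c(0.25, 0.66))
  o_flipped <- make_assoc(c("rs1", "rs2"), c("G", "T"), c("A", "C"),
                          c(-0.05, -0.03), c(0.02, 0.01),
                          eaf = c(0.75, 0.34))
  h <- harmonize(e, o)
  hf <- harmonize(e, o_flipped)
  expect_equal(hf$beta_out, h$beta_out)
  expect_equal(hf$se_out, h$se_out)
  expect_equal(hf$eaf_out, h$eaf_out)
})

test_that("summary statistics round-trip through the tab-delimited dialect", {
  d <- simulate_two_sample(sim_config(n_snps = 12, seed = 55))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(d$exposure, path)
  back <- read_summary_stats(path, trait = attr(d$exposure, "trait"),
                             sample_size = attr(d$exposure, "sample_size"))
  cols <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "pval")
  expect_equal(as.data.frame(back)[, cols],
               as.data.frame(d$exposure)[, cols], tolerance = 1e-12)
})
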