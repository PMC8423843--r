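test_that("Wald ratios follow the first-order formula, signs included", {
  h <- harmonized_set(c("a", "b", "c"),
                      beta_exp = c(0.1, 1, -0.1),
                      se_exp = rep(0.01, 3),
                      beta_out = c(0.05, 0, 0.05),
                      se_out = c(0.01, 0.02, 0.01))
  w <- wald_ratios(h)
  expect_equal(w$ratio, c(0.5, 0, -0.5))
  expect_equal(w$se, c(0.1, 0.02, 0.1))
  expect_equal(w$weight, w$se^-2)
})

test_that("a zero exposure beta names the offending SNP", {
  h <- harmonized_set(c("a", "bad"), beta_exp = c(0.1, 0),
                      se_exp = c(0.01, 0.01), beta_out = c(0.1, 0.1),
                      se_out = c(0.01, 0.01))
  expect_error(wald_ratios(h), "bad")
})

test_that("IVW equals weighted least squares through the origin", {
  h <- make_harmonized(ratio = c(0.2, 0.3, 0.7),
                       se_wald = c(0.05, 0.10, 0.20),
                       beta_exp = c(0.08, 0.12, 0.05))
  got <- mr_ivw(wald_ratios(h))
  oracle <- ivw_wls_oracle(h)
  expect_equal(got$estimate$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(got$heterogeneity$q, oracle$q, tolerance = 1e-10)
  expected_se <- oracle$se_fixed * max(1, sqrt(oracle$q / (nrow(h) - 1)))
  expect_equal(got$estimate$se, expected_se, tolerance = 1e-10)

  # and on a larger random fixture
  set.seed(4)
  h2 <- make_harmonized(ratio = rnorm(20, 0.1, 0.3),
                        se_wald = runif(20, 0.02, 0.3),
                        beta_exp = runif(20, 0.03, 0.2))
  got2 <- mr_ivw(wald_ratios(h2))
  oracle2 <- ivw_wls_oracle(h2)
  expect_equal(got2$estimate$beta, oracle2$beta, tolerance = 1e-10)
  expect_equal(got2$heterogeneity$q, oracle2$q, tolerance = 1e-10)
})

test_that("IVW symmetry and single-variant degradation", {
  h <- make_harmonized(ratio = c(0.4, 0.6), se_wald = c(0.1, 0.1))
  expect_equal(mr_ivw(wald_ratios(h))$estimate$beta, 0.5)
  h1 <- make_harmonized(ratio = 0.37, se_wald = 0.08)
  expect_message(got <- mr_ivw(wald_ratios(h1)), "Wald")
  expect_equal(got$estimate$beta, 0.37)
  expect_equal(got$estimate$se, 0.08)
  expect_equal(got$estimate$method, "Wald")
})

test_that("Q is zero for identical ratios and invariant to relabeling", {
  h <- make_harmonized(ratio = rep(0.3, 5), se_wald = runif(5, 0.05, 0.2))
  expect_equal(mr_ivw(wald_ratios(h))$heterogeneity$q, 0, tolerance = 1e-20)
  set.seed(7)
  h2 <- make_harmonized(ratio = rnorm(8, 0.2, 0.1),
                        se_wald = runif(8, 0.05, 0.2))
  q1 <- mr_ivw(wald_ratios(h2))$heterogeneity$q
  perm <- sample(8)
  h3 <- harmonized_set(h2$variant_id[perm], h2$beta_exp[perm],
                       h2$se_exp[perm], h2$beta_out[perm], h2$se_out[perm])
  expect_equal(mr_ivw(wald_ratios(h3))$heterogeneity$q, q1,
               tolerance = 1e-12)
})

test_that("Egger recovers a constructed slope and intercept exactly", {
  # all variants share ratio b and zero intercept: perfect fit
  h <- make_harmonized(ratio = rep(0.25, 5), se_wald = runif(5, 0.05, 0.2),
                       beta_exp = seq(0.05, 0.13, length.out = 5))
  eg <- mr_egger(h)
  expect_equal(eg$slope$beta, 0.25, tolerance = 1e-12)
  expect_equal(eg$intercept$beta, 0, tolerance = 1e-12)

  # constant +0.01 additive offset on beta_out: the weighted regression has
  # the exact solution intercept 0.01, slope b
  b <- 0.3
  beta_exp <- seq(0.05, 0.2, length.out = 5)
  h2 <- harmonized_set(sprintf("s%d", 1:5), beta_exp, rep(0.005, 5),
                       b * beta_exp + 0.01, runif(5, 0.01, 0.03))
  eg2 <- mr_egger(h2)
  expect_equal(eg2$intercept$beta, 0.01, tolerance = 1e-10)
  expect_equal(eg2$slope$beta, b, tolerance = 1e-10)
})

test_that("Egger orients exposure betas positive before regressing", {
  beta_exp <- c(0.05, -0.08, 0.12, -0.06, 0.09)
  b <- 0.4
  h <- harmonized_set(sprintf("s%d", 1:5), beta_exp, rep(0.005, 5),
                      b * beta_exp + 0.02 * sign(beta_exp), rep(0.02, 5))
  flipped <- harmonized_set(sprintf("s%d", 1:5), abs(beta_exp),
                            rep(0.005, 5), b * abs(beta_exp) + 0.02,
                            rep(0.02, 5))
  expect_equal(mr_egger(h)$slope$beta, mr_egger(flipped)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(h)$intercept$beta, 0.02, tolerance = 1e-10)
})

test_that("degenerate Egger designs error out", {
  h <- make_harmonized(ratio = c(0.1, 0.2), se_wald = c(0.1, 0.1))
  expect_error(mr_egger(h), "insufficient instruments")
  h2 <- make_harmonized(ratio = c(0.1, 0.2, 0.3), se_wald = rep(0.1, 3),
                        beta_exp = rep(0.1, 3))
  expect_error(mr_egger(h2), "collinear")
})

test_that("I2GX reflects exposure-side measurement error", {
  # negligible se_exp: I2GX near 1
  h_clean <- make_harmonized(ratio = rep(0.2, 10),
                             se_wald = rep(0.05, 10),
                             beta_exp = seq(0.05, 0.14, 0.01),
                             se_exp = 1e-6)
  expect_gt(mr_egger(h_clean)$heterogeneity$i_squared_gx, 0.999)
  # se_exp comparable to the spread: I2GX well below 1
  h_noisy <- make_harmonized(ratio = rep(0.2, 10),
                             se_wald = rep(0.05, 10),
                             beta_exp = seq(0.05, 0.14, 0.01),
                             se_exp = 0.03)
  expect_lt(mr_egger(h_noisy)$heterogeneity$i_squared_gx, 0.7)
})

test_that("weighted median matches a dense-grid quantile oracle", {
  # symmetric equal-weight case
  h <- make_harmonized(ratio = c(0.1, 0.5, 0.9), se_wald = rep(0.1, 3))
  w <- wald_ratios(h)
  expect_equal(mr_weighted_median(w, boot_reps = 0)$beta, 0.5)

  # dominating weight pins the estimate
  h2 <- make_harmonized(ratio = c(0.12, 0.4, 0.6, 0.8, 0.95),
                        se_wald = c(0.01, rep(0.1, 4)))
  expect_lt(abs(mr_weighted_median(wald_ratios(h2), boot_reps = 0)$beta -
                  0.12), 0.02)

  # unequal weights against a brute-force interpolated-quantile oracle:
  # scan a dense grid of probabilities, interpolate manually
  h3 <- make_harmonized(ratio = c(0.05, 0.22, 0.47, 0.9),
                        se_wald = c(0.05, 0.12, 0.07, 0.2))
  w3 <- wald_ratios(h3)
  ord <- order(w3$ratio)
  r <- w3$ratio[ord]; wt <- w3$weight[ord]
  p <- (cumsum(wt) - wt / 2) / sum(wt)
  grid <- seq(0, 1, by = 1e-6)
  interp <- numeric(length(grid))
  for (j in seq_along(grid)) {
    g <- grid[j]
    if (g <= p[1]) interp[j] <- r[1]
    else if (g >= p[length(p)]) interp[j] <- r[length(r)]
    else {
      k <- max(which(p <= g))
      interp[j] <- r[k] + (r[k + 1] - r[k]) * (g - p[k]) / (p[k + 1] - p[k])
    }
  }
  oracle <- interp[which.min(abs(grid - 0.5))]
  expect_equal(mr_weighted_median(w3, boot_reps = 0)$beta, oracle,
               tolerance = 1e-5)
})

test_that("weighted median bootstrap is seeded and reproducible", {
  h <- make_harmonized(ratio = c(0.1, 0.3, 0.5, 0.2),
                       se_wald = c(0.05, 0.1, 0.2, 0.07))
  w <- wald_ratios(h)
  a <- mr_weighted_median(w, boot_reps = 200, seed = 11)
  b <- mr_weighted_median(w, boot_reps = 200, seed = 11)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
  expect_error(mr_weighted_median(w, boot_reps = 200), "seed")
})

test_that("weighted mode finds the dominant cluster, not the mean", {
  ratio <- c(rep(0.2, 7) + seq(-0.015, 0.015, length.out = 7),
             1.0, 1.05, 0.95)
  h <- make_harmonized(ratio = ratio, se_wald = rep(0.1, 10))
  est <- mr_weighted_mode(wald_ratios(h), boot_reps = 0)
  expect_lt(abs(est$beta - 0.2), 0.05)
  expect_gt(abs(est$beta - mean(ratio)), 0.1)
})

test_that("weighted mode handles degenerate and seeded cases", {
  h <- make_harmonized(ratio = rep(0.3, 4), se_wald = rep(0.1, 4))
  expect_message(est <- mr_weighted_mode(wald_ratios(h), boot_reps = 0),
                 "identical")
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, mr_ivw(wald_ratios(h))$estimate$se)

  h2 <- make_harmonized(ratio = c(0.1, 0.25, 0.3, 0.5),
                        se_wald = c(0.05, 0.1, 0.2, 0.07))
  a <- mr_weighted_mode(wald_ratios(h2), boot_reps = 150, seed = 3)
  b <- mr_weighted_mode(wald_ratios(h2), boot_reps = 150, seed = 3)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
})

test_that("SIMEX equals the naive Egger slope without measurement error", {
  h <- make_harmonized(ratio = c(0.22, 0.18, 0.25, 0.2, 0.21),
                       se_wald = rep(0.05, 5),
                       beta_exp = seq(0.05, 0.13, length.out = 5),
                       se_exp = 1e-10)
  naive <- mr_egger(h)$slope$beta
  sx <- mr_simex_egger(h, b_reps = 60, seed = 1)
  expect_equal(sx$beta, naive, tolerance = 1e-6)
})

test_that("SIMEX is deterministic given the seed and refuses tiny b_reps", {
  h <- make_harmonized(ratio = c(0.22, 0.18, 0.25, 0.2, 0.21),
                       se_wald = rep(0.05, 5),
                       beta_exp = seq(0.05, 0.13, length.out = 5),
                       se_exp = 0.02)
  a <- mr_simex_egger(h, b_reps = 60, seed = 9)
  b <- mr_simex_egger(h, b_reps = 60, seed = 9)
  expect_identical(a$beta, b$beta)
  expect_identical(a$se, b$se)
  expect_error(mr_simex_egger(h, b_reps = 20, seed = 1), "unstable")
  expect_error(mr_simex_egger(h, b_reps = 60), "seed")
})

test_that("SIMEX moves an attenuated Egger slope back toward the truth", {
  # exposure measurement error of the same order as the spread of the true
  # effects (I2GX around 0.6) dilutes the naive Egger slope; SIMEX should
  # recover part of the loss on average
  true_slope <- 0.2
  n <- 30
  reps <- 200
  naive <- numeric(reps)
  simex <- numeric(reps)
  i2 <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    beta_true <- runif(n, 0.05, 0.13)
    se_exp <- rep(0.019, n)
    bx <- beta_true + rnorm(n, 0, se_exp)
    by <- true_slope * beta_true + rnorm(n, 0, 0.004)
    h <- harmonized_set(sprintf("s%02d", 1:n), bx, se_exp, by,
                        rep(0.004, n))
    eg <- mr_egger(h)
    naive[r] <- eg$slope$beta
    i2[r] <- eg$heterogeneity$i_squared_gx
    simex[r] <- mr_simex_egger(h, b_reps = 60, seed = 2000 + r)$beta
  }
  expect_gt(mean(i2), 0.4)
  expect_lt(mean(i2), 0.8)
  expect_lt(mean(naive), true_slope)  # attenuation is real
  expect_lt(abs(mean(simex) - true_slope), abs(mean(naive) - true_slope))
})

test_that("all estimators agree on valid instruments (no pleiotropy)", {
  truth <- 0.127
  reps <- 300
  ests <- matrix(NA_real_, reps, 4,
                 dimnames = list(NULL, c("ivw", "egger", "median", "mode")))
  for (r in seq_len(reps)) {
    # a wide spread of instrument strengths keeps I2GX near 1, so the Egger
    # slope is not regression-diluted and all four estimands coincide
    d <- simulate_two_sample(sim_config(n_snps = 30, true_effect = truth,
                                        var_explained_range = c(0.001, 0.01),
                                        seed = 3000 + r))
    h <- harmonize(d$exposure, d$outcome)
    w <- wald_ratios(h)
    ests[r, "ivw"] <- mr_ivw(w)$estimate$beta
    ests[r, "egger"] <- mr_egger(h)$slope$beta
    ests[r, "median"] <- mr_weighted_median(w, boot_reps = 0)$beta
    ests[r, "mode"] <- mr_weighted_mode(w, boot_reps = 0)$beta
  }
  for (m in colnames(ests)) {
    mc_se <- sd(ests[, m]) / sqrt(reps)
    # the kernel mode carries O(bandwidth^2) smoothing bias at finite n,
    # hence the small absolute allowance on top of the MC band
    expect_lt(abs(mean(ests[, m]) - truth), 3 * mc_se + 0.005)
  }
})

test_that("directional pleiotropy: Egger intercept gains power, median stays closer", {
  reps <- 300
  hit <- logical(reps)
  err_ivw <- numeric(reps)
  err_med <- numeric(reps)
  truth <- 0.1
  for (r in seq_len(reps)) {
    d <- simulate_two_sample(sim_config(n_snps = 30, true_effect = truth,
                                        pleiotropy_mode = "directional",
                                        pleiotropy_mean = 0.05,
                                        pleiotropy_sd = 0.005,
                                        prop_invalid = 0.4,
                                        var_explained_range = c(0.001, 0.01),
                                        seed = 4000 + r))
    h <- harmonize(d$exposure, d$outcome)
    w <- wald_ratios(h)
    hit[r] <- mr_egger(h)$intercept$pval < 0.05
    err_ivw[r] <- abs(mr_ivw(w)$estimate$beta - truth)
    err_med[r] <- abs(mr_weighted_median(w, boot_reps = 0)$beta - truth)
  }
  expect_gt(mean(hit), 0.10)            # power above the nominal 5% rate
  expect_lt(mean(err_med), mean(err_ivw))
})
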