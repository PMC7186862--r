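hand_insts <- data.frame(
  snp_id = sprintf("rs%d", 1:5),
  beta_exp = c(0.10, 0.15, -0.08, 0.12, 0.20),
  se_exp   = c(0.004, 0.005, 0.003, 0.006, 0.005),
  beta_out = c(0.021, 0.028, -0.018, 0.030, 0.037),
  se_out   = c(0.015, 0.020, 0.012, 0.018, 0.022),
  stringsAsFactors = FALSE)

test_that("Wald ratios follow the delta method in both orders", {
  one <- data.frame(beta_exp = 0.1, se_exp = 0.004,
                    beta_out = 0.02, se_out = 0.05)
  wr <- wald_ratio(one)
  expect_equal(wr$estimate, 0.2)
  expect_equal(wr$se, 0.5)
  zero <- data.frame(beta_exp = 0.1, se_exp = 0.004,
                     beta_out = 0, se_out = 0.05)
  expect_equal(wald_ratio(zero)$estimate, 0)
  null <- data.frame(beta_exp = 0, se_exp = 0.004,
                     beta_out = 0.1, se_out = 0.05)
  expect_error(wald_ratio(null), "null instrument",
               class = "crossmr_domain_error")
  # second-order SE against a finite-difference error-propagation oracle
  se2 <- wald_ratio(one, second_order = TRUE)$se
  expect_equal(se2, wald_se2_fd_oracle(0.1, 0.02, 0.004, 0.05),
               tolerance = 1e-6)
})

test_that("IVW equals its closed-form identities", {
  # a single instrument is its own Wald ratio
  one <- hand_insts[1, ]
  expect_equal(suppressWarnings(ivw(one))$estimate,
               wald_ratio(one)$estimate)
  # all-null outcomes give a zero estimate
  null <- hand_insts
  null$beta_out <- 0
  expect_equal(ivw(null)$estimate, 0)
  # fixed-effects estimate and SE match the WLS-through-origin oracle
  for (s in 1:10) {
    insts <- rand_insts(sample(3:30, 1), seed = 100 + s)
    fit <- ivw(insts, model = "fixed")
    orc <- ivw_wls_oracle(insts)
    expect_equal(signif(fit$estimate, 10), signif(orc$estimate, 10))
    expect_equal(signif(fit$se, 10), signif(orc$se_fixed, 10))
    # and the meta-analysis form: inverse-variance pooling of Wald ratios
    wr <- wald_ratio(insts)
    meta <- sum(wr$estimate / wr$se^2) / sum(1 / wr$se^2)
    expect_equal(signif(fit$estimate, 10), signif(meta, 10))
  }
  # multiplicative random effects never deflates below fixed
  insts <- rand_insts(25, seed = 7, pleio_sd = 0.01)
  expect_gte(ivw(insts, "mre")$se, ivw(insts, "fixed")$se)
  expect_warning(ivw(hand_insts[1, ], "mre"), "fixed")
})

test_that("MR-Egger recovers exact linear structure and matches normal equations", {
  # noiseless: beta_out = 0.01 + 0.3 * beta_exp recovered exactly
  exact <- data.frame(beta_exp = c(0.05, 0.1, 0.15, 0.2),
                      se_exp = 0.001,
                      beta_out = 0.01 + 0.3 * c(0.05, 0.1, 0.15, 0.2),
                      se_out = c(0.01, 0.02, 0.015, 0.012))
  fit <- egger(exact)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-12)
  expect_equal(fit$estimate, 0.3, tolerance = 1e-12)
  # hand instruments against the generic weighted-regression oracle
  for (s in 1:6) {
    insts <- rand_insts(sample(6:40, 1), seed = 200 + s, pleio_sd = 0.005)
    fit <- egger(insts)
    orc <- egger_ne_oracle(insts)
    expect_equal(fit$estimate, orc$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-10)
    expect_equal(fit$se, orc$slope_se, tolerance = 1e-8)
    expect_equal(fit$intercept_se, orc$intercept_se, tolerance = 1e-8)
  }
  expect_error(egger(hand_insts[1:2, ]), ">= 3",
               class = "crossmr_method_error")
})

test_that("balanced pleiotropy leaves the Egger intercept at zero", {
  set.seed(77)
  n <- 4000
  gamma <- runif(n, 0.05, 0.2)
  se_out <- runif(n, 0.01, 0.03)
  insts <- data.frame(
    beta_exp = gamma, se_exp = 0,
    beta_out = 0.1 * gamma + rnorm(n, 0, 0.01) + rnorm(n, 0, se_out),
    se_out = se_out)
  fit <- egger(insts)
  expect_lt(abs(fit$intercept), 3.5 * fit$intercept_se)
})

test_that("RAPS collapses to IVW without exposure error and matches the grid oracle", {
  insts <- rand_insts(20, seed = 303, exposure_noise = FALSE)
  insts$se_exp <- 0
  expect_equal(signif(raps(insts)$estimate, 8),
               signif(ivw(insts, model = "fixed")$estimate, 8))
  for (s in 1:5) {
    insts <- rand_insts(5, seed = 400 + s)
    fit <- raps(insts)
    expect_true(fit$converged)
    expect_equal(fit$estimate, raps_grid_oracle(insts, step = 1e-5),
                 tolerance = 1e-4)
  }
  # under a true null the estimate is within Monte-Carlo error of zero
  insts <- rand_insts(300, seed = 99, b_true = 0)
  fit <- raps(insts)
  expect_lt(abs(fit$estimate), 3.5 * fit$se)
  # huber loss and overdispersion run and report sane diagnostics
  od <- raps(rand_insts(50, seed = 5, pleio_sd = 0.02),
             overdispersed = TRUE, loss = "huber")
  expect_true(od$converged)
  expect_gte(od$tau2, 0)
})

test_that("Cochran's Q measures ratio dispersion on n-1 df", {
  same <- data.frame(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0,
                     beta_out = c(0.05, 0.10, 0.20), se_out = c(1, 2, 1))
  expect_equal(cochran_q(same)$q_stat, 0)
  # two hand instruments, direct arithmetic:
  # w = (0.1/0.02)^2 = 25, (0.2/0.02)^2 = 100; theta = 0.3, 0.15
  # est = (25*0.3 + 100*0.15)/125 = 0.18
  # Q = 25*(0.12)^2 + 100*(-0.03)^2 = 0.36 + 0.09 = 0.45
  two <- data.frame(beta_exp = c(0.1, 0.2), se_exp = 0,
                    beta_out = c(0.03, 0.03), se_out = c(0.02, 0.02))
  q <- cochran_q(two)
  expect_equal(q$q_stat, 0.45, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_error(cochran_q(same[1, ]), class = "crossmr_method_error")
})

test_that("F statistics follow both stated conventions", {
  one <- data.frame(beta_exp = 0.1, se_exp = 0.01,
                    beta_out = 0, se_out = 1)
  expect_equal(f_statistic(one), 100)
  expect_equal(f_statistic(mode = "overall-r2", n_exposure = 1000,
                           r2 = 0, n_snps = 10), 0)
  # direct arithmetic: (694649 - 319 - 1)/319 * 0.039/0.961
  expect_equal(f_statistic(mode = "overall-r2", n_exposure = 694649,
                           r2 = 0.039, n_snps = 319),
               (694649 - 319 - 1) / 319 * 0.039 / (1 - 0.039))
  expect_error(f_statistic(mode = "overall-r2", r2 = 0.04),
               class = "crossmr_config_error")
})

test_that("single-SNP table is consistent with per-instrument Wald ratios", {
  tab <- single_snp_table(hand_insts)
  expect_equal(nrow(tab), 5)
  for (i in 1:5) {
    wr <- wald_ratio(hand_insts[i, , drop = FALSE])
    expect_equal(tab$estimate[i], wr$estimate)
    expect_equal(tab$se[i], wr$se)
  }
  expect_equal(tab$funnel_x, tab$estimate)
  expect_equal(tab$funnel_y, 1 / tab$se)
  # type-I calibration: fraction significant under the null near alpha
  null <- rand_insts(10000, seed = 12, b_true = 0, exposure_noise = FALSE)
  frac <- mean(single_snp_table(null)$significant)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("leave-one-out rows equal IVW recomputed without that instrument", {
  two <- hand_insts[1:2, ]
  loo <- leave_one_out(two)
  wr <- wald_ratio(two)
  expect_equal(loo$estimate, rev(wr$estimate))
  insts <- rand_insts(10, seed = 31)
  loo <- leave_one_out(insts)
  for (k in seq_len(10)) {
    expect_equal(loo$estimate[k],
                 ivw(insts[-k, , drop = FALSE])$estimate,
                 tolerance = 1e-12)
  }
  dup <- insts[rep(3, 4), ]
  loo_dup <- leave_one_out(dup)
  expect_lt(diff(range(loo_dup$estimate)), 1e-12)
  expect_error(leave_one_out(insts[1, , drop = FALSE]),
               class = "crossmr_method_error")
})

test_that("estimators are invariant to instrument orientation", {
  insts <- rand_insts(30, seed = 61, pleio_sd = 0.004)
  flipped <- insts
  pick <- seq(1, 30, by = 3)
  flipped$beta_exp[pick] <- -flipped$beta_exp[pick]
  flipped$beta_out[pick] <- -flipped$beta_out[pick]
  expect_equal(ivw(insts)$estimate, ivw(flipped)$estimate, tolerance = 1e-12)
  expect_equal(cochran_q(insts)$q_stat, cochran_q(flipped)$q_stat,
               tolerance = 1e-12)
  expect_equal(raps(insts)$estimate, raps(flipped)$estimate,
               tolerance = 1e-8)
  expect_equal(egger(insts)$estimate, egger(flipped)$estimate,
               tolerance = 1e-12)
  expect_equal(egger(insts)$intercept, egger(flipped)$intercept,
               tolerance = 1e-12)
})

test_that("the full battery returns a coherent report", {
  insts <- rand_insts(40, seed = 81)
  rep <- mr_analysis(insts, n_exposure = 694649, r2 = 0.039)
  expect_setequal(rep$results$method, c("ivw", "egger", "raps", "raps"))
  expect_true(all(rep$results$se > 0))
  expect_equal(nrow(rep$single_snp), 40)
  expect_equal(nrow(rep$leave_one_out), 40)
  expect_equal(rep$q$q_df, 39L)
  expect_true(is.finite(rep$f_mean_per_snp))
  expect_true(is.finite(rep$f_overall_r2))
  expect_equal(nrow(rep$plot_data$scatter), 40)
  expect_equal(sum(rep$plot_data$forest$kind == "summary"), 2)
})
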