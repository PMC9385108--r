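test_that("genotypes follow HWE at the target MAF", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 1,
                    maf_range = c(0.3, 0.3), seed = 101)
  g <- simulate_genotypes(cfg)
  d <- g$dosage[, 1]
  expect_lt(abs(mean(d) / 2 - 0.3), 0.02)
  props <- tabulate(d + 1L, 3L) / length(d)
  expect_lt(max(abs(props - c(0.49, 0.42, 0.09))), 0.02)
})

test_that("LD blocks hit their target r2 and blocks are independent", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 4,
                    ld_block_sizes = c(2, 2), ld_block_r2 = c(1, 0.9),
                    maf_range = c(0.3, 0.3), seed = 202)
  g <- simulate_genotypes(cfg)
  expect_equal(pairwise_r2(g, 1, 2), 1.0)
  expect_identical(g$dosage[, 1], g$dosage[, 2])
  # calibrated copula block: 3 Monte-Carlo standard errors at n = 5000
  expect_lt(abs(pairwise_r2(g, 3, 4) - 0.9), 3 / sqrt(5000) * 2)
  expect_lt(pairwise_r2(g, 1, 3), 0.01)
  cfg2 <- sim_config(n_subjects = 5000, n_snps = 2, seed = 203)
  g2 <- simulate_genotypes(cfg2)
  expect_lt(pairwise_r2(g2, 1, 2), 0.01)
})

test_that("degenerate simulation configs are rejected", {
  expect_error(sim_config(n_subjects = 10, n_snps = 2,
                          ld_block_sizes = c(3), seed = 1),
               "larger than the panel")
  expect_error(sim_config(seed = 1, maf_range = c(0.01, 0.3)), "maf_range")
  expect_error(sim_config(seed = 1, stage_probs = c(0.5, 0.5, 0.2, 0)),
               "summing to 1")
  expect_error(sim_config(n_subjects = 10, n_snps = 2), "seed")
})

test_that("covariates match their configured distributions", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 1, seed = 303)
  cov <- simulate_covariates(cfg)
  # closed-form mean of Normal(61, 10) truncated to [20, 75]
  a <- (20 - 61) / 10; b <- (75 - 61) / 10
  mu_trunc <- 61 + 10 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(cov$age) - mu_trunc), 0.5)
  expect_true(all(cov$age >= 20 & cov$age <= 75))
  one <- simulate_covariates(sim_config(n_subjects = 1, n_snps = 1, seed = 9))
  expect_identical(nrow(one), 1L)
  expect_false(anyNA(one))
  deg <- simulate_covariates(sim_config(n_subjects = 50, n_snps = 1,
                                        stage_probs = c(0, 0, 0, 1), seed = 10))
  expect_true(all(deg$stage == 4))
})

test_that("null survival times follow the closed-form Weibull law", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 1, gamma = numeric(),
                    horizon = Inf, dropout_rate = 0, seed = 404)
  co <- simulate_cohort(cfg, effect = NULL)
  expect_true(all(co$pheno$event == 1))
  tt <- sort(co$pheno$time_years)
  F_theory <- 1 - exp(-cfg$weibull_scale * tt^cfg$weibull_shape)
  ks <- max(abs(seq_along(tt) / length(tt) - F_theory))
  expect_lt(ks, 0.02)
})

test_that("planted hazard ratios are recoverable from the true indicator", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 2, maf_range = c(0.5, 0.5),
                    gamma = numeric(), seed = 505)
  eff <- planted_effect("xor2", c(1, 2), log_hr = log(4))
  co <- simulate_cohort(cfg, eff)
  high <- survmdr:::effect_indicator(eff, co$geno)
  fit <- survival::coxph(survival::Surv(time_years, event) ~ high,
                         data = co$pheno, ties = "breslow")
  expect_lt(abs(exp(coef(fit)) - 4) / 4, 0.15)
})

test_that("a zero horizon censors everyone and blocks the null fit", {
  cfg <- sim_config(n_subjects = 50, n_snps = 1, horizon = 1e-10,
                    dropout_rate = 0, seed = 606)
  co <- simulate_cohort(cfg)
  expect_true(all(co$pheno$event == 0))
  expect_error(fit_cox_null(co$pheno, covariates = covariate_names()),
               "no events")
})

test_that("dichotomization follows the horizon rule and partitions the cohort", {
  df <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                       time_years = c(3, 7, 3, 5),
                       event = c(1L, 0L, 0L, 0L))
  out <- dichotomize_survival(df, horizon = 5)
  expect_identical(out$status5y, c(1L, 0L, NA_integer_, 0L))
  expect_identical(out$included5y, c(1L, 1L, 0L, 1L))
  co <- quick_cohort(707, n = 300)
  d5 <- co$pheno
  expect_identical(sum(d5$status5y == 1, na.rm = TRUE) +
                     sum(d5$status5y == 0, na.rm = TRUE) +
                     sum(d5$included5y == 0), 300L)
  # an observed event before the horizon is never excluded
  expect_true(all(d5$included5y[d5$event == 1 & d5$time_years <= 5] == 1))
  expect_error(dichotomize_survival(df, horizon = 0), "horizon")
})

test_that("planted-effect presets define the documented cells", {
  dom <- planted_effect("dominant", 3)
  expect_identical(sort(dom$high_cells[, 1]), c(1L, 2L))
  rec <- planted_effect("recessive", 3)
  expect_identical(rec$high_cells[, 1], 2L)
  xor3 <- planted_effect("xor3", 1:3)
  # parity construction: exactly 4 of the 8 heterozygosity classes are high
  classes <- unique(apply(xor3$high_cells == 1L, 1, paste, collapse = ""))
  expect_identical(length(classes), 4L)
  expect_true(all(rowSums(xor3$high_cells == 1L) %% 2 == 1))
  expect_error(planted_effect("dominant", 1, log_hr = Inf), "finite")
  expect_error(planted_effect("xor2", 1), "2 SNP")
})

test_that("xor2 at MAF 0.5 has no marginal dosage-risk correlation", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 2, maf_range = c(0.5, 0.5),
                    seed = 808)
  g <- simulate_genotypes(cfg)
  eff <- planted_effect("xor2", c(1, 2), log_hr = log(4))
  high <- survmdr:::effect_indicator(eff, g)
  expect_lt(abs(cor(g$dosage[, 1], high)), 0.03)
  expect_lt(abs(cor(g$dosage[, 2], high)), 0.03)
})

test_that("simulation is bit-reproducible under the seed", {
  cfg <- sim_config(n_subjects = 80, n_snps = 6,
                    ld_block_sizes = 3, ld_block_r2 = 0.8, seed = 909)
  eff <- planted_effect("dominant", 2, log_hr = log(2))
  a <- simulate_cohort(cfg, eff)
  b <- simulate_cohort(cfg, eff)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno, b$pheno)
})
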