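two_group_sheet <- function(n_ctl = 3, n_case = 3) {
  validate_sample_sheet(data.frame(
    sample_id = c(paste0("c", seq_len(n_ctl)), paste0("a", seq_len(n_case))),
    genotype = rep(c("control", "case"), c(n_ctl, n_case)),
    age_group = "child", stringsAsFactors = FALSE))
}

test_that("designs encode the factorial contrast correctly", {
  sheet <- tiny_sheet()
  ds <- build_design(sheet, "genotype_by_age")
  expect_equal(qr(ds$design)$rank, 4)
  # contrast on cell means (case.child, control.child, case.adult,
  # control.adult) = (2, 1, 4, 4) yields (2-1) - (4-4) = 1
  mu <- c(case.child = 2, control.child = 1, case.adult = 4,
          control.adult = 4)
  expect_equal(drop(ds$contrast %*% mu[names(ds$contrast)]), 1)

  ds2 <- build_design(two_group_sheet(), "genotype_only")
  expect_equal(qr(ds2$design)$rank, 2)

  no_adult_cases <- sheet[!(sheet$genotype == "case" &
                            sheet$age_group == "adult"), ]
  expect_error(build_design(no_adult_cases, "genotype_by_age"), "case.adult")
})

test_that("per-probe OLS matches the hand-computed two-group case", {
  sheet <- two_group_sheet()
  m <- matrix(c(0, 1, 2, 3, 4, 5), 1, dimnames = list("p1", sheet$sample_id))
  fit <- fit_probe_models(m, build_design(sheet, "genotype_only"))
  expect_equal(fit$effect, 3, ignore_attr = TRUE)
  expect_equal(fit$s_sq, 1)
  expect_equal(fit$df, 4)
  expect_equal(fit$unscaled_se, sqrt(1 / 3 + 1 / 3))

  # identical groups: zero effect; adding a constant changes nothing
  m2 <- rbind(p1 = c(1, 2, 3, 1, 2, 3))
  colnames(m2) <- sheet$sample_id
  expect_equal(fit_probe_models(m2, build_design(sheet, "genotype_only"))$effect,
               0, ignore_attr = TRUE)
  fit_shift <- fit_probe_models(m + 7, build_design(sheet, "genotype_only"))
  expect_equal(fit_shift$effect, fit$effect)
})

test_that("moderated t reduces to the ordinary t at d0 = 0", {
  sheet <- two_group_sheet()
  m <- matrix(c(0, 1, 2, 3, 4, 5), 1, dimnames = list("p1", sheet$sample_id))
  fit <- fit_probe_models(m, build_design(sheet, "genotype_only"))
  res <- moderated_test(fit$effect, fit$s_sq, fit$df, list(d0 = 0),
                        fit$unscaled_se)
  expect_equal(res$t_mod, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t_mod, 3.674, tolerance = 1e-3)
  expect_equal(res$df_total, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
})

test_that("moderation estimator handles degenerate and scaled inputs", {
  eq <- estimate_moderation(rep(1, 100), d = 4)
  expect_true(is.infinite(eq$d0))
  expect_equal(eq$s0_sq, 1, tolerance = 1e-9)

  set.seed(31)
  s2 <- 2 * rchisq(5000, 4) / 4
  fit1 <- estimate_moderation(s2, 4)
  fit2 <- estimate_moderation(2 * s2, 4)
  expect_equal(fit2$s0_sq, 2 * fit1$s0_sq, tolerance = 1e-8)
  expect_equal(fit2$d0, fit1$d0, tolerance = 1e-6)

  expect_error(estimate_moderation(rep(1, 5), 4), "at least 10")
})

test_that("shrinkage has the right fixed point and limits", {
  # all probes at the prior variance: moderated t = ordinary t for any d0
  effect <- c(1, -2, 0.5)
  s_sq <- rep(1.3, 3)
  for (d0 in c(0, 2, 50)) {
    res <- moderated_test(effect, s_sq, 4, list(d0 = d0, s0_sq = 1.3), 0.5)
    expect_equal(res$t_mod, effect / (0.5 * sqrt(1.3)), tolerance = 1e-12)
  }
  # d0 = Inf: posterior variance is the prior for every probe
  res_inf <- moderated_test(effect, c(0.1, 5, 80), 4,
                            list(d0 = Inf, s0_sq = 2), 1)
  expect_equal(res_inf$t_mod, effect / sqrt(2), tolerance = 1e-12)
  expect_error(moderated_test(1, 1, 0, list(d0 = 0), 1), "positive")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated pipeline agrees with an independent moderated fit", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_probes = 300, n_chrom = 2, var_inflation_df = 6,
                    seed = 5)
  man <- simulate_manifest(cfg)
  co <- simulate_cohort(man, cfg)
  m <- beta_to_m(co$beta)
  res <- diff_methylation(co$beta, co$sheet, mode = "genotype_by_age")

  cell <- factor(paste(co$sheet$genotype, co$sheet$age_group, sep = "."))
  design <- stats::model.matrix(~ 0 + cell)
  colnames(design) <- levels(cell)
  lfit <- limma::lmFit(m, design)
  cm <- limma::makeContrasts(
    (case.child - control.child) - (case.adult - control.adult),
    levels = design)
  efit <- limma::eBayes(limma::contrasts.fit(lfit, cm))

  # exact agreement of the OLS layer
  expect_equal(res$effect_m, unname(efit$coefficients[, 1]),
               tolerance = 1e-10)
  # hyperparameters and moderated inference agree closely (the two
  # method-of-moments variants differ only in finite-sample details)
  ours <- estimate_moderation(lfit$sigma^2, lfit$df.residual[1])
  expect_equal(ours$d0, efit$df.prior, tolerance = 0.05)
  expect_equal(ours$s0_sq, efit$s2.prior, tolerance = 0.02)
  expect_lt(max(abs(res$t_mod - efit$t[, 1]) / pmax(abs(efit$t[, 1]), 1)),
            0.005)
  expect_lt(max(abs(res$p - efit$p.value[, 1])), 0.005)
})

test_that("moderated p-values are calibrated on a small null cohort", {
  cfg <- sim_config(n_probes = 4000, n_control_child = 8, n_case_child = 8,
                    n_control_adult = 0, n_case_adult = 0, seed = 17)
  man <- simulate_manifest(cfg)
  co <- simulate_cohort(man, cfg)
  res <- diff_methylation(co$beta, co$sheet, mode = "genotype_only")
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 4000))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 4000))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(sign(res$t_mod) == sign(res$effect_m) | res$t_mod == 0))
})
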