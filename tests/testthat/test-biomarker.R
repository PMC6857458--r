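make_panel <- function(n = 24, p = 6, signal = 0, seed = 1,
                       n_pos = n %/% 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c(1, 0), c(n_pos, n - n_pos))
  if (signal > 0) x[y == 1, 1] <- x[y == 1, 1] + signal
  list(x = x, y = y)
}

test_that("full shrinkage returns the prevalence-only model", {
  pan <- make_panel(n = 20, p = 4, seed = 2, n_pos = 8)
  fit <- fit_lasso_logistic(pan$x, pan$y, lambda = Inf)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(0.4), tolerance = 1e-6)
  # balanced classes at lambda = Inf: intercept 0
  bal <- make_panel(n = 20, p = 4, seed = 3, n_pos = 10)
  fit_bal <- fit_lasso_logistic(bal$x, bal$y, lambda = Inf)
  expect_equal(fit_bal$intercept, 0, tolerance = 1e-8)
  # any lambda above lambda_max also gives the all-zero model
  lmax <- lasso_lambda_max(pan$x, pan$y)
  fit2 <- fit_lasso_logistic(pan$x, pan$y, lambda = lmax * 1.001)
  expect_true(all(fit2$coefficients == 0))
  expect_equal(fit2$intercept, qlogis(0.4), tolerance = 1e-4)
  # ... while just below it at least one coefficient activates
  fit3 <- fit_lasso_logistic(pan$x, pan$y, lambda = lmax * 0.8)
  expect_gt(sum(fit3$coefficients != 0), 0)
})

test_that("KKT conditions hold at every returned solution", {
  for (seed in 1:5) {
    pan <- make_panel(n = 30, p = 8, signal = 1, seed = seed, n_pos = 15)
    std <- dmrkit:::standardize_columns(pan$x)
    lam <- lasso_lambda_max(pan$x, pan$y) * 0.3
    fit <- fit_lasso_logistic(pan$x, pan$y, lam)
    eta <- drop(fit$intercept_std + std$x %*% fit$beta_std)
    prob <- 1 / (1 + exp(-eta))
    g <- colMeans(std$x * (pan$y - prob))
    zero <- fit$beta_std == 0
    expect_true(all(abs(g[zero]) <= lam + 1e-6))
    if (any(!zero)) {
      expect_equal(unname(g[!zero]), lam * sign(fit$beta_std[!zero]),
                   tolerance = 1e-5, ignore_attr = TRUE)
    }
    # intercept score is zero
    expect_lt(abs(mean(pan$y - prob)), 1e-6)
  }
})

test_that("coordinate descent matches a generic convex solver", {
  for (seed in 1:3) {
    pan <- make_panel(n = 30, p = 5, signal = 1.2, seed = seed + 10,
                      n_pos = 15)
    std <- dmrkit:::standardize_columns(pan$x)
    lam <- lasso_lambda_max(pan$x, pan$y) * 0.4
    fit <- fit_lasso_logistic(pan$x, pan$y, lam)
    oracle <- lasso_lbfgs_oracle(std$x, pan$y, lam)
    expect_lt(max(abs(unname(fit$beta_std) - oracle$beta)), 1e-5)
    expect_lt(abs(fit$intercept_std - oracle$b0), 1e-5)
    ours <- lasso_objective(fit$beta_std, fit$intercept_std, std$x, pan$y,
                            lam)
    expect_lte(ours, oracle$value + 1e-8)
  }
})

test_that("solutions agree with an independent penalized fit", {
  skip_if_not_installed("glmnet")
  pan <- make_panel(n = 40, p = 6, signal = 1, seed = 9, n_pos = 20)
  lam <- 0.05
  ours <- fit_lasso_logistic(pan$x, pan$y, lam)
  g <- glmnet::glmnet(pan$x, pan$y, family = "binomial", lambda = lam,
                      standardize = TRUE, thresh = 1e-14)
  expect_equal(unname(ours$coefficients), as.numeric(g$beta),
               tolerance = 1e-6)
  expect_equal(ours$intercept, as.numeric(g$a0), tolerance = 1e-6)
})

test_that("cross-validated penalty selection behaves at the extremes", {
  # pure noise: the conservative (1-SE) selector stays at or near full
  # shrinkage; the min-deviance selector is known to chase spurious CV
  # minima on noise panels of this size
  near_null <- 0
  for (seed in 1:20) {
    pan <- make_panel(n = 23, p = 10, signal = 0, seed = 100 + seed,
                      n_pos = 11)
    sel <- select_lambda_cv(pan$x, pan$y, nlambda = 50, one_se = TRUE)
    fit <- fit_lasso_logistic(pan$x, pan$y, sel$lambda)
    if (sum(fit$coefficients != 0) <= 1) near_null <- near_null + 1
  }
  expect_gte(near_null, 16)  # >= 80% of seeds

  # a strongly separating feature is selected
  pan <- make_panel(n = 23, p = 10, signal = 3, seed = 55, n_pos = 11)
  sel <- select_lambda_cv(pan$x, pan$y)
  fit <- fit_lasso_logistic(pan$x, pan$y, sel$lambda)
  expect_true(fit$coefficients["f1"] != 0)

  # the 1-SE rule never selects a smaller penalty than the minimum
  sel1 <- select_lambda_cv(pan$x, pan$y, one_se = TRUE)
  expect_gte(sel1$lambda, sel1$lambda_min)
})

test_that("LOOCV scores separate a strong panel and flag degenerate splits", {
  pan <- make_panel(n = 16, p = 5, signal = 3, seed = 77, n_pos = 8)
  lo <- loocv_scores(pan$x, pan$y, nlambda = 40)
  expect_length(lo$scores, 16)
  expect_false(any(lo$flagged))
  expect_gt(roc_auc(lo$scores, pan$y)$auc, 0.9)

  # fixed-lambda mode runs the same splits faster
  lam <- select_lambda_cv(pan$x, pan$y, nlambda = 40)$lambda
  lo_fix <- loocv_scores(pan$x, pan$y, lambda = lam)
  expect_true(all(is.finite(lo_fix$scores)))

  expect_error(loocv_scores(pan$x[1:3, ], pan$y[1:3]), "at least 4")
})

test_that("AUC matches pair counting, handles ties, and is rank-invariant", {
  r <- roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r_tie <- roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(r_tie$auc, 0.5)

  r_mix <- roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(r_mix$auc, 3 / 4)

  set.seed(41)
  sc <- rnorm(30); y <- rbinom(30, 1, 0.5)
  if (length(unique(y)) == 2) {
    base <- roc_auc(sc, y)
    expect_equal(base$auc, auc_pair_count(sc, y), tolerance = 1e-12)
    mono <- roc_auc(exp(2 * sc) + 5, y)   # strictly monotone transform
    expect_equal(mono$auc, base$auc, tolerance = 1e-12)
    expect_true(base$ci95[1] <= base$auc && base$auc <= base$ci95[2])
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC, SE and CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  sc <- rnorm(20); lb <- rep(c(0, 1), 10)
  r <- roc_auc(sc, lb)
  pr <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_equal(r$auc_se, sqrt(pROC::var(pr)), tolerance = 1e-10)

  sc2 <- sc + rnorm(20, 0, 0.5)
  dt <- delong_test(sc, sc2, lb)
  rt <- pROC::roc.test(pr, pROC::roc(lb, sc2, quiet = TRUE,
                                     direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dt$p, rt$p.value, tolerance = 1e-10)
})

test_that("DeLong test is degenerate on self-comparison and matches permutation", {
  set.seed(8)
  y <- rep(c(1, 0), 4)
  sa <- rnorm(8)
  self <- delong_test(sa, sa, y)
  expect_equal(self$p, 1)
  expect_equal(self$z, 0)
  expect_true(self$degenerate)

  sb <- sa + rnorm(8, 0, 1)
  dt <- delong_test(sa, sb, y)
  perm <- delong_perm_oracle(sa, sb, y, n_rep = 4000, seed = 5)
  expect_lt(abs(dt$p - perm), 0.1)
})
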