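as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (is.null(positive)) {
    lv <- sort(unique(labels))
    positive <- if ("case" %in% lv) "case" else if ("cALD" %in% lv) "cALD"
      else lv[length(lv)]
  }
  as.numeric(labels == positive)
}

standardize_columns <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- sqrt(colMeans(xc^2))
  scale[scale == 0] <- 1
  list(x = sweep(xc, 2, scale, "/"), center = center, scale = scale)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Cyclic coordinate descent on the IRLS quadratic approximation of the
# L1-penalized logistic likelihood (compiled; see src/lasso_cd.cpp).
lasso_logistic_cd <- function(xs, y, lambda, tol = 1e-7, max_iter = 250) {
  fit <- cpp_lasso_path(xs, y, lambda, tol, max_iter)
  if (!all(fit$converged)) {
    stop(errorCondition(
      "coordinate descent did not converge",
      class = c("lasso_nonconvergence", "error", "condition"),
      iterate = list(beta = drop(fit$betas), b0 = fit$b0s[1])))
  }
  list(beta = drop(fit$betas[, 1]), b0 = fit$b0s[1], converged = TRUE)
}

#' Fit an L1-penalized (LASSO) logistic regression
#'
#' Maximizes the penalized mean log-likelihood
#' \code{(1/n) sum loglik - lambda * sum |beta_j|} (intercept unpenalized)
#' by cyclic coordinate descent on the iteratively reweighted quadratic
#' approximation; features are standardized internally to zero mean and
#' unit (population) SD. At the solution the Karush-Kuhn-Tucker conditions
#' hold: each zero coefficient's mean score \code{|mean(x_j (y - p))|} is
#' bounded by lambda, each nonzero one attains it with matching sign.
#'
#' @param x samples x features numeric matrix.
#' @param y binary labels (logical, 0/1, or character with \code{positive}).
#' @param lambda penalty (>= 0); may be \code{Inf} for full shrinkage.
#' @param positive positive-class label for character \code{y}.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum IRLS iterations.
#' @return object of class \code{"biomarker_model"}: standardized-scale
#'   coefficients (\code{beta_std}, \code{intercept_std}), original-scale
#'   ones (\code{coefficients}, \code{intercept}), \code{lambda} and the
#'   standardization parameters.
#' @export
fit_lasso_logistic <- function(x, y, lambda, positive = NULL,
                               tol = 1e-7, max_iter = 250) {
  y <- as_binary_labels(y, positive)
  if (lambda < 0) stop("lambda must be >= 0")
  std <- standardize_columns(as.matrix(x))
  if (is.infinite(lambda)) {
    prev <- min(max(mean(y), 1e-5), 1 - 1e-5)
    fit <- list(beta = numeric(ncol(std$x)), b0 = log(prev / (1 - prev)))
  } else {
    fit <- lasso_logistic_cd(std$x, y, lambda, tol = tol,
                             max_iter = max_iter)
  }
  coef_orig <- fit$beta / std$scale
  intercept <- fit$b0 - sum(fit$beta * std$center / std$scale)
  structure(list(
    intercept = intercept,
    coefficients = stats::setNames(coef_orig, colnames(x)),
    intercept_std = fit$b0,
    beta_std = stats::setNames(fit$beta, colnames(x)),
    lambda = lambda, center = std$center, scale = std$scale),
    class = "biomarker_model")
}

#' @export
predict.biomarker_model <- function(object, newx, type = c("response",
                                                           "link"), ...) {
  type <- match.arg(type)
  eta <- drop(object$intercept + as.matrix(newx) %*% object$coefficients)
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' Closed-form largest useful penalty
#'
#' The smallest lambda at which every coefficient is exactly zero:
#' \code{max_j |mean(x_j (y - ybar))|} over standardized features.
#'
#' @inheritParams fit_lasso_logistic
#' @return scalar lambda_max.
#' @export
lasso_lambda_max <- function(x, y, positive = NULL) {
  y <- as_binary_labels(y, positive)
  std <- standardize_columns(as.matrix(x))
  max(abs(colMeans(std$x * (y - mean(y)))))
}

lasso_path_fit <- function(xs, y, lambdas, tol = 1e-7) {
  fit <- cpp_lasso_path(xs, y, lambdas, tol, 250L)
  if (!all(fit$converged)) {
    stop(errorCondition(
      "coordinate descent did not converge along the lambda path",
      class = c("lasso_nonconvergence", "error", "condition"),
      iterate = fit))
  }
  list(betas = fit$betas, b0s = fit$b0s)
}

binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  -2 * (y * log(prob) + (1 - y) * log(1 - prob))
}

#' Select the LASSO penalty by cross-validation
#'
#' Builds a path of \code{nlambda} log-spaced penalties from the
#' closed-form lambda_max down to \code{lambda_min_ratio * lambda_max} and
#' selects the penalty minimizing mean held-out binomial deviance under
#' leave-one-out cross-validation (the default; LOO has no fold
#' randomness, so selection is deterministic). Degenerate single-class
#' training folds predict the training prevalence. The 1-SE rule (largest
#' penalty within one standard error of the minimum) is available.
#'
#' @inheritParams fit_lasso_logistic
#' @param nlambda number of penalties on the path (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of lambda_max.
#' @param nfolds number of folds; \code{NULL} (default) means leave-one-out.
#' @param one_se use the 1-SE rule instead of the minimum.
#' @return list with the selected \code{lambda}, the \code{path}, mean
#'   held-out deviance \code{cvm} and its SE \code{cvsd}.
#' @export
select_lambda_cv <- function(x, y, positive = NULL, nlambda = 100,
                             lambda_min_ratio = 0.01, nfolds = NULL,
                             one_se = FALSE) {
  x <- as.matrix(x)
  y <- as_binary_labels(y, positive)
  n <- nrow(x)
  lmax <- lasso_lambda_max(x, y)
  if (lmax <= 0) lmax <- 1e-3
  path <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  folds <- if (is.null(nfolds)) seq_len(n) else
    rep_len(seq_len(nfolds), n)
  dev <- matrix(NA_real_, n, nlambda)
  for (f in unique(folds)) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    ytr <- y[train]
    if (length(unique(ytr)) < 2) {
      dev[test, ] <- binomial_deviance(y[test], mean(ytr))
      next
    }
    std <- standardize_columns(x[train, , drop = FALSE])
    fit <- lasso_path_fit(std$x, ytr, path)
    xte <- sweep(sweep(x[test, , drop = FALSE], 2, std$center), 2,
                 std$scale, "/")
    eta <- sweep(xte %*% fit$betas, 2, fit$b0s, "+")
    prob <- 1 / (1 + exp(-eta))
    dev[test, ] <- binomial_deviance(y[test], prob)
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(n)
  imin <- which.min(cvm)
  sel <- if (one_se) {
    min(which(cvm <= cvm[imin] + cvsd[imin]))
  } else imin
  list(lambda = path[sel], path = path, cvm = cvm, cvsd = cvsd,
       lambda_min = path[imin])
}

#' Leave-one-out cross-validated scores
#'
#' For each sample: refit the LASSO logistic model on the remaining n - 1
#' samples and score the held-out one. By default the penalty is reselected
#' inside each training split (honest nested leave-one-out); passing a
#' fixed \code{lambda} skips the inner selection, which is faster but
#' slightly optimistic. Single-class training splits score the held-out
#' sample at the training prevalence and are flagged.
#'
#' @inheritParams select_lambda_cv
#' @param lambda optional fixed penalty; \code{NULL} (default) means nested
#'   reselection per split.
#' @return list with \code{scores} (per-sample held-out probabilities),
#'   \code{lambda} (penalty used per split) and \code{flagged} (splits that
#'   fell back to prevalence prediction).
#' @export
loocv_scores <- function(x, y, positive = NULL, lambda = NULL,
                         nlambda = 100, lambda_min_ratio = 0.01) {
  x <- as.matrix(x)
  y <- as_binary_labels(y, positive)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples for LOOCV")
  scores <- numeric(n)
  lambdas <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    ytr <- y[train]
    if (length(unique(ytr)) < 2) {
      scores[i] <- mean(ytr); lambdas[i] <- NA_real_; flagged[i] <- TRUE
      next
    }
    lam <- if (is.null(lambda)) {
      select_lambda_cv(x[train, , drop = FALSE], ytr, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio)$lambda
    } else lambda
    fit <- fit_lasso_logistic(x[train, , drop = FALSE], ytr, lam)
    scores[i] <- predict(fit, x[i, , drop = FALSE])
    lambdas[i] <- lam
  }
  names(scores) <- rownames(x)
  list(scores = scores, lambda = lambdas, flagged = flagged)
}

# Mann-Whitney AUC and DeLong structural components.
delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       n1 = n1, n0 = n0)
}

#' ROC curve summary with DeLong variance
#'
#' AUC by the Mann-Whitney statistic (ties count 1/2), standard error from
#' the DeLong structural components, normal-approximation 95% CI truncated
#' to [0, 1], and the Youden-optimal operating threshold with its
#' sensitivity and specificity (positive calls are scores >= threshold).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary labels; see [fit_lasso_logistic()] conventions.
#' @param positive positive-class label for character \code{labels}.
#' @return object of class \code{"roc_result"} with \code{auc},
#'   \code{auc_se}, \code{ci95}, \code{threshold}, \code{sensitivity},
#'   \code{specificity} and the per-sample scores.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(unique(y)) < 2) stop("both classes must be present")
  comp <- delong_components(scores, y)
  v1 <- if (comp$n1 > 1) stats::var(comp$v10) else 0
  v0 <- if (comp$n0 > 1) stats::var(comp$v01) else 0
  se <- sqrt(v1 / comp$n1 + v0 / comp$n0)
  ci <- pmin(pmax(comp$auc + c(-1, 1) * 1.96 * se, 0), 1)
  su <- sort(unique(scores))
  thr <- c(-Inf, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] < t), numeric(1))
  best <- which.max(sens + spec - 1)
  structure(list(auc = comp$auc, auc_se = se, ci95 = ci,
                 threshold = thr[best], sensitivity = sens[best],
                 specificity = spec[best], scores = scores, labels = y),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f); Youden threshold %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
    x$auc, x$auc_se, x$ci95[1], x$ci95[2], x$threshold,
    100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two markers measured on the same
#' samples: z = delta-AUC / sqrt(var), with the variance of the difference
#' built from the covariance of the DeLong structural components; two-sided
#' normal p. Identical score vectors (zero variance) are degenerate:
#' z = 0, p = 1.
#'
#' @param scores_a,scores_b scores of the two markers on the same samples.
#' @param labels shared binary labels.
#' @param positive positive-class label for character \code{labels}.
#' @return list with \code{delta_auc}, \code{z}, \code{p} and
#'   \code{degenerate}.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(y)) {
    stop("both markers and labels must cover the same samples")
  }
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  d10 <- ca$v10 - cb$v10
  d01 <- ca$v01 - cb$v01
  v <- (if (ca$n1 > 1) stats::var(d10) else 0) / ca$n1 +
    (if (ca$n0 > 1) stats::var(d01) else 0) / ca$n0
  delta <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    return(list(delta_auc = delta, z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(v)
  list(delta_auc = delta, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}
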