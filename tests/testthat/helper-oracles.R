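# Independent oracles used to freeze expected values. These are brute-force
# or closed-form re-derivations, kept deliberately separate from the package
# code paths they check.

# chi-square survival for even df = 2k in closed form:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
chisq_surv_even_df <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# step-up BH by hand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by exhaustive table enumeration
# (sum of probabilities of tables no more likely than the observed one)
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper tail by direct summation of the pmf
hyper_upper_enum <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hypergeometric upper tail by enumerating every n-subset of the universe
hyper_upper_subsets <- function(N, K, n, k) {
  subs <- utils::combn(N, n)
  mean(colSums(subs <= K) >= k)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mw_enum_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  assignments <- utils::combn(na + nb, na)
  us <- apply(assignments, 2, function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Mann-Whitney AUC by explicit pair counting
auc_pair_count <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# paired label-swap permutation p for the difference of two correlated AUCs
delong_perm_oracle <- function(scores_a, scores_b, y, n_rep = 10000,
                               seed = 1) {
  set.seed(seed)
  obs <- abs(auc_pair_count(scores_a, y) - auc_pair_count(scores_b, y))
  n <- length(y)
  hits <- 0
  for (r in seq_len(n_rep)) {
    swap <- stats::runif(n) < 0.5
    sa <- ifelse(swap, scores_b, scores_a)
    sb <- ifelse(swap, scores_a, scores_b)
    if (abs(auc_pair_count(sa, y) - auc_pair_count(sb, y)) >= obs - 1e-12) {
      hits <- hits + 1
    }
  }
  hits / n_rep
}

# penalized logistic objective (minimization form), for generic-solver checks
lasso_objective <- function(beta_std, b0, xs, y, lambda) {
  eta <- drop(b0 + xs %*% beta_std)
  -mean(y * eta - log1p(exp(eta))) + lambda * sum(abs(beta_std))
}

# generic convex solver for the same objective via the split beta = a - b,
# a,b >= 0 reformulation and box-constrained L-BFGS
lasso_lbfgs_oracle <- function(xs, y, lambda) {
  p <- ncol(xs)
  obj <- function(par) {
    b0 <- par[1]
    beta <- par[2:(p + 1)] - par[(p + 2):(2 * p + 1)]
    eta <- drop(b0 + xs %*% beta)
    -mean(y * eta - log1p(exp(eta))) +
      lambda * sum(par[-1])
  }
  grad <- function(par) {
    b0 <- par[1]
    beta <- par[2:(p + 1)] - par[(p + 2):(2 * p + 1)]
    eta <- drop(b0 + xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g_beta <- -colMeans(xs * (y - mu))
    c(-mean(y - mu), g_beta + lambda, -g_beta + lambda)
  }
  fit <- stats::optim(rep(0, 2 * p + 1), obj, grad, method = "L-BFGS-B",
                      lower = c(-Inf, rep(0, 2 * p)),
                      control = list(maxit = 2000, factr = 10))
  list(b0 = fit$par[1],
       beta = fit$par[2:(p + 1)] - fit$par[(p + 2):(2 * p + 1)],
       value = fit$value)
}
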