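#' Build a design/contrast specification
#'
#' Two designs are supported. \code{genotype_only} pools children and adults
#' and tests case vs control. \code{genotype_by_age} uses group-means coding
#' over the four cohort cells and the single interaction contrast
#' (case.child - control.child) - (case.adult - control.adult), i.e. the
#' genotype-by-age interaction that isolates phenotype differences after
#' removing shared genotype and age effects.
#'
#' @param sheet sample sheet.
#' @param mode \code{"genotype_only"} or \code{"genotype_by_age"}.
#' @return list of class \code{"design_spec"} with the design matrix
#'   (samples x coefficients), the contrast vector and the mode.
#' @export
build_design <- function(sheet, mode = c("genotype_by_age", "genotype_only")) {
  mode <- match.arg(mode)
  if (mode == "genotype_only") {
    x <- cbind(intercept = 1, case = as.numeric(sheet$genotype == "case"))
    contrast <- c(intercept = 0, case = 1)
  } else {
    cell <- paste(sheet$genotype, sheet$age_group, sep = ".")
    levels_needed <- c("case.child", "control.child", "case.adult",
                       "control.adult")
    missing <- setdiff(levels_needed, unique(cell))
    if (length(missing) > 0) {
      stop("factorial design requires samples in every cell; empty: ",
           paste(missing, collapse = ", "))
    }
    x <- vapply(levels_needed, function(l) as.numeric(cell == l),
                numeric(nrow(sheet)))
    colnames(x) <- levels_needed
    contrast <- c(case.child = 1, control.child = -1,
                  case.adult = -1, control.adult = 1)
  }
  rownames(x) <- sheet$sample_id
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  structure(list(design = x, contrast = contrast, mode = mode),
            class = "design_spec")
}

#' Per-probe ordinary least squares fits
#'
#' Fits the design to every probe's M values by OLS and returns the contrast
#' estimate, residual variance and residual degrees of freedom, plus the
#' contrast leverage factor sqrt(c' (X'X)^-1 c) that converts a residual SD
#' into the contrast's standard error.
#'
#' @param m M-value matrix (probes x samples).
#' @param design a \code{design_spec} from [build_design()].
#' @return list with \code{effect}, \code{s_sq}, \code{df} (scalar),
#'   \code{unscaled_se} (scalar) and \code{probe_id}.
#' @export
fit_probe_models <- function(m, design) {
  x <- design$design
  if (ncol(m) != nrow(x)) stop("sample dimension mismatch")
  if (ncol(m) <= ncol(x)) stop("need more samples than coefficients")
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) stop("design matrix is rank deficient")
  coef <- qr.coef(qr_x, t(m))                    # coefficients x probes
  fitted <- x %*% coef
  res <- t(m) - fitted
  df <- nrow(x) - qr_x$rank
  s_sq <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  cvec <- design$contrast[colnames(x)]
  unscaled_se <- sqrt(drop(t(cvec) %*% xtx_inv %*% cvec))
  effect <- drop(crossprod(coef, cvec))
  list(probe_id = rownames(m), effect = effect, s_sq = unname(s_sq),
       df = df, unscaled_se = unscaled_se)
}

# Newton inversion of the trigamma function, as used in the
# method-of-moments fit of the variance prior.
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & x <= 0] <- Inf
  y <- 0.5 + 1 / x[ok]
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[ok]) / psigamma(y, 2)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  out[ok] <- y
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of the scaled inverse chi-square prior for probe
#' variances, matching the mean and variance of log s^2 against the scaled
#' log-F distribution it implies (trigamma matching). Returns the prior
#' degrees of freedom \code{d0} (possibly \code{Inf}, i.e. complete
#' shrinkage) and the prior variance \code{s0_sq}.
#'
#' @param s_sq vector of per-probe residual variances.
#' @param d residual degrees of freedom (scalar).
#' @return list with \code{d0} and \code{s0_sq}.
#' @export
estimate_moderation <- function(s_sq, d) {
  s_sq <- s_sq[is.finite(s_sq) & s_sq >= 0]
  if (length(s_sq) < 10) stop("need at least 10 probes to fit the prior")
  if (d < 1) stop("residual df must be >= 1")
  z <- log(pmax(s_sq, 1e-300))
  if (stats::var(z) < 1e-15) {
    # exactly equal variances: complete shrinkage onto the common value
    return(list(d0 = Inf, s0_sq = exp(mean(z))))
  }
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-tests
#'
#' Shrinks each probe's residual variance toward the prior,
#' s2_post = (d0 * s0_sq + d * s2) / (d0 + d), and tests the contrast with
#' t = effect / (unscaled_se * s_post) on d + d0 degrees of freedom. With
#' d0 = 0 this is the ordinary t-test; as d0 grows all probes share the
#' prior variance.
#'
#' @param effect vector of contrast estimates.
#' @param s_sq vector of residual variances.
#' @param d residual df (scalar).
#' @param params moderation parameters from [estimate_moderation()], or
#'   \code{list(d0 = 0)} for no moderation.
#' @param unscaled_se contrast leverage factor from [fit_probe_models()].
#' @param probe_id optional probe ids.
#' @return data.frame with \code{probe_id}, \code{effect}, \code{t_mod},
#'   \code{df_total}, \code{p} (two-sided).
#' @export
moderated_test <- function(effect, s_sq, d, params, unscaled_se,
                           probe_id = NULL) {
  d0 <- params$d0
  if (d0 + d <= 0) stop("total degrees of freedom must be positive")
  s_post_sq <- if (is.infinite(d0)) {
    rep(params$s0_sq, length(s_sq))
  } else if (d0 == 0) {
    s_sq
  } else {
    (d0 * params$s0_sq + d * s_sq) / (d0 + d)
  }
  t_mod <- effect / (unscaled_se * sqrt(s_post_sq))
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(probe_id = if (is.null(probe_id)) seq_along(effect) else probe_id,
             effect = effect, t_mod = t_mod, df_total = df_total, p = p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity enforcement;
#' ties keep their input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe differential methylation analysis
#'
#' The full probe-level pipeline: transform beta to M, build the requested
#' design, fit per-probe OLS models, moderate the variances by empirical
#' Bayes (unless \code{moderation = "none"}), compute moderated t-tests and
#' BH-adjust. The reported \code{delta_beta} is the contrast applied to the
#' per-cell mean beta values (the beta scale is kept for reporting while
#' testing is done on M).
#'
#' @param beta beta matrix (probes x samples), columns matching the sheet.
#' @param sheet sample sheet.
#' @param mode design mode, see [build_design()].
#' @param moderation \code{"moments"} (default) or \code{"none"}.
#' @param eps clamp bound for the M transform.
#' @return data.frame with columns \code{probe_id}, \code{effect_m},
#'   \code{delta_beta}, \code{t_mod}, \code{df}, \code{p}, \code{p_adj}.
#' @export
diff_methylation <- function(beta, sheet,
                             mode = c("genotype_by_age", "genotype_only"),
                             moderation = c("moments", "none"),
                             eps = 1e-6) {
  mode <- match.arg(mode)
  moderation <- match.arg(moderation)
  if (!identical(colnames(beta), sheet$sample_id)) {
    beta <- beta[, sheet$sample_id, drop = FALSE]
  }
  m <- beta_to_m(beta, eps)
  design <- build_design(sheet, mode)
  fit <- fit_probe_models(m, design)
  params <- if (moderation == "moments") {
    estimate_moderation(fit$s_sq, fit$df)
  } else list(d0 = 0)
  res <- moderated_test(fit$effect, fit$s_sq, fit$df, params,
                        fit$unscaled_se, probe_id = fit$probe_id)
  # contrast of per-cell mean beta for reporting
  if (mode == "genotype_only") {
    db <- rowMeans(beta[, sheet$genotype == "case", drop = FALSE]) -
      rowMeans(beta[, sheet$genotype == "control", drop = FALSE])
  } else {
    cell_mean <- function(g, a) {
      rowMeans(beta[, sheet$genotype == g & sheet$age_group == a,
                    drop = FALSE])
    }
    db <- (cell_mean("case", "child") - cell_mean("control", "child")) -
      (cell_mean("case", "adult") - cell_mean("control", "adult"))
  }
  data.frame(probe_id = res$probe_id, effect_m = res$effect,
             delta_beta = unname(db), t_mod = res$t_mod, df = res$df_total,
             p = res$p, p_adj = adjust_bh(res$p),
             stringsAsFactors = FALSE)
}
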