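#' Array vs pyrosequencing concordance
#'
#' Pools matched (probe, sample) pairs across the validation panel and
#' computes the Pearson correlation between array beta values (0-1) and
#' pyrosequencing percent methylation (0-100, rescaled internally), with
#' the usual t-based test of r = 0.
#'
#' @param array_beta matrix or vector of array beta values.
#' @param pyro_pct matched matrix or vector of pyrosequencing values on the
#'   0-100 scale.
#' @return list with \code{n}, \code{r}, \code{p}.
#' @export
array_pyro_concordance <- function(array_beta, pyro_pct) {
  a <- as.numeric(array_beta)
  b <- as.numeric(pyro_pct) / 100
  if (length(a) != length(b)) stop("inputs must be matched pairs")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 matched pairs")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(n = length(a), r = unname(ct$estimate), p = ct$p.value)
}

#' Methylation-expression concordance
#'
#' Joins per-gene DMR delta-beta values with per-gene expression
#' differences, computes their Pearson correlation and counts genes in the
#' concordant quadrants (hypermethylated & downregulated, hypomethylated &
#' upregulated) — the coordination expected when promoter methylation
#' represses transcription.
#'
#' @param dmr_delta_beta named numeric vector: per-gene DMR mean delta-beta.
#' @param expr_diff named numeric vector: per-gene log2 expression
#'   difference (case - control).
#' @return list with \code{n} genes, \code{r}, \code{p},
#'   \code{n_concordant}, \code{concordant_fraction} and the merged
#'   \code{table}.
#' @export
meth_expression_concordance <- function(dmr_delta_beta, expr_diff) {
  genes <- intersect(names(dmr_delta_beta), names(expr_diff))
  if (length(genes) == 0) stop("no overlapping genes")
  db <- dmr_delta_beta[genes]
  ed <- expr_diff[genes]
  concordant <- (db > 0 & ed < 0) | (db < 0 & ed > 0)
  ct <- if (length(genes) >= 3) stats::cor.test(db, ed) else NULL
  list(n = length(genes),
       r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       p = if (is.null(ct)) NA_real_ else ct$p.value,
       n_concordant = sum(concordant),
       concordant_fraction = mean(concordant),
       table = data.frame(gene = genes, delta_beta = unname(db),
                          expr_diff = unname(ed),
                          concordant = unname(concordant),
                          stringsAsFactors = FALSE))
}

#' Relative expression by the comparative Ct method
#'
#' 2^-(Ct_target - Ct_reference); technical duplicates are averaged before
#' calling this. Adding a constant to both Ct values leaves the result
#' unchanged.
#'
#' @param ct_target Ct of the gene of interest.
#' @param ct_reference Ct of the reference gene.
#' @return relative expression value(s).
#' @export
ddct <- function(ct_target, ct_reference) {
  2^-(ct_target - ct_reference)
}

#' Normality-gated group comparison
#'
#' Dispatches the comparison of a numeric outcome across groups the way
#' small validation panels are analyzed: Shapiro-Wilk normality per group
#' at alpha = 0.05; if all groups look normal, Student's t-test (2 groups)
#' or one-way ANOVA (> 2); otherwise the Wilcoxon rank-sum (2) or
#' Kruskal-Wallis (> 2) test. Groups with fewer than 3 values cannot be
#' gate-tested, so the nonparametric branch is forced and flagged.
#'
#' @param values numeric outcome vector.
#' @param group_labels group factor (>= 2 levels).
#' @param alpha normality-gate level (default 0.05).
#' @return list with \code{test} (name of the test run), \code{statistic},
#'   \code{p}, \code{normal} (gate outcome) and \code{forced_nonparametric}.
#' @export
auto_group_test <- function(values, group_labels, alpha = 0.05) {
  group_labels <- factor(group_labels)
  k <- nlevels(group_labels)
  if (k < 2) stop("need at least 2 groups")
  groups <- split(values, group_labels)
  forced <- any(lengths(groups) < 3)
  normal <- if (forced) FALSE else all(vapply(groups, function(g) {
    if (length(unique(g)) == 1) return(FALSE)  # degenerate: not normal
    stats::shapiro.test(g)$p.value > alpha
  }, logical(1)))
  if (normal) {
    if (k == 2) {
      ht <- stats::t.test(groups[[1]], groups[[2]])
      out <- list(test = "t", statistic = unname(ht$statistic),
                  p = ht$p.value)
    } else {
      ht <- summary(stats::aov(values ~ group_labels))[[1]]
      out <- list(test = "anova", statistic = ht$`F value`[1],
                  p = ht$`Pr(>F)`[1])
    }
  } else {
    if (k == 2) {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      p <- ht$p.value
      if (is.nan(p)) p <- 1  # complete ties: no evidence either way
      out <- list(test = "wilcoxon", statistic = unname(ht$statistic),
                  p = p)
    } else {
      ht <- stats::kruskal.test(values, group_labels)
      out <- list(test = "kruskal", statistic = unname(ht$statistic),
                  p = ht$p.value)
    }
  }
  c(out, list(normal = normal, forced_nonparametric = forced))
}

#' Mann-Whitney U test
#'
#' Exact p-value when both samples are small (min n <= 8) and tie-free;
#' normal approximation with tie correction otherwise. Returns the U
#' statistic for the first sample (U_a + U_b = n_a * n_b).
#'
#' @param values_a,values_b numeric samples.
#' @return list with \code{u} and \code{p}.
#' @export
mann_whitney_u <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both samples must be non-empty")
  }
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            exact = exact))
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # complete ties
  list(u = unname(ht$statistic), p = p)
}
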