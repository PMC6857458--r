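#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact conditional test; the two-sided p sums the probabilities
#' of all tables (with the observed margins) no more likely than the
#' observed one. The reported odds ratio is the sample odds ratio
#' a*d / (b*c); with a zero margin the test is degenerate (p = 1, odds
#' ratio NaN).
#'
#' @param a,b,c,d non-negative integer cell counts, rows = group
#'   membership, columns = class membership.
#' @return list with \code{odds_ratio}, \code{p} and \code{degenerate}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NaN, p = 1, degenerate = TRUE))
  }
  or <- (a * d) / (b * c)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p, degenerate = FALSE)
}

#' Positional feature-distribution tests
#'
#' Compares the CpG-feature (island/shore/shelf/open sea) or gene-feature
#' (promoter/body/intergenic) distribution of a set of DMR CpGs against all
#' probes on the (filtered) array, one two-sided Fisher's exact test per
#' class. The background column is the whole array, DMR CpGs included, as
#' when DMR CpGs are compared with CpGs on the total array.
#'
#' @param dmr_cpgs character vector of probe ids (e.g. all CpGs in
#'   hypermethylated DMRs); must be non-empty and present in the manifest.
#' @param manifest probe manifest restricted to the filtered background.
#' @param feature_axis \code{"cpg_feature"} or \code{"gene_feature"}.
#' @return data.frame with one row per class: counts \code{a} (DMR CpGs in
#'   class), \code{b} (DMR CpGs out of class), \code{c}, \code{d}
#'   (background in/out of class), \code{odds_ratio} and \code{p}.
#' @export
feature_distribution <- function(dmr_cpgs, manifest,
                                 feature_axis = c("cpg_feature",
                                                  "gene_feature")) {
  feature_axis <- match.arg(feature_axis)
  if (length(dmr_cpgs) == 0) stop("dmr_cpgs must be non-empty")
  if (!all(dmr_cpgs %in% manifest$probe_id)) {
    stop("dmr_cpgs contains ids absent from the manifest")
  }
  classes <- if (feature_axis == "cpg_feature") CPG_FEATURES else GENE_FEATURES
  feat <- stats::setNames(manifest[[feature_axis]], manifest$probe_id)
  in_dmr <- feat[dmr_cpgs]
  res <- lapply(classes, function(cl) {
    a <- sum(in_dmr == cl)
    b <- length(in_dmr) - a
    cc <- sum(feat == cl)
    dd <- length(feat) - cc
    ft <- fisher_exact_2x2(a, b, cc, dd)
    data.frame(feature = cl, a = a, b = b, c = cc, d = dd,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of the query genes by the
#' hypergeometric upper tail P(X >= k) with universe N = array-annotated
#' genes, set size K (restricted to the universe), query size n and overlap
#' k; BH adjustment across sets. Query genes outside the universe are
#' dropped with a warning. A gene counts once however many of its probes
#' fall in DMRs.
#'
#' @param query_genes character vector of query gene symbols.
#' @param collection named list of gene sets from [read_gmt()].
#' @param universe character vector of background gene symbols (genes
#'   annotated to at least one retained array probe).
#' @return data.frame with columns \code{set}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p}, \code{p_adj}, sorted as the collection.
#' @export
geneset_enrichment <- function(query_genes, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe must be non-empty")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query_genes <- intersect(query_genes, universe)
  }
  n <- length(query_genes)
  N <- length(universe)
  res <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    p <- if (K == 0 || k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(set = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  out$p_adj <- adjust_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Overlap test between two gene lists
#'
#' Builds the 2x2 membership table of two gene lists over a common universe
#' and routes it through [fisher_exact_2x2()] — the mechanics used to test,
#' e.g., a methylome gene list against externally curated lists.
#'
#' @param list_a,list_b character vectors of gene symbols, subsets of the
#'   universe.
#' @param universe background gene symbols.
#' @return list with \code{overlap}, \code{odds_ratio}, \code{p}.
#' @export
gene_list_overlap <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    stop("both lists must be subsets of the universe")
  }
  a <- length(intersect(list_a, list_b))
  b <- length(setdiff(list_a, list_b))
  cc <- length(setdiff(list_b, list_a))
  dd <- length(universe) - a - b - cc
  ft <- fisher_exact_2x2(a, b, cc, dd)
  list(overlap = a, odds_ratio = ft$odds_ratio, p = ft$p,
       degenerate = ft$degenerate)
}
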