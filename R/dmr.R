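#' Fisher's method for combining p-values
#'
#' X2 = -2 * sum(log p_i) is chi-square with 2k df under the null; the
#' combined p is the chi-square survival probability. With k = 1 the
#' combined p equals the input p exactly. Zero p-values are clamped to the
#' smallest positive representable double, with a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with \code{stat} (X2) and \code{p_comb}.
#' @export
fisher_combine <- function(p) {
  k <- length(p)
  if (k < 1) stop("need at least one p-value")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value clamped to smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  stat <- -2 * sum(log(p))
  list(stat = stat, p_comb = stats::pchisq(stat, df = 2 * k,
                                           lower.tail = FALSE))
}

#' Enumerate candidate 1-kb sliding windows
#'
#' One candidate window is anchored at each probe position p (0-based),
#' spanning the half-open interval [p, p + window_size). Because windows are
#' anchored at probes, the sliding step equals the inter-probe gaps and each
#' distinct probe neighborhood is visited exactly once. Windows with fewer
#' than \code{min_probes} member probes are dropped (regional methylation
#' changes are expected to span multiple CpGs). Per window, the member
#' probes' raw p-values are combined by Fisher's method.
#'
#' @param manifest probe manifest.
#' @param probe_results per-probe results from [diff_methylation()] (raw
#'   \code{p} and \code{delta_beta} are used).
#' @param window_size window span in bp (default 1000).
#' @param min_probes minimum member probes per window (default 2).
#' @return data.frame of candidate windows: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{n_probes}, \code{fisher_stat},
#'   \code{p_comb}, \code{mean_delta_beta}, and a list-column
#'   \code{probe_ids}.
#' @export
enumerate_windows <- function(manifest, probe_results, window_size = 1000,
                              min_probes = 2) {
  if (window_size <= 0) stop("window_size must be positive")
  idx <- match(probe_results$probe_id, manifest$probe_id)
  if (any(is.na(idx))) stop("probe_results contains ids absent from manifest")
  df <- data.frame(probe_id = probe_results$probe_id,
                   chrom = manifest$chrom[idx],
                   pos0 = manifest$pos[idx] - 1L,
                   p = probe_results$p,
                   delta_beta = probe_results$delta_beta,
                   stringsAsFactors = FALSE)
  if (any(df$p <= 0)) {
    df$p <- pmax(df$p, .Machine$double.xmin)
  }
  df <- df[order(df$chrom, df$pos0), , drop = FALSE]
  out <- lapply(split(df, df$chrom), function(ch) {
    n <- nrow(ch)
    # last member index of the window anchored at each probe (half-open)
    last <- findInterval(ch$pos0 + window_size - 0.5, ch$pos0)
    k <- last - seq_len(n) + 1L
    keep <- which(k >= min_probes)
    if (length(keep) == 0) return(NULL)
    clp <- cumsum(log(ch$p))
    cdb <- cumsum(ch$delta_beta)
    stat <- -2 * (clp[last[keep]] - c(0, clp)[keep])
    mean_db <- (cdb[last[keep]] - c(0, cdb)[keep]) / k[keep]
    data.frame(chrom = ch$chrom[keep], start = ch$pos0[keep],
               end = ch$pos0[keep] + as.integer(window_size),
               n_probes = k[keep], fisher_stat = stat,
               p_comb = stats::pchisq(stat, df = 2 * k[keep],
                                      lower.tail = FALSE),
               mean_delta_beta = mean_db,
               probe_ids = I(lapply(keep, function(i)
                 ch$probe_id[i:last[i]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      fisher_stat = numeric(0), p_comb = numeric(0),
                      mean_delta_beta = numeric(0),
                      probe_ids = I(list()))
  }
  rownames(out) <- NULL
  out
}

#' BH-significant windows
#'
#' Benjamini-Hochberg adjustment across all candidate windows; windows with
#' adjusted p below the threshold are kept.
#'
#' @param windows candidate windows from [enumerate_windows()].
#' @param fdr_threshold window-level FDR threshold.
#' @return the significant subset, with a \code{p_adj} column added.
#' @export
call_significant_windows <- function(windows, fdr_threshold = 1e-4) {
  if (nrow(windows) == 0) {
    windows$p_adj <- numeric(0)
    return(windows)
  }
  windows$p_adj <- adjust_bh(windows$p_comb)
  out <- windows[windows$p_adj < fdr_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Majority sign of the member-probe delta-betas, plus a mixed flag raised
# when the minority sign exceeds a quarter of the signed probes. The
# reported direction label collapses to "mixed" when the flag is raised.
dmr_direction <- function(delta_beta) {
  pos <- sum(delta_beta > 0)
  neg <- sum(delta_beta < 0)
  majority <- if (pos >= neg) "hyper" else "hypo"
  mixed <- pos > 0 && neg > 0 && min(pos, neg) / (pos + neg) > 0.25
  list(label = if (mixed) "mixed" else majority,
       majority = majority, mixed = mixed)
}

#' Merge significant windows into DMRs
#'
#' Overlapping or bookended significant windows on the same chromosome are
#' merged into a non-redundant set of differentially methylated regions.
#' Member probe sets are unioned; the best window -log10(p_comb) is kept;
#' the direction is \code{hyper} if every member probe's delta-beta is
#' >= 0, \code{hypo} if every one is <= 0, otherwise the majority sign, or
#' \code{mixed} when the minority sign exceeds a quarter of the signed
#' probes.
#'
#' @param windows significant windows from [call_significant_windows()].
#' @param probe_results per-probe results carrying \code{delta_beta}
#'   (used for the direction rule and the DMR mean delta-beta).
#' @return data.frame of DMRs: \code{chrom}, \code{start}, \code{end},
#'   \code{n_probes}, \code{direction} (label, collapsing to "mixed"),
#'   \code{majority_direction} (always hyper/hypo), \code{mixed} (flag),
#'   \code{mean_delta_beta}, \code{best_neglog10_p} and list-column
#'   \code{probe_ids}.
#' @export
merge_windows <- function(windows, probe_results) {
  if (nrow(windows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      direction = character(0),
                      majority_direction = character(0), mixed = logical(0),
                      mean_delta_beta = numeric(0),
                      best_neglog10_p = numeric(0), probe_ids = I(list())))
  }
  db <- stats::setNames(probe_results$delta_beta, probe_results$probe_id)
  out <- lapply(split(windows, windows$chrom), function(ch) {
    ch <- ch[order(ch$start, ch$end), , drop = FALSE]
    grp <- cumsum(c(TRUE, ch$start[-1] > cummax(ch$end)[-nrow(ch)]))
    res <- lapply(split(seq_len(nrow(ch)), grp), function(i) {
      probes <- unique(unlist(ch$probe_ids[i]))
      pdb <- db[probes]
      dir <- dmr_direction(pdb)
      data.frame(chrom = ch$chrom[i[1]], start = min(ch$start[i]),
                 end = max(ch$end[i]), n_probes = length(probes),
                 direction = dir$label,
                 majority_direction = dir$majority,
                 mixed = dir$mixed,
                 mean_delta_beta = mean(pdb),
                 best_neglog10_p = max(-log10(pmax(ch$p_comb[i],
                                                   .Machine$double.xmin))),
                 probe_ids = I(list(probes)), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genes to DMRs
#'
#' A DMR's genes are the union of its member probes' gene symbols. When a
#' DMR has no annotated gene and a DHS-to-gene map is supplied, the genes of
#' DNase I-hypersensitive intervals overlapping the DMR span are used as the
#' fallback assignment; unassigned DMRs are retained with an empty gene set.
#'
#' @param dmrs DMR data.frame from [merge_windows()].
#' @param manifest probe manifest (carries per-probe gene symbols).
#' @param dhs_map optional DHS interval map from [read_dhs_map()].
#' @return the DMRs with a list-column \code{genes} added.
#' @export
assign_genes <- function(dmrs, manifest, dhs_map = NULL) {
  gene_of <- stats::setNames(manifest$gene, manifest$probe_id)
  genes <- lapply(seq_len(nrow(dmrs)), function(i) {
    g <- unique(gene_of[dmrs$probe_ids[[i]]])
    g <- g[!is.na(g)]
    if (length(g) == 0 && !is.null(dhs_map)) {
      hit <- dhs_map$chrom == dmrs$chrom[i] &
        dhs_map$start < dmrs$end[i] & dhs_map$end > dmrs$start[i]
      g <- unique(dhs_map$gene[hit])
    }
    unname(g)
  })
  dmrs$genes <- I(genes)
  dmrs
}

#' Full DMR-calling pipeline
#'
#' Enumerate probe-anchored 1-kb windows, combine member probe p-values by
#' Fisher's method, BH-correct across windows, keep windows below the FDR
#' threshold, merge overlaps into a non-redundant DMR set and assign genes.
#'
#' @inheritParams enumerate_windows
#' @inheritParams call_significant_windows
#' @inheritParams assign_genes
#' @return list with \code{windows} (all candidates, with \code{p_adj}),
#'   \code{significant} (significant windows) and \code{dmrs} (merged,
#'   gene-annotated DMRs).
#' @export
call_dmrs <- function(manifest, probe_results, window_size = 1000,
                      min_probes = 2, fdr_threshold = 1e-4, dhs_map = NULL) {
  windows <- enumerate_windows(manifest, probe_results, window_size,
                               min_probes)
  windows$p_adj <- if (nrow(windows) > 0) adjust_bh(windows$p_comb)
    else numeric(0)
  sig <- windows[windows$p_adj < fdr_threshold, , drop = FALSE]
  rownames(sig) <- NULL
  dmrs <- merge_windows(sig, probe_results)
  dmrs <- assign_genes(dmrs, manifest, dhs_map)
  list(windows = windows, significant = sig, dmrs = dmrs)
}

#' Export DMRs to BED6
#'
#' @param dmrs DMRs from [call_dmrs()] or [merge_windows()].
#' @param path output path.
#' @export
dmrs_to_bed <- function(dmrs, path) {
  intervals <- data.frame(chrom = dmrs$chrom, start = dmrs$start,
                          end = dmrs$end,
                          name = if (nrow(dmrs) > 0)
                            sprintf("DMR%04d", seq_len(nrow(dmrs)))
                          else character(0),
                          score = dmrs$best_neglog10_p,
                          stringsAsFactors = FALSE)
  write_bed(intervals, path)
}
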