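probe_results_for <- function(manifest, p = NULL, delta_beta = NULL) {
  n <- nrow(manifest)
  data.frame(probe_id = manifest$probe_id,
             p = if (is.null(p)) rep(0.5, n) else p,
             delta_beta = if (is.null(delta_beta)) rep(0.1, n) else delta_beta,
             stringsAsFactors = FALSE)
}

test_that("Fisher's method matches the closed-form chi-square survival", {
  # single p identity
  expect_equal(fisher_combine(0.05)$p_comb, 0.05, tolerance = 1e-12)
  # worked two-p case
  fc <- fisher_combine(c(0.01, 0.02))
  expect_equal(fc$stat, -2 * (log(0.01) + log(0.02)), tolerance = 1e-12)
  expect_equal(fc$stat, 17.0344, tolerance = 1e-4)
  expect_equal(fc$p_comb, exp(-fc$stat / 2) * (1 + fc$stat / 2),
               tolerance = 1e-12)
  expect_equal(fc$p_comb, 1.90e-3, tolerance = 1e-2)
  # degenerate all-ones
  expect_equal(fisher_combine(rep(1, 4)), list(stat = 0, p_comb = 1))
  # independent survival implementation, k up to 10
  set.seed(6)
  for (k in 1:10) {
    p <- runif(k, 0.001, 1)
    fc <- fisher_combine(p)
    expect_equal(fc$p_comb, chisq_surv_even_df(fc$stat, k),
                 tolerance = 1e-12)
  }
  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("window enumeration respects the half-open 1-kb convention", {
  man <- validate_manifest_df(data.frame(
    probe_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(100L, 500L, 1500L), cpg_feature = "island",
    gene_feature = "promoter", gene = "G1", stringsAsFactors = FALSE))
  pr <- probe_results_for(man, p = c(0.01, 0.02, 0.5))
  w <- enumerate_windows(man, pr, window_size = 1000, min_probes = 2)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 99)
  expect_equal(w$end, 1099)
  expect_equal(w$probe_ids[[1]], c("a", "b"))
  expect_equal(w$fisher_stat, -2 * (log(0.01) + log(0.02)),
               tolerance = 1e-12)

  w1 <- enumerate_windows(man, pr, min_probes = 1)
  expect_equal(nrow(w1), 3)

  # probes exactly 1000 bp apart are not co-windowed
  man2 <- validate_manifest_df(transform(man, pos = c(100L, 1100L, 5000L)))
  w2 <- enumerate_windows(man2, probe_results_for(man2), min_probes = 2)
  expect_equal(nrow(w2), 0)
  man3 <- validate_manifest_df(transform(man, pos = c(100L, 1099L, 5000L)))
  w3 <- enumerate_windows(man3, probe_results_for(man3), min_probes = 2)
  expect_equal(nrow(w3), 1)
  expect_error(enumerate_windows(man, pr, window_size = 0), "positive")
})

test_that("window FDR keeps a strong window and rejects nulls", {
  set.seed(12)
  n <- 1000
  w <- data.frame(chrom = "chr1", start = seq_len(n) * 2000,
                  end = seq_len(n) * 2000 + 1000, n_probes = 2,
                  fisher_stat = 1, p_comb = runif(n),
                  mean_delta_beta = 0, stringsAsFactors = FALSE)
  w$probe_ids <- I(as.list(paste0("p", seq_len(n))))
  w$p_comb[1] <- 1e-12
  sig <- call_significant_windows(w, fdr_threshold = 1e-4)
  # BH arithmetic: 1e-12 * 1000 = 1e-9 < 1e-4; nulls survive with
  # probability ~ m * 1e-4
  expect_true(1 %in% which(w$p_comb == 1e-12))
  expect_true(any(sig$start == w$start[1]))
  expect_lte(nrow(sig), 2)
  expect_equal(call_significant_windows(w[0, ], 1e-4)$p_adj, numeric(0))
})

test_that("merging unions overlapping windows and applies the sign rule", {
  mk_win <- function(chrom, start, end, probes) {
    data.frame(chrom = chrom, start = start, end = end,
               n_probes = length(probes), fisher_stat = 10, p_comb = 1e-6,
               mean_delta_beta = 0, probe_ids = I(list(probes)),
               stringsAsFactors = FALSE)
  }
  w <- rbind(mk_win("chr1", 100, 1100, c("a", "b")),
             mk_win("chr1", 600, 1600, c("b", "c")),
             mk_win("chr2", 100, 1100, c("d", "e")))
  pr <- data.frame(probe_id = letters[1:5], p = 1e-4,
                   delta_beta = c(0.2, 0.15, -0.01, -0.3, -0.2),
                   stringsAsFactors = FALSE)
  dmrs <- merge_windows(w, pr)
  expect_equal(nrow(dmrs), 2)
  expect_equal(dmrs$start, c(100, 100))
  expect_equal(dmrs$end, c(1600, 1100))
  # chr1 member deltas (+0.2, +0.15, -0.01): minority 1/3 > 0.25 -> mixed
  expect_equal(dmrs$direction[1], "mixed")
  expect_equal(dmrs$majority_direction[1], "hyper")
  expect_true(dmrs$mixed[1])
  # chr2: all negative -> hypo
  expect_equal(dmrs$direction[2], "hypo")
  expect_false(dmrs$mixed[2])

  # disjoint windows stay separate; bookended windows merge
  w2 <- rbind(mk_win("chr1", 0, 1000, "a"), mk_win("chr1", 1000, 2000, "b"),
              mk_win("chr1", 5000, 6000, "c"))
  d2 <- merge_windows(w2, pr)
  expect_equal(nrow(d2), 2)
  expect_equal(d2$end[1], 2000)

  # minority exactly at 1/4 is not mixed: majority sign wins
  w3 <- mk_win("chr1", 0, 1000, c("a", "b", "c", "d"))
  pr3 <- data.frame(probe_id = c("a", "b", "c", "d"), p = 1e-4,
                    delta_beta = c(0.2, 0.1, 0.3, -0.05),
                    stringsAsFactors = FALSE)
  expect_equal(merge_windows(w3, pr3)$direction, "hyper")

  # idempotence: re-merging the merged set changes nothing
  as_windows <- dmrs
  as_windows$p_comb <- 10^(-dmrs$best_neglog10_p)
  d3 <- merge_windows(as_windows[, c("chrom", "start", "end", "n_probes",
                                     "p_comb", "probe_ids")], pr)
  expect_equal(d3$start, dmrs$start)
  expect_equal(d3$end, dmrs$end)
  # merged intervals pairwise disjoint per chromosome
  for (ch in unique(dmrs$chrom)) {
    d <- dmrs[dmrs$chrom == ch, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("gene assignment unions probe genes with a DHS fallback", {
  man <- tiny_manifest()
  dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 4000L),
                     end = c(1000L, 6000L), stringsAsFactors = FALSE)
  dmrs$probe_ids <- I(list(c("cgA", "cgB"), "cgE"))
  out <- assign_genes(dmrs, man)
  expect_equal(out$genes[[1]], "MBP")
  expect_equal(out$genes[[2]], character(0))  # intergenic, retained

  dhs <- data.frame(chrom = "chr2", start = 4500L, end = 5200L,
                    gene = "GENE7", stringsAsFactors = FALSE)
  out2 <- assign_genes(dmrs, man, dhs_map = dhs)
  expect_equal(out2$genes[[1]], "MBP")  # direct annotation wins
  expect_equal(out2$genes[[2]], "GENE7")
})

test_that("the DMR caller recovers a planted region end to end", {
  base <- sim_config(n_probes = 2000, n_control_child = 8, n_case_child = 8,
                     n_control_adult = 0, n_case_adult = 0, seed = 19)
  man <- simulate_manifest(base)
  sp <- propose_spikes(man, 2, min_probes = 4, delta_beta = 0.2,
                       groups = "case", seed = 19)
  cfg <- sim_config(n_probes = 2000, n_control_child = 8, n_case_child = 8,
                    n_control_adult = 0, n_case_adult = 0, seed = 19,
                    spikes = sp)
  co <- simulate_cohort(man, cfg)
  res <- diff_methylation(co$beta, co$sheet, mode = "genotype_only")
  out <- call_dmrs(man, res, fdr_threshold = 0.01)
  expect_gt(nrow(out$dmrs), 0)
  for (i in seq_len(nrow(sp))) {
    hit <- out$dmrs$chrom == sp$chrom[i] & out$dmrs$start < sp$end[i] &
      out$dmrs$end > sp$start[i]
    expect_true(any(hit))
    expect_true(all(out$dmrs$majority_direction[hit] == "hyper"))
  }
  # BED export round-trips coordinates
  path <- withr::local_tempfile(fileext = ".bed")
  dmrs_to_bed(out$dmrs, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, out$dmrs$start)
  expect_equal(bed$V3, out$dmrs$end)
})
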