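# Small deterministic fixtures built in code.

tiny_manifest <- function() {
  validate_manifest_df(data.frame(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 500L, 1500L, 200L, 5000L),
    cpg_feature = c("island", "shore", "open_sea", "shelf", "shore"),
    gene_feature = c("promoter", "promoter", "intergenic", "body",
                     "intergenic"),
    gene = c("MBP", "MBP", NA, "CNP", NA),
    stringsAsFactors = FALSE))
}

tiny_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c("ctl_c1", "ctl_c2", "ctl_a1", "ctl_a2",
                  "ald_c1", "ald_c2", "ald_a1", "ald_a2"),
    genotype = rep(c("control", "case"), each = 4),
    age_group = rep(c("child", "child", "adult", "adult"), 2),
    stringsAsFactors = FALSE))
}

tiny_beta <- function(manifest = tiny_manifest(), sheet = tiny_sheet()) {
  set.seed(11)
  b <- matrix(runif(nrow(manifest) * nrow(sheet), 0.2, 0.8),
              nrow(manifest), nrow(sheet),
              dimnames = list(manifest$probe_id, sheet$sample_id))
  b
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
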