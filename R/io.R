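#' @keywords internal
#' @useDynLib dmrkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

CPG_FEATURES <- c("island", "shore", "shelf", "open_sea")
GENE_FEATURES <- c("promoter", "body", "intergenic")

#' Read a probe manifest
#'
#' Reads per-CpG genomic annotation from a tab-separated file with columns
#' \code{probe_id}, \code{chrom}, \code{pos} (1-based coordinate of the
#' interrogated cytosine), \code{cpg_feature} (one of \code{island},
#' \code{shore}, \code{shelf}, \code{open_sea}), \code{gene_feature} (one of
#' \code{promoter}, \code{body}, \code{intergenic}) and optionally
#' \code{gene}. Probes are returned sorted by (chrom, pos).
#'
#' Coordinates are kept 1-based in the manifest (the array-annotation
#' convention); conversion to 0-based half-open happens only at interval
#' operations and BED output.
#'
#' @param path path to a TSV file with a header row.
#' @return a \code{data.frame} with the six manifest columns, one row per
#'   probe, sorted by (chrom, pos).
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_manifest_df(df)
}

validate_manifest_df <- function(df) {
  required <- c("probe_id", "chrom", "pos", "cpg_feature", "gene_feature")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos))
  if (length(bad) > 0) {
    stop("manifest 'pos' is not numeric at data line ", bad[1])
  }
  if (any(pos < 1)) {
    stop("manifest 'pos' must be a 1-based coordinate (>= 1); offending probe: ",
         df$probe_id[which(pos < 1)[1]])
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    stop("duplicated probe_id in manifest: ", dup[1])
  }
  if (!all(df$cpg_feature %in% CPG_FEATURES)) {
    bad <- setdiff(unique(df$cpg_feature), CPG_FEATURES)
    stop("unknown cpg_feature label: ", bad[1])
  }
  if (!all(df$gene_feature %in% GENE_FEATURES)) {
    bad <- setdiff(unique(df$gene_feature), GENE_FEATURES)
    stop("unknown gene_feature label: ", bad[1])
  }
  df$pos <- as.integer(pos)
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("probe_id", "chrom", "pos", "cpg_feature", "gene_feature", "gene")]
}

#' Write a probe manifest
#'
#' @param manifest a manifest data.frame as returned by [read_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{genotype} (\code{case} /
#' \code{control}) and \code{age_group} (\code{child} / \code{adult}).
#'
#' @param path path to the TSV file.
#' @return a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "genotype", "age_group")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("sample sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) stop("duplicated sample_id: ", dup[1])
  if (!all(df$genotype %in% c("case", "control"))) {
    stop("genotype must be 'case' or 'control'")
  }
  if (!all(df$age_group %in% c("child", "adult"))) {
    stop("age_group must be 'child' or 'adult'")
  }
  rownames(df) <- NULL
  df[, required]
}

#' Write a sample sheet
#' @param sheet sample sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix
#'
#' Reads a probes-by-samples table of methylation beta values (TSV, first
#' column or row names = probe ids) and reindexes it to the order of the
#' supplied manifest and sample sheet. Values must lie in [0, 1].
#'
#' @param path path to a TSV/CSV file; the delimiter is sniffed from the
#'   extension (".csv" means comma).
#' @param manifest probe manifest; matrix row keys must be a subset of its
#'   probe ids.
#' @param sheet sample sheet; matrix column keys must be a subset of its
#'   sample ids.
#' @return a numeric matrix with rownames in manifest order (restricted to
#'   rows present) and colnames in sheet order.
#' @export
read_beta_matrix <- function(path, manifest, sheet) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  mat <- as.matrix(df)
  validate_beta_matrix(mat, manifest, sheet)
}

validate_beta_matrix <- function(mat, manifest, sheet) {
  unknown <- setdiff(rownames(mat), manifest$probe_id)
  if (length(unknown) > 0) {
    stop("beta matrix contains probe id absent from manifest: ", unknown[1])
  }
  unknown_s <- setdiff(colnames(mat), sheet$sample_id)
  if (length(unknown_s) > 0) {
    stop("beta matrix contains sample id absent from sample sheet: ",
         unknown_s[1])
  }
  bad <- which(is.na(mat) | mat < 0 | mat > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value outside [0,1] at probe ", rownames(mat)[bad[1, 1]],
         ", sample ", colnames(mat)[bad[1, 2]])
  }
  probe_order <- manifest$probe_id[manifest$probe_id %in% rownames(mat)]
  sample_order <- sheet$sample_id[sheet$sample_id %in% colnames(mat)]
  mat[probe_order, sample_order, drop = FALSE]
}

#' Write a probes-by-samples matrix as TSV
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, \code{name TAB description TAB
#' gene TAB gene ...}. Duplicate genes within a line are collapsed;
#' duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of gene symbols, with a
#'   \code{"description"} attribute carrying the per-set descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  names_v <- vapply(fields, `[[`, character(1), 1)
  dup <- names_v[duplicated(names_v)]
  if (length(dup) > 0) stop("duplicated gene-set name in GMT: ", dup[1])
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  if (any(lengths(sets) == 0)) {
    stop("GMT line ", which(lengths(sets) == 0)[1], " defines an empty set")
  }
  names(sets) <- names_v
  names(desc) <- names_v
  attr(sets, "description") <- desc
  sets
}

#' Write genomic intervals as BED6
#'
#' Intervals carry 0-based half-open coordinates. The score column holds the
#' best window -log10(p), capped at 1000 per the BED convention; strand is
#' written as ".".
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}, \code{score}.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("invalid interval: start >= end")
  }
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(intervals$score, 1000)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$name,
                   format(score, trim = TRUE, digits = 6))
  writeLines(lines, path)
  invisible(path)
}

#' Read a DHS-to-gene interval map
#'
#' TSV with columns \code{chrom}, \code{start}, \code{end} (0-based
#' half-open), \code{gene} and optionally \code{score} (association score of
#' the DNase I-hypersensitive site with the gene's expression).
#'
#' @param path path to the TSV file.
#' @return a data.frame of intervals.
#' @export
read_dhs_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("DHS map is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop("invalid DHS interval: start >= end")
  if (any(is.na(df$gene) | df$gene == "")) stop("DHS interval with empty gene")
  df
}
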