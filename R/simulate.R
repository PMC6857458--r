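#' Simulation configuration
#'
#' Builds the configuration object for the synthetic 450K-like data
#' generator. The defaults reproduce the cohort structure the analyses in
#' this package assume: four cells of 8 child controls, 9 adult controls,
#' 8 child cases (cALD-like) and 9 adult cases (cAMN-like), beta baselines
#' that depend on CpG-feature class, and homoscedastic Gaussian noise on the
#' M (logit2) scale.
#'
#' Effects are injected on the M scale and reported on the beta scale.
#' \code{genotype_effect} is added to all case samples, \code{age_effect} to
#' all adult samples, and \code{interaction_effect} to childhood cases only,
#' so the genotype-by-age interaction contrast
#' (case.child - control.child) - (case.adult - control.adult) recovers
#' \code{+interaction_effect}.
#'
#' Spiked DMRs are supplied as a data.frame with columns \code{chrom},
#' \code{start}, \code{end} (0-based half-open), \code{delta_beta} (shift on
#' the beta scale, applied through the M scale) and \code{groups} (one of
#' \code{"case"}, \code{"control"}, \code{"case_child"}, \code{"case_adult"},
#' \code{"child"}, \code{"adult"}, \code{"all"}).
#'
#' @param n_probes number of probes to simulate.
#' @param n_chrom number of synthetic chromosomes.
#' @param feature_proportions named fractions over island/shore/shelf/open_sea;
#'   must sum to 1.
#' @param gene_feature_proportions named fractions over
#'   promoter/body/intergenic; must sum to 1.
#' @param n_control_child,n_control_adult,n_case_child,n_case_adult cohort
#'   cell sizes (defaults 8/9/8/9).
#' @param baseline_beta named per-feature mean beta baselines in (0, 1).
#' @param baseline_m_sd SD of the per-probe baseline around its feature mean,
#'   on the M scale.
#' @param noise_sd per-sample noise SD on the M scale.
#' @param genotype_effect,age_effect,interaction_effect global effects on the
#'   M scale (see Details).
#' @param var_inflation_df if finite, per-probe noise variances are drawn as
#'   scaled inverse chi-square with these prior df, giving the heteroscedastic
#'   structure empirical-Bayes moderation expects; \code{Inf} (default) means
#'   homoscedastic.
#' @param spikes optional spiked-DMR data.frame (see Details).
#' @param expr_base,expr_slope,expr_noise_sd parameters of the matched
#'   expression generator: log2 expression = base - slope * promoter mean
#'   beta + noise, so hypermethylation maps to downregulation when
#'   \code{expr_slope > 0}.
#' @param seed single integer master seed; every stage derives its own
#'   stream from it.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_probes = 20000,
                       n_chrom = 5,
                       feature_proportions = c(island = 0.3, shore = 0.3,
                                               shelf = 0.1, open_sea = 0.3),
                       gene_feature_proportions = c(promoter = 0.25,
                                                    body = 0.45,
                                                    intergenic = 0.30),
                       n_control_child = 8, n_control_adult = 9,
                       n_case_child = 8, n_case_adult = 9,
                       baseline_beta = c(island = 0.2, shore = 0.4,
                                         shelf = 0.6, open_sea = 0.7),
                       baseline_m_sd = 0.5,
                       noise_sd = 0.3,
                       genotype_effect = 0, age_effect = 0,
                       interaction_effect = 0,
                       var_inflation_df = Inf,
                       spikes = NULL,
                       expr_base = 8, expr_slope = 4, expr_noise_sd = 0.5,
                       seed = 1) {
  cfg <- list(n_probes = n_probes, n_chrom = n_chrom,
              feature_proportions = feature_proportions,
              gene_feature_proportions = gene_feature_proportions,
              n_control_child = n_control_child,
              n_control_adult = n_control_adult,
              n_case_child = n_case_child, n_case_adult = n_case_adult,
              baseline_beta = baseline_beta, baseline_m_sd = baseline_m_sd,
              noise_sd = noise_sd,
              genotype_effect = genotype_effect, age_effect = age_effect,
              interaction_effect = interaction_effect,
              var_inflation_df = var_inflation_df,
              spikes = spikes,
              expr_base = expr_base, expr_slope = expr_slope,
              expr_noise_sd = expr_noise_sd,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_probes < 1) stop("n_probes must be >= 1")
  if (abs(sum(cfg$feature_proportions) - 1) > 1e-8) {
    stop("feature_proportions must sum to 1")
  }
  if (abs(sum(cfg$gene_feature_proportions) - 1) > 1e-8) {
    stop("gene_feature_proportions must sum to 1")
  }
  if (any(cfg$baseline_beta <= 0 | cfg$baseline_beta >= 1)) {
    stop("baseline_beta values must lie strictly in (0, 1)")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (!setequal(names(cfg$feature_proportions), CPG_FEATURES)) {
    stop("feature_proportions must be named over ",
         paste(CPG_FEATURES, collapse = ", "))
  }
  invisible(cfg)
}

# Derive a stage-specific 31-bit seed from the master seed so each generator
# stage has its own reproducible stream.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stage))
  force(code)
}

#' Simulate a probe manifest
#'
#' Places probes on a small number of synthetic chromosomes with inter-probe
#' spacing drawn from a mixture of clustered (geometric, mean ~200 bp) and
#' isolated (exponential, mean ~5 kb) gaps, so that 1-kb neighborhoods
#' containing anywhere from 1 to ~8 probes occur. CpG- and gene-feature
#' classes are assigned i.i.d. from the configured proportions; gene symbols
#' are shared within positional blocks so that neighboring probes annotate
#' to the same gene, and intergenic probes carry no gene.
#'
#' @param config a [sim_config()] object.
#' @return a probe manifest data.frame (see [read_manifest()]).
#' @export
simulate_manifest <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "manifest", {
    n <- config$n_probes
    per_chrom <- diff(round(seq(0, n, length.out = config$n_chrom + 1)))
    chrom <- rep(sprintf("chr%02d", seq_len(config$n_chrom)), per_chrom)
    clustered <- stats::runif(n) < 0.75
    gaps <- ifelse(clustered,
                   stats::rgeom(n, 1 / 200) + 2,
                   round(stats::rexp(n, 1 / 5000)) + 1000)
    pos <- unlist(lapply(split(gaps, chrom), function(g) 1000L + cumsum(g)),
                  use.names = FALSE)
    cpg_feature <- sample(CPG_FEATURES, n, replace = TRUE,
                          prob = config$feature_proportions[CPG_FEATURES])
    gene_feature <- sample(GENE_FEATURES, n, replace = TRUE,
                           prob = config$gene_feature_proportions[GENE_FEATURES])
    # new gene block whenever the gap to the previous probe exceeds 2 kb
    block <- unlist(lapply(split(gaps, chrom),
                           function(g) cumsum(c(TRUE, g[-1] > 2000))),
                    use.names = FALSE)
    gene <- sprintf("G%s_%04d", sub("chr", "", chrom), block)
    gene[gene_feature == "intergenic"] <- NA_character_
    df <- data.frame(probe_id = sprintf("cg%07d", seq_len(n)),
                     chrom = chrom, pos = as.integer(pos),
                     cpg_feature = cpg_feature, gene_feature = gene_feature,
                     gene = gene, stringsAsFactors = FALSE)
    validate_manifest_df(df)
  })
}

build_sample_sheet <- function(config) {
  cells <- list(
    control_child = config$n_control_child,
    control_adult = config$n_control_adult,
    case_child = config$n_case_child,
    case_adult = config$n_case_adult)
  rows <- lapply(names(cells), function(cell) {
    n <- cells[[cell]]
    if (n == 0) return(NULL)
    parts <- strsplit(cell, "_")[[1]]
    data.frame(
      sample_id = sprintf("%s_%s_%02d", toupper(substr(parts[1], 1, 3)),
                          parts[2], seq_len(n)),
      genotype = parts[1], age_group = parts[2], stringsAsFactors = FALSE)
  })
  validate_sample_sheet(do.call(rbind, rows))
}

group_mask <- function(sheet, groups) {
  switch(groups,
         all = rep(TRUE, nrow(sheet)),
         case = sheet$genotype == "case",
         control = sheet$genotype == "control",
         child = sheet$age_group == "child",
         adult = sheet$age_group == "adult",
         case_child = sheet$genotype == "case" & sheet$age_group == "child",
         case_adult = sheet$genotype == "case" & sheet$age_group == "adult",
         control_child = sheet$genotype == "control" & sheet$age_group == "child",
         control_adult = sheet$genotype == "control" & sheet$age_group == "adult",
         stop("unknown spike group: ", groups))
}

#' Simulate a methylation cohort
#'
#' Draws a beta matrix for the configured cohort. Each probe gets a baseline
#' M value around its CpG-feature baseline; each sample value is
#' inverse-logit2 of baseline + genotype/age/interaction effects + spike
#' effects + Gaussian noise (all on the M scale). Spiked intervals shift the
#' member probes of the affected groups by \code{delta_beta} on the beta
#' scale (applied via the M scale). The returned truth object records the
#' spiked intervals, their member probes and direction, and the
#' noise-free per-cell mean beta of every probe.
#'
#' @param manifest a probe manifest.
#' @param config a [sim_config()] object.
#' @return list with elements \code{beta} (matrix), \code{sheet}
#'   (sample sheet) and \code{truth}.
#' @export
simulate_cohort <- function(manifest, config) {
  validate_sim_config(config)
  sheet <- build_sample_sheet(config)
  n <- nrow(manifest)
  ns <- nrow(sheet)
  with_stage_seed(config$seed, "cohort", {
    m0 <- beta_to_m(config$baseline_beta[manifest$cpg_feature]) +
      stats::rnorm(n, 0, config$baseline_m_sd)
    is_case <- sheet$genotype == "case"
    is_adult <- sheet$age_group == "adult"
    cell_shift <- config$genotype_effect * is_case +
      config$age_effect * is_adult +
      config$interaction_effect * (is_case & !is_adult)
    m <- outer(m0, cell_shift, function(a, b) a + b)

    mu0 <- m_to_beta(m0)
    spike_probes <- list()
    truth_spikes <- NULL
    if (!is.null(config$spikes) && nrow(config$spikes) > 0) {
      sp <- config$spikes
      sp$n_probes <- 0L
      sp$empty <- FALSE
      for (i in seq_len(nrow(sp))) {
        idx <- which(manifest$chrom == sp$chrom[i] &
                     manifest$pos - 1L >= sp$start[i] &
                     manifest$pos - 1L < sp$end[i])
        sp$n_probes[i] <- length(idx)
        if (length(idx) == 0) {
          warning("spike interval ", sp$chrom[i], ":", sp$start[i], "-",
                  sp$end[i], " contains no probes")
          sp$empty[i] <- TRUE
          spike_probes[[i]] <- character(0)
          next
        }
        spike_probes[[i]] <- manifest$probe_id[idx]
        dm <- beta_to_m(pmin(pmax(mu0[idx] + sp$delta_beta[i], 0), 1)) -
          beta_to_m(mu0[idx])
        cols <- which(group_mask(sheet, sp$groups[i]))
        m[idx, cols] <- m[idx, cols] + dm
      }
      sp$direction <- ifelse(sp$delta_beta >= 0, "hyper", "hypo")
      truth_spikes <- sp
    }

    probe_sd <- if (is.finite(config$var_inflation_df)) {
      config$noise_sd * sqrt(config$var_inflation_df /
                             stats::rchisq(n, config$var_inflation_df))
    } else rep(config$noise_sd, n)

    group_means <- m_to_beta(vapply(
      c("control_child", "control_adult", "case_child", "case_adult"),
      function(cell) {
        cols <- which(group_mask(sheet, cell))
        if (length(cols) == 0) rep(NA_real_, n) else m[, cols[1]]
      }, numeric(n)))
    rownames(group_means) <- manifest$probe_id

    noise <- matrix(stats::rnorm(n * ns, 0, probe_sd), n, ns)
    beta <- m_to_beta(m + noise)
    dimnames(beta) <- list(manifest$probe_id, sheet$sample_id)

    truth <- list(spikes = truth_spikes, spike_probes = spike_probes,
                  group_means = group_means, probe_sd = probe_sd)
    list(beta = beta, sheet = sheet, truth = truth)
  })
}

#' Simulate matched expression values
#'
#' For each requested gene, the per-sample log2 expression is
#' \code{expr_base - expr_slope * (mean promoter beta of that gene in that
#' sample) + noise}, so that with positive slope promoter hypermethylation
#' translates into downregulated expression, the coordination the
#' integration analysis looks for.
#'
#' @param beta beta matrix (probes x samples).
#' @param manifest probe manifest; each gene must have at least one promoter
#'   probe.
#' @param genes character vector of gene symbols.
#' @param config a [sim_config()] object.
#' @return samples x genes matrix of log2 expression.
#' @export
simulate_expression <- function(beta, manifest, genes, config) {
  with_stage_seed(config$seed, "expression", {
    expr <- matrix(NA_real_, ncol(beta), length(genes),
                   dimnames = list(colnames(beta), genes))
    for (g in genes) {
      probes <- manifest$probe_id[!is.na(manifest$gene) & manifest$gene == g &
                                  manifest$gene_feature == "promoter"]
      probes <- intersect(probes, rownames(beta))
      if (length(probes) == 0) {
        stop("gene ", g, " has no mapped promoter probes")
      }
      prom <- colMeans(beta[probes, , drop = FALSE])
      expr[, g] <- config$expr_base - config$expr_slope * prom +
        stats::rnorm(ncol(beta), 0, config$expr_noise_sd)
    }
    expr
  })
}

#' Simulate pyrosequencing-style validation values
#'
#' Pyro value = clamp(100 * beta + Normal(0, noise_sd_pct), 0, 100),
#' emulating a bisulfite-pyrosequencing validation panel measured in percent
#' methylation.
#'
#' @param beta beta matrix.
#' @param probes probe ids to include (must be rows of \code{beta}).
#' @param noise_sd_pct measurement noise SD in percentage points.
#' @param config a [sim_config()] object (for the seed).
#' @return probes x samples matrix on the 0-100 scale.
#' @export
simulate_pyro <- function(beta, probes, noise_sd_pct = 5, config = sim_config()) {
  if (length(probes) == 0) stop("probe subset must be non-empty")
  if (!all(probes %in% rownames(beta))) {
    stop("probe subset contains ids absent from the beta matrix")
  }
  with_stage_seed(config$seed, "pyro", {
    x <- 100 * beta[probes, , drop = FALSE]
    pmin(pmax(x + stats::rnorm(length(x), 0, noise_sd_pct), 0), 100)
  })
}

#' Propose spike-in intervals over dense probe neighborhoods
#'
#' Scans the manifest for 1-kb neighborhoods containing at least
#' \code{min_probes} probes and returns \code{n_spikes} non-overlapping
#' intervals formatted for the \code{spikes} slot of [sim_config()].
#' Intervals are chosen deterministically given the seed, spread across the
#' genome.
#'
#' @param manifest probe manifest.
#' @param n_spikes number of intervals to propose.
#' @param min_probes minimum probes within the 1-kb span.
#' @param delta_beta beta-scale shift (recycled).
#' @param groups affected groups (recycled; see [sim_config()]).
#' @param span interval width in bp (default 1000).
#' @param seed integer seed for the deterministic choice.
#' @return spikes data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{delta_beta}, \code{groups}.
#' @export
propose_spikes <- function(manifest, n_spikes, min_probes = 4,
                           delta_beta = 0.2, groups = "case",
                           span = 1000, seed = 1) {
  pos0 <- manifest$pos - 1L
  cand <- do.call(rbind, lapply(split(seq_len(nrow(manifest)),
                                      manifest$chrom), function(idx) {
    p <- pos0[idx]
    last <- findInterval(p + span - 0.5, p)
    k <- last - seq_along(p) + 1L
    ok <- which(k >= min_probes)
    if (length(ok) == 0) return(NULL)
    data.frame(chrom = manifest$chrom[idx[1]], start = p[ok],
               end = p[ok] + as.integer(span), n = k[ok],
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0) {
    stop("no neighborhood with ", min_probes, " probes within ", span, " bp")
  }
  with_stage_seed(seed, "spikes", {
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    chosen <- list()
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) == n_spikes) break
      overlaps <- any(vapply(chosen, function(cc) {
        cc$chrom == cand$chrom[i] && cc$start < cand$end[i] + span &&
          cc$end > cand$start[i] - span
      }, logical(1)))
      if (!overlaps) chosen[[length(chosen) + 1]] <- cand[i, ]
    }
    if (length(chosen) < n_spikes) {
      stop("could not place ", n_spikes, " non-overlapping spike intervals")
    }
    out <- do.call(rbind, chosen)[, c("chrom", "start", "end")]
    out$delta_beta <- rep_len(delta_beta, n_spikes)
    out$groups <- rep_len(groups, n_spikes)
    rownames(out) <- NULL
    out
  })
}
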