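---
title: "Methods and design notes for dmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dmrkit` implements a differential DNA-methylation pipeline for 450K-style
beta-value matrices in small case/control cohorts stratified into two age
groups, of the kind used to compare childhood and adult cerebral phenotypes
of X-linked adrenoleukodystrophy against age-matched controls. This
vignette is the package's own account of the statistical machinery, the
choices that were genuinely open, and what the test suite does and does not
establish.

## The measurement scales

A CpG's beta value is the methylated fraction of signal, bounded in
[0, 1]; it is the natural reporting scale but has strongly
mean-dependent variance near the boundaries. All testing is therefore done
on the M scale, M = log2(beta / (1 - beta)), which is approximately
variance-stabilized, and effect sizes are translated back to beta for
reporting. `beta_to_m()` clamps beta to [eps, 1 - eps] with eps = 1e-6
before the transform: small enough that no interior value moves by more
than ~1e-6 on the beta scale, large enough that M stays finite
(|M| <= ~19.9). The transforms are mutually inverse to < 1e-12 away from
the clamp bounds.

## Per-probe models and empirical-Bayes moderation

Each probe is fit by ordinary least squares on M values under one of two
designs:

* `genotype_only` — intercept plus a case indicator, testing the pooled
  case-vs-control difference;
* `genotype_by_age` — group-means coding over the four cohort cells with
  the single contrast (case.child - control.child) - (case.adult -
  control.adult). Any additive genotype effect shared by both age groups
  and any additive age effect shared by cases and controls cancel in this
  contrast, so it isolates the phenotype-specific (interaction) signal.

With 16-34 samples, per-probe variance estimates on 12-30 residual df are
noisy, so variances are moderated: probe variances are modelled as draws
from a scaled inverse chi-square prior with parameters (d0, s0^2)
estimated by the method of moments on log s^2 — the mean and variance of
log s^2 are matched to the scaled log-F distribution the prior implies,
which requires inverting the trigamma function (done by Newton's method).
The posterior variance (d0 s0^2 + d s^2)/(d0 + d) feeds a t statistic on
d + d0 df. Degenerate inputs are handled explicitly: exactly equal
variances give d0 = Inf with s0^2 equal to the common value; a moment
estimate with non-positive excess variance also gives complete shrinkage.
d0 = 0 reproduces the ordinary t exactly, which the tests verify to
1e-10, and the whole moderated layer is cross-checked against an
independent moderated-fit implementation where one is installed.

The reported `delta_beta` is the contrast applied to per-cell mean beta
values, not the back-transformed M effect: the M effect is the tested
quantity, the beta contrast the interpretable one, and the two are kept
side by side rather than conflated.

## DMR calling by 1-kb Fisher windows

Regulatory methylation changes usually span several neighboring CpGs, so
single-probe significance is aggregated over 1-kb windows:

* **Anchoring.** One candidate window starts at each probe position
  (0-based), spanning the half-open interval [p, p + 1000). Anchoring at
  probes rather than tiling the genome or sliding base-by-base visits
  every distinct probe neighborhood exactly once — the effective step is
  the inter-probe gap — and makes the candidate family finite and
  data-driven. Windows with fewer than `min_probes = 2` members are
  dropped; a single CpG cannot form a region (configurable to 1).
* **Aggregation.** Member probes' raw p-values (not BH-adjusted ones;
  adjusting twice would double-correct) are combined by Fisher's method,
  X^2 = -2 sum(ln p_i) ~ chi-square(2k). Exact zeros are clamped to the
  smallest positive double with a warning.
* **FDR family.** BH is applied across candidate windows, and windows
  with adjusted p below the threshold are kept. The window family — not
  probes, not merged regions — is the family over which the procedure
  controls FDR, and the empirical-FDR checks in the test suite measure
  false discoveries at that same level. Overlapping windows share probes
  and are positively dependent; BH is used regardless, a knowingly
  anti-conservative convention for this analysis style, which is why the
  calibration tests allow up to twice the nominal rate.
* **Merging and direction.** Overlapping or bookended significant windows
  merge; probe sets are unioned; each region keeps the best window
  -log10(p). Direction is the majority sign of member-probe delta-beta,
  recorded in `majority_direction`; when the minority sign exceeds a
  quarter of the signed probes the region is additionally flagged `mixed`
  and its `direction` label collapses to "mixed". Both fields are kept
  because significant windows legitimately absorb flanking null probes
  whose delta-beta signs are random — a region dominated by hypermethylated
  probes with one small negative neighbor is still, for recovery purposes,
  a hypermethylated region.
* **Genes.** A region's genes are the union of member-probe gene symbols;
  regions with no annotated gene fall back to the genes of overlapping
  DNase-I-hypersensitive intervals when a DHS-to-gene map is supplied,
  and are retained unannotated otherwise.

## Enrichment

Feature-distribution tests build one 2x2 Fisher's exact test per class
(island/shore/shelf/open sea, or promoter/body/intergenic), comparing the
DMR CpGs against *all* probes on the filtered array — the background
column includes the DMR CpGs themselves, so a query equal to the whole
array gives odds ratio 1 exactly. The reported odds ratio is the sample
odds ratio ad/bc; the p-value is the two-sided exact conditional p (sum
of table probabilities no larger than the observed one). Gene-set
enrichment is the hypergeometric upper tail with the universe restricted
to genes annotated to at least one retained probe, set sizes restricted to
that universe, and BH across sets; a gene counts once no matter how many
of its probes fall in DMRs.

## The age-corrected extremes contrast

To compare disease severity between the childhood and adult phenotypes,
each CpG's case mean beta has its age-matched control mean subtracted —
childhood cases minus child controls, adult cases minus adult controls.
This removes any additive age effect exactly (verified as an invariance
test). CpGs whose corrected value exceeds +0.1 (or falls below -0.1) are
counted per phenotype; 0.1 on the beta scale is the conventional
reporting threshold for a biologically meaningful methylation difference.
Two tests are emitted, clearly labelled, because they answer different
questions: a two-tailed paired t-test across the selected CpGs compares
the corrected values themselves, and an exact binomial sign test with
p0 = 0.5 compares the exceedance counts. The selection rule for the
paired test takes a CpG extreme in *either* phenotype (OR); an AND rule is
available by flag. OR is the default because it keeps the per-phenotype
counts asymmetric and comparable — under AND the two count fields would be
equal by construction.

## Biomarker models

The LASSO logistic model maximizes (1/n) sum loglik - lambda sum|beta_j|
with an unpenalized intercept, by cyclic coordinate descent on the IRLS
quadratic approximation (compiled; probabilities clamped to
[1e-5, 1 - 1e-5]); features are standardized internally to zero mean and
unit population SD. Convergence is declared when the largest coefficient
change falls below 1e-7, at which point the Karush-Kuhn-Tucker conditions
hold: the mean score of every zero coefficient is bounded by lambda, every
active one attains it with matching sign. The solver starts from the
intercept-only solution, so any lambda at or above the closed-form
lambda_max = max_j |mean(x_j (y - ybar))| returns exactly zero
coefficients. Solutions are cross-checked in the tests against a generic
box-constrained quasi-Newton solver of the same objective (via the
beta = a - b split) and against an independent penalized-regression
implementation.

The penalty is chosen by leave-one-out cross-validated binomial deviance
over 100 log-spaced values from lambda_max down to lambda_max/100;
leave-one-out has no fold randomness, so selection is deterministic. The
minimum-deviance rule is the default; the 1-SE rule (largest penalty
within one standard error of the minimum) is available and is the rule
under which near-complete shrinkage on pure-noise panels is a reliable
property — the minimum rule chases spurious CV minima on noise panels of
this size, a behavior it shares with the reference implementation it was
checked against.

`loocv_scores()` refits the model n times, each time scoring the single
held-out sample; by default the penalty is re-selected inside each
training split (honest nested LOO), with a faster fixed-penalty mode for
permutation work. ROC summaries use the Mann-Whitney AUC (ties count
half), DeLong structural-component standard errors, a normal 95% CI
truncated to [0, 1], and the Youden-optimal threshold for
sensitivity/specificity. The DeLong test compares two correlated ROC
curves on the same samples.

**A pooled-LOOCV caveat.** Held-out LOOCV scores pooled into one ROC are
not label-independent under the null: each fold's model is trained on a
set whose class balance shifts opposite to the held-out label, so at
strong shrinkage the score degenerates to the training prevalence — an
*anti*-predictor — and the pooled null AUC piles up near 0 rather than
0.5. Per-fold centering mitigates but does not remove the effect. For
this reason the permutation check of an AUC in this package permutes the
labels against the *computed* score vector (the standard AUC permutation
test, whose null is the Mann-Whitney distribution); re-running the whole
LOOCV pipeline per permutation is statistically valid only with this bias
in mind, and its null should not be assumed to concentrate around 0.5.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the pipeline assumes: cohort cells of 8 child controls, 9
adult controls, 8 childhood cases and 9 adult cases; per-feature beta
baselines (islands 0.2, shores 0.4, shelves 0.6, open sea 0.7 — islands
mostly unmethylated, open sea mostly methylated); per-probe baseline
spread of 0.5 and noise of 0.3 on the M scale; feature proportions
island 0.30 / shore 0.30 / shelf 0.10 / open sea 0.30. Probe spacing is a
mixture of clustered gaps (geometric, mean ~200 bp, 75% of probes) and
isolated gaps (exponential, mean ~5 kb), so 1-kb windows contain one to
about eight probes and the minimum-probes rule is genuinely exercised.
Effects enter on the M scale: a genotype effect for all cases, an age
effect for all adults, and an interaction effect applied to childhood
cases only, so the interaction contrast recovers it with a positive sign.
Spiked DMRs shift member probes of the affected groups by a target
delta-beta (applied through the M scale, clamped near the boundaries);
spike effect sizes of 0.1-0.3 on the beta scale reflect the 0.1 reporting
threshold for meaningful differences. Matched expression is generated as
base - slope x (promoter mean beta) + noise, so hypermethylation maps to
downregulation; pyrosequencing-like values are 100 x beta plus Gaussian
percent-scale noise, clamped to [0, 100]. A single master seed drives
every stage through derived per-stage streams, so outputs are
bit-reproducible.

What the generator does *not* emulate: array chemistry and batch
structure, spatially varying probe affinity, cell-type composition
differences, correlated (co-methylated) noise beyond the planted regions,
5hmC/5mC mixing, and sex chromosomes. Passing tests therefore establish
the statistical machinery under idealized homoscedastic-to-moderately
heteroscedastic Gaussian noise on M — not robustness to the full failure
modes of real arrays.

## Numerical and procedural choices

* Detection filtering drops a probe when its detection p exceeds 0.01 in
  *any* sample — the strictest reading — with a sample-fraction relaxation
  available; detection removal is applied before the blacklist so the two
  removal sets are disjoint.
* Manifest coordinates are 1-based (array convention); all interval work
  and BED output use 0-based half-open coordinates, converted once at the
  boundary. Two probes exactly 1000 bp apart do not share a 1-kb window.
  Strand is ignored throughout and written as "." in BED.
* The MDS diagnostic is classical (Torgerson) metric scaling on Euclidean
  distances between samples over a chosen probe subset, deterministic up
  to axis sign.
* BH ties are resolved by stable sort on input order; the step-up
  adjustment is delegated to the standard library routine and verified
  against a hand-written oracle.
* Test and acceptance problem sizes were chosen to make every
  calibration readable at interactive timescales: 20,000-probe genomes
  for null calibration and the end-to-end run, 4,000 for spike recovery
  (20 seeds each), 50,000 probes for variance-prior recovery, and
  23-sample, 22-feature panels for the biomarker layer, mirroring a
  typical pyrosequencing validation panel.

## Known limitations

* BH over overlapping windows ignores positive dependence
  (anti-conservative); merged-region-level FDR is mechanically higher
  than window-level FDR because true windows merge many-to-one.
* The pooled-LOOCV ROC bias described above.
* The 450K signal sums 5mC and 5hmC; the pipeline inherits that
  ambiguity.
* No between-array normalization, batch correction or cell-type
  deconvolution: the pipeline starts from already-normalized beta values
  and a randomized design is assumed.
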