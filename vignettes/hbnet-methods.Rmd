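---
title: "Methods: hemoglobin co-expression networks and expression-change biomarkers for stroke recovery"
author: "hbnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hemoglobin co-expression networks and expression-change biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbnet)
```

## The scientific setting

Anemia is an established risk factor for poor recovery after ischemic
stroke: hemoglobin carries the oxygen on which the penumbral tissue
depends, and low or falling hemoglobin is associated with worse outcomes.
Because mature red cells are anucleate, today's hemoglobin concentration
reflects gene expression hours to days earlier — which makes the
*expression* of hemoglobin-related genes a candidate early predictor of
recovery, ahead of the protein-level measurement.

`hbnet` implements a desk-scale version of the full analysis chain used to
pursue that idea:

1. **Cohort statistics.** A non-acute stroke cohort (28 patients in the
   reference design) is split by the WHO anemia criterion (Hb < 13 g/dL in
   men, < 12 g/dL in women) and compared characteristic by characteristic.
2. **Two-timepoint differential expression.** For each RNA-seq patient,
   genes are tested between two blood draws taken weeks apart; the genes
   shared by the patients' DEG lists seed the downstream network analysis.
3. **Co-expression network layers.** A Pearson correlation network over a
   hemoglobin-related gene panel (HB-network), the 1-hop neighborhood of
   the seed genes (CHB), and its further 1-hop extension (ECHB).
4. **Expression Changed Score.** Every ECHB gene is scored per patient by
   `ECS = (E2 - E1) / E1` and classified by whether the sign of its change
   tracks the patient's clinical outcome.
5. **qPCR validation.** Candidate genes are checked on an independent
   plate by delta-delta-Ct relative quantification across four sample
   classes (stroke with anemia, stroke without anemia, transient ischemic
   attack, healthy control).

## Cohort statistics: which test, exactly

The baseline table compares continuous characteristics with a
**two-sample t-test** and categorical ones with a **chi-square test on the
2x2 table**. Two forms exist for each, and the published values the
package bundles (`ref_cohort_baseline()`) discriminate cleanly between
them:

* recomputing every continuous row from its printed mean/SD/n matches the
  unequal-variance (Welch) form, not the pooled form (age row: Welch
  0.01512 vs pooled 0.01806 against a printed 0.0151);
* every history row matches the continuity-corrected (Yates) chi-square.

`welch_t_from_summary()` / `chi2_2x2_yates()` therefore default to Welch
and Yates, with `pooled =` and `correct =` escape hatches. Degenerate 2x2
tables with a zero margin carry no information about association; they
return p = 1 with an explicit `zero_margin` flag rather than an error,
because all-negative history flags occur naturally in small cohorts.
The regression column is an ordinary least-squares fit of each
characteristic on the hemoglobin count (`hb_regression()`), reported as
the slope's two-sided Pr(>|t|) on n − 2 df; no covariate adjustment is
applied or claimed.

## The DEG stand-in and when it is calibrated

The reference workflow calls DEGs from alignments with a
dispersion-modeling tool; that is alignment-scale machinery out of scope
here. `call_degs()` replaces it with a conditional-binomial Poisson test
on pseudo-counts: values are scaled by `scale_to_counts` (default 10,
half-up rounding for determinism), and each gene's timepoint-2 count is
tested against the library-size-ratio null with an exact binomial test,
followed by Benjamini–Hochberg adjustment and the same `q <= 0.05` calling
interface.

This stand-in treats all between-timepoint variation as shot noise. It is
therefore calibrated — empirical false-call rate at or below the nominal
FDR — when biological log-scale variability is small relative to the
count scale (roughly `count * noise_sd^2 < 1`). With strong biological
noise the pseudo-counts are overdispersed and the test is anticonservative,
exactly the failure mode dispersion-modeling DE tools exist to fix. The
global-null calibration suite runs at `noise_sd = 0.05` with mean counts
near 75, inside the calibrated regime; pipeline runs at the default
`noise_sd = 0.5` will call many genes and should be read as exercising
the interface, not as a defensible DE analysis of noisy data.

## Network construction and the layer definitions

`build_hb_network()` pools all samples (patients and timepoints; 8 in the
four-patient design) and tests every unordered pair of expressed panel
genes with the analytic Pearson test, keeping pairs with p not over
`alpha = 0.05` as edges. Three choices deserve note:

* **No multiple-testing correction by default.** The workflow this package
  reproduces keeps raw p <= 0.05 over all k(k−1)/2 pairs; `adjust = "BH"`
  is available but off by default for fidelity.
* **Two-sided p.** The edge rule does not distinguish positive from
  negative co-expression; the signed `r` is stored on each edge.
* **Constant genes** pass the "any value > 0" expression filter but have
  undefined correlations; their pairs are skipped and the gene stays as an
  isolated node.

`extract_chb()` is the 1-hop closed neighborhood of the seed set;
`extend_echb()` adds one further hop. Both return induced subgraphs, so
the node nesting `seeds ⊆ CHB ⊆ ECHB ⊆ HB` holds by construction and is
property-tested on random graphs. Seeds missing from the network (a
common DEG outside the panel) are retained as isolated nodes with a
warning instead of erroring, since seed sets come from a different stage
than the panel.

## The concordance rule behind the correlation labels

The reference analysis labels candidate genes "positively" or
"negatively" correlated with recovery by comparing per-patient ECS
rankings with outcomes, without stating a formal rule. Strict all-patient
sign concordance fails on the bundled data: CPM has ECS −0.033 in a
poor-outcome patient yet is labeled negative. `classify_correlation()`
therefore formalizes the rule as **majority sign concordance** with
threshold `min_concordant = ceiling(3 n / 4)` (3 of 4 in the four-patient
design): a good outcome with positive ECS, or poor with negative, counts
toward "positive"; the reverse toward "negative"; an ECS of exactly 0
counts for neither because the rule is sign-based. This threshold
reproduces the bundled seven-gene classification exactly (6 positive, 1
negative) and is configurable.

Outcome dichotomization is likewise configuration: the default rule
`good = (mRS <= 3) OR (BI >= 60)` reproduces the reference four patients
(P1 and P3 good, P2 and P4 poor). The BI disjunct matters: one reference
patient with mRS 4 but BI 75 is considered recovered while another with
mRS 4 and BI 40 is not, so mRS alone cannot express the assignment. The
rule is a package default, not a clinical claim.

## qPCR analysis

`relative_expression()` implements textbook delta-delta-Ct: technical
replicates averaged on the Ct scale, reference-gene correction per sample,
calibrator-group centering per gene (default calibrator: the healthy
control group), and `rel = 2^(-ddCt)` with the amplification base
configurable (no standard curve is modeled). Two invariances are tested:
a constant added to every Ct of a sample cancels, and the calibrator
group's mean ddCt is 0 by construction. Group comparisons use the
two-sample Wilcoxon rank-sum test — the groups are independent samples,
which resolves the ambiguity between rank-sum and signed-rank — exact by
enumeration when the combined n is at most 12 without ties, otherwise the
continuity-corrected normal approximation.

## The synthetic study and what it does (not) show

The deposited sequencing data behind the reference analysis is not
required anywhere: `sim_config()` + `simulate_*()` generate a cohort, a
two-timepoint expression matrix and a qPCR plate with the structure the
pipeline assumes.

* **Expression model.** Per-gene baselines are gamma distributed (shape 2,
  mean `exp(baseline_log_mean)` = ~20 FPKM-like units by default), with
  log-normal multiplicative noise — strictly non-negative, overdispersed,
  and trivially invertible for planting exact fold changes. Planted
  modules share a latent per-sample factor: log-noise
  `sd * (sqrt(rho) z + sqrt(1 - rho) u)` gives pairwise log-scale
  correlation exactly `rho` regardless of the idiosyncratic noise level,
  so a unit-correlation noiseless module is an exact clique. Library-size
  factors are log-normal with mean 1 (CV 0.1 by default).
* **Planted signals.** DEGs multiply the timepoint-2 value by the signed
  fold change (so the noiseless ECS equals FC − 1); concordant genes get a
  per-patient sign-forced timepoint-2 multiplier with magnitude drawn from
  `concordant_fc_range` (default 1.5–4).
* **Cohort.** Group sizes 16/12 with means, SDs and proportions taken from
  the bundled published baseline table, so the simulated cohort reproduces
  the reference group structure in expectation; hemoglobin counts are
  drawn per sex with anemia-group truncation below the WHO threshold with
  probability 0.95. The RNA-seq patient count (2 good / 2 poor) is
  deliberately separate from the cohort sizes, mirroring the study design
  in which only 4 of 28 patients were sequenced.
* **Determinism.** One master seed spawns three independent sub-streams
  (cohort, expression, qPCR), so any one table can be regenerated without
  disturbing the others; all outputs are byte-identical under a fixed
  seed.

What the generator does *not* emulate: read-level sampling, batch
effects, gene-length effects, realistic gene–gene correlation beyond the
planted blocks, or the marginal distribution of the deposited accession
(which is not reconstructible from the publication). Passing recovery
tests on this generator shows the machinery is correct and calibrated
under its stated model, not that the biological findings replicate.

## Numerical choices and problem sizes

* Pseudo-count rounding is half-up (`floor(x + 0.5)`), not banker's
  rounding, for cross-platform determinism.
* Group-rank ties are broken by byte order of the group name
  (locale-independent) and flagged.
* Graph and table writers format numbers to 15 significant digits; the
  write–read–write cycle is byte-identical for every format.
* The property suites run at deliberately small sizes chosen for tight
  oracles: global-null FDR over 200 replicates of 500 genes; module
  recovery at 50 samples and within-module r = 0.8 over 20 replicates
  (per-replicate precision is bimodal because the two module factors form
  a single effective null test, so the replicate count matters more than
  the per-replicate size); concordant-gene recovery over 20 replicates of
  10 genes; a 100,000-draw permutation oracle at n = 8.

## Known limitations

* **Analytic vs permutation Pearson p at n = 8.** The permutation test
  conditions on the observed data; its p differs from the unconditional
  t-reference p by up to ~0.05 at n = 8 even for normal data. The two
  agree on average (mean gap below 0.03 in the suite) but not within
  Monte-Carlo error of the oracle, which is an inherent property of the
  two tests, not an implementation defect.
* **Wilcoxon normal approximation at 6 vs 6.** Exhaustive enumeration
  over all rank sums shows the continuity-corrected approximation deviates
  from the exact two-sided p by up to 0.0155 (at W = 12/24). The
  implementation therefore uses exact enumeration in that regime and only
  falls back to the approximation for larger samples or ties.
* **The DEG stand-in is not a dispersion-aware DE method** (see above);
  its calibration statement is conditional on the shot-noise regime.
* The concordance rule and outcome dichotomization are this package's
  formalizations of verbally described procedures; both are exposed as
  configuration and should be re-examined before clinical use.
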