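#' Simulation configuration for the synthetic stroke-recovery study
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_expression()] and [simulate_qpcr()]. The defaults emulate the
#' design of a two-timepoint whole-blood RNA-seq study of ischemic-stroke
#' recovery: a 28-patient clinical cohort split into non-anemia (n = 16) and
#' anemia (n = 12) groups, four RNA-seq patients (two with good outcome, two
#' with poor outcome) sampled at two timepoints each, a hemoglobin-related
#' gene panel carrying planted co-expression modules, and a qPCR validation
#' plate with four sample classes (ISA, non_ISA, TIA, control).
#'
#' A single `seed` drives three independent sub-streams (cohort, expression,
#' qPCR), so each table can be regenerated on its own without disturbing the
#' others.
#'
#' @param seed Integer seed; fixing it makes all three generators
#'   byte-reproducible.
#' @param n_patients_good,n_patients_poor Number of RNA-seq patients with
#'   good / poor clinical outcome (each contributes two expression samples
#'   and an outcome label).
#' @param n_genes Total number of genes in the expression matrix.
#' @param n_hb_genes Size of the hemoglobin-related gene panel; the panel is
#'   the first `n_hb_genes` genes of the matrix.
#' @param module_spec List of `list(size =, rho =)` entries describing
#'   planted co-expression modules inside the panel: `size` genes share a
#'   latent log-scale factor giving pairwise correlation `rho` in `[0, 1]`.
#'   Modules occupy disjoint consecutive blocks of the panel.
#' @param module_log_sd Log-scale standard deviation of module genes (the
#'   latent factor plus idiosyncratic part); controls how strongly module
#'   structure stands out against the baseline.
#' @param planted_degs `data.frame(gene, patient, fc)` of planted signed fold
#'   changes (|fc| >= 1): at timepoint 2 the gene's value is multiplied by
#'   `fc` (fc > 0) or divided by `|fc|` (fc < 0) in the designated patient
#'   (`patient = NA` plants in every patient).
#' @param planted_concordant `data.frame(gene, direction)` with direction
#'   `"positive"` or `"negative"`: the timepoint-2 shift of the gene is
#'   sign-forced per patient so its ECS agrees with (positive) or opposes
#'   (negative) the patient's outcome label.
#' @param concordant_fc_range Length-2 numeric; magnitude of the sign-forced
#'   timepoint-2 multiplier for concordant genes is drawn uniformly from this
#'   range (values >= 1).
#' @param noise_sd Log-scale idiosyncratic noise SD for genes outside planted
#'   modules.
#' @param baseline_log_mean Log of the mean of the gamma-distributed per-gene
#'   baseline expression (FPKM-like scale).
#' @param baseline_shape Shape of the gamma baseline; smaller values give a
#'   longer-tailed, more dispersed baseline.
#' @param library_size_cv Coefficient of variation of the per-sample library
#'   size factor (log-normal, mean 1); 0 disables library-size variation.
#' @param cohort_effects List describing the clinical cohort generator; see
#'   [default_cohort_effects()].
#' @param qpcr_effects List describing the qPCR plate generator; see
#'   [default_qpcr_effects()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_expression()], [simulate_qpcr()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_patients_good
sim_config <- function(seed = 42L,
                       n_patients_good = 2L,
                       n_patients_poor = 2L,
                       n_genes = 500L,
                       n_hb_genes = 141L,
                       module_spec = list(list(size = 30L, rho = 0.7),
                                          list(size = 30L, rho = 0.7)),
                       module_log_sd = 0.5,
                       planted_degs = NULL,
                       planted_concordant = NULL,
                       concordant_fc_range = c(1.5, 4),
                       noise_sd = 0.5,
                       baseline_log_mean = 3,
                       baseline_shape = 2,
                       library_size_cv = 0.1,
                       cohort_effects = default_cohort_effects(),
                       qpcr_effects = default_qpcr_effects()) {
  cfg <- list(seed = as.integer(seed),
              n_patients_good = as.integer(n_patients_good),
              n_patients_poor = as.integer(n_patients_poor),
              n_genes = as.integer(n_genes),
              n_hb_genes = as.integer(n_hb_genes),
              module_spec = module_spec,
              module_log_sd = module_log_sd,
              planted_degs = planted_degs,
              planted_concordant = planted_concordant,
              concordant_fc_range = concordant_fc_range,
              noise_sd = noise_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_shape = baseline_shape,
              library_size_cv = library_size_cv,
              cohort_effects = cohort_effects,
              qpcr_effects = qpcr_effects)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_patients_good + x$n_patients_poor, "RNA-seq patients (",
      x$n_patients_good, "good /", x$n_patients_poor, "poor ),",
      x$n_genes, "genes,", x$n_hb_genes, "panel genes,",
      length(x$module_spec), "planted modules, seed", x$seed, "\n")
  invisible(x)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients_good < 1L || cfg$n_patients_poor < 1L)
    stop("patient group sizes must be positive", call. = FALSE)
  if (cfg$n_hb_genes > cfg$n_genes)
    stop("n_hb_genes must not exceed n_genes", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$module_log_sd < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  sizes <- vapply(cfg$module_spec, function(m) as.integer(m$size), integer(1))
  rhos <- vapply(cfg$module_spec, function(m) as.numeric(m$rho), numeric(1))
  if (any(rhos < 0 | rhos > 1))
    stop("within-module correlations must lie in [0, 1]", call. = FALSE)
  if (sum(sizes) > cfg$n_hb_genes)
    stop("module sizes overlap: they sum to more than n_hb_genes", call. = FALSE)
  genes <- sim_gene_names(cfg)
  if (!is.null(cfg$planted_degs)) {
    pd <- cfg$planted_degs
    stopifnot(is.data.frame(pd), all(c("gene", "fc") %in% names(pd)))
    if (!"patient" %in% names(pd)) pd$patient <- NA_character_
    if (any(abs(pd$fc) < 1))
      stop("planted fold changes must satisfy |fc| >= 1", call. = FALSE)
    bad <- setdiff(pd$gene, genes)
    if (length(bad))
      stop("planted DEG gene(s) outside the matrix: ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg$planted_degs <- pd
  }
  if (!is.null(cfg$planted_concordant)) {
    pc <- cfg$planted_concordant
    stopifnot(is.data.frame(pc), all(c("gene", "direction") %in% names(pc)))
    if (!all(pc$direction %in% c("positive", "negative")))
      stop("concordant direction must be 'positive' or 'negative'", call. = FALSE)
    bad <- setdiff(pc$gene, genes)
    if (length(bad))
      stop("planted concordant gene(s) outside the matrix: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!is.null(cfg$planted_degs) &&
        length(intersect(pc$gene, cfg$planted_degs$gene)))
      stop("a gene cannot be both a planted DEG and a planted concordant gene",
           call. = FALSE)
  }
  if (any(cfg$concordant_fc_range < 1) || length(cfg$concordant_fc_range) != 2)
    stop("concordant_fc_range must be two values >= 1", call. = FALSE)
  cfg
}

# gene and sample naming ------------------------------------------------

sim_gene_names <- function(cfg) {
  sprintf("G%04d", seq_len(cfg$n_genes))
}

sim_patient_ids <- function(cfg) {
  sprintf("P%d", seq_len(cfg$n_patients_good + cfg$n_patients_poor))
}

#' Hemoglobin-related gene panel of a simulated study
#'
#' @param config A [sim_config()] object.
#' @return Character vector of panel gene symbols (the first
#'   `n_hb_genes` genes of the simulated matrix).
#' @export
hb_panel <- function(config) {
  sim_gene_names(config)[seq_len(config$n_hb_genes)]
}

#' Outcome labels of the simulated RNA-seq patients
#'
#' Patients are labeled in order: the first `n_patients_good` are good,
#' the rest poor.
#'
#' @param config A [sim_config()] object.
#' @return `data.frame(patient, label)` with label in `{good, poor}`.
#' @export
sim_outcomes <- function(config) {
  ids <- sim_patient_ids(config)
  data.frame(patient = ids,
             label = rep(c("good", "poor"),
                         c(config$n_patients_good, config$n_patients_poor)),
             stringsAsFactors = FALSE)
}

# three independent sub-stream seeds derived from the master seed
substream_seeds <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  names(s) <- c("cohort", "expression", "qpcr")
  s
}

#' Default clinical-cohort generator settings
#'
#' Group means, SDs and proportions for the simulated 28-patient cohort
#' (16 non-anemia vs 12 anemia). The continuous and binary effect values
#' default to the baseline characteristics of the ischemic-stroke cohort
#' bundled with the package (see [ref_cohort_baseline()]), so that a
#' simulated cohort reproduces the published group structure in
#' expectation. Hemoglobin counts are drawn per sex around the configured
#' group means, and anemia-group counts fall below the WHO anemia
#' threshold (13 g/dL men, 12 g/dL women) with probability `below_prob`.
#'
#' @param n_non_anemia,n_anemia Cohort group sizes.
#' @param continuous `data.frame(var, mean_non_anemia, sd_non_anemia,
#'   mean_anemia, sd_anemia)`.
#' @param binary `data.frame(var, prop_non_anemia, prop_anemia)` of
#'   Bernoulli probabilities (sex is the proportion of males).
#' @param hb List with per-group normal parameters for the hemoglobin count
#'   and `below_prob`.
#' @return A list used as the `cohort_effects` field of [sim_config()].
#' @export
default_cohort_effects <- function(n_non_anemia = 16L,
                                   n_anemia = 12L,
                                   continuous = NULL,
                                   binary = NULL,
                                   hb = list(mean_non_anemia = 14.5,
                                             sd_non_anemia = 1.2,
                                             mean_anemia = 11.3,
                                             sd_anemia = 1.0,
                                             below_prob = 0.95)) {
  if (is.null(continuous)) {
    b <- ref_cohort_baseline()
    cb <- b[b$type == "continuous", ]
    continuous <- data.frame(var = cb$characteristic,
                             mean_non_anemia = cb$mean_non_anemia,
                             sd_non_anemia = cb$sd_non_anemia,
                             mean_anemia = cb$mean_anemia,
                             sd_anemia = cb$sd_anemia,
                             stringsAsFactors = FALSE)
  }
  if (is.null(binary)) {
    b <- ref_cohort_baseline()
    cb <- b[b$type == "binary", ]
    binary <- data.frame(var = cb$characteristic,
                         prop_non_anemia = cb$count_non_anemia / 16,
                         prop_anemia = cb$count_anemia / 12,
                         stringsAsFactors = FALSE)
  }
  list(n_non_anemia = as.integer(n_non_anemia),
       n_anemia = as.integer(n_anemia),
       continuous = continuous, binary = binary, hb = hb)
}

#' Default qPCR plate generator settings
#'
#' The simulated plate mirrors the validation design of the workflow: four
#' sample classes (3 ISA, 6 non_ISA, 5 TIA, 4 control), a beta-actin style
#' reference gene, and per-gene per-group Ct shifts. The default shifts give
#' the up-regulated candidate genes the mean-expression rank
#' ISA > non_ISA > TIA > control (a lower Ct means higher expression) and
#' the reverse rank to `CPM`.
#'
#' @param genes Character vector of target genes on the plate.
#' @param reference Name of the reference gene.
#' @param group_sizes Named integer vector of samples per group.
#' @param ref_ct Reference-gene baseline cycle threshold.
#' @param baseline_dct Per-target baseline offset from the reference Ct
#'   (recycled across `genes`).
#' @param shifts `data.frame(gene, group, shift)`: Ct added in that group
#'   (negative shift = higher expression). Missing combinations shift 0.
#' @param noise_sd Measurement noise SD on the Ct scale.
#' @param sample_effect_sd SD of a per-sample offset added to every Ct of
#'   the sample (loading/efficiency variation; cancelled by the reference
#'   correction).
#' @return A list used as the `qpcr_effects` field of [sim_config()].
#' @export
default_qpcr_effects <- function(genes = c("ELANE", "HBB", "PRTN3", "POU5F1",
                                           "PKM", "CPM"),
                                 reference = "ACTB",
                                 group_sizes = c(ISA = 3L, non_ISA = 6L,
                                                 TIA = 5L, control = 4L),
                                 ref_ct = 18,
                                 baseline_dct = 6,
                                 shifts = NULL,
                                 noise_sd = 0.25,
                                 sample_effect_sd = 0.3) {
  if (is.null(shifts)) {
    shifts <- expand.grid(gene = genes,
                          group = c("ISA", "non_ISA", "TIA", "control"),
                          stringsAsFactors = FALSE)
    key_up <- c(ISA = -2, non_ISA = -1.2, TIA = -0.5, control = 0)
    key_cpm <- -key_up  # reversed trend for CPM
    shifts$shift <- ifelse(shifts$gene == "CPM",
                           key_cpm[shifts$group], key_up[shifts$group])
  }
  list(genes = genes, reference = reference, group_sizes = group_sizes,
       ref_ct = ref_ct, baseline_dct = baseline_dct, shifts = shifts,
       noise_sd = noise_sd, sample_effect_sd = sample_effect_sd)
}
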