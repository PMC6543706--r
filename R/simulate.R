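#' Two-timepoint expression matrix container
#'
#' Lightweight container pairing a non-negative genes-by-samples value
#' matrix with per-sample metadata (patient and timepoint). Sample IDs are
#' `<patient>_T1` / `<patient>_T2`.
#'
#' @param values Numeric matrix, genes in rows (rownames = unique symbols),
#'   samples in columns.
#' @param samples `data.frame(sample, patient, timepoint)` matching the
#'   matrix columns; derived from the column names when omitted.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, samples = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene symbols: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (is.null(samples)) samples <- parse_sample_ids(colnames(values))
  stopifnot(identical(samples$sample, colnames(values)))
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_T([12])$", ids))
  bad <- ids[vapply(m, length, integer(1)) != 3L]
  if (length(bad))
    stop("sample IDs must look like <patient>_T1/<patient>_T2; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  data.frame(sample = ids,
             patient = vapply(m, `[`, character(1), 2L),
             timepoint = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples (",
      length(unique(x$samples$patient)), "patients, 2 timepoints )\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# value of one gene/patient/timepoint
em_value <- function(em, gene, patient, timepoint) {
  s <- em$samples$sample[em$samples$patient == patient &
                           em$samples$timepoint == timepoint]
  em$values[gene, s]
}

#' Simulate a clinical stroke cohort table
#'
#' Draws a per-patient clinical table with the two-group (non-anemia vs
#' anemia) structure configured in `config$cohort_effects`: continuous
#' covariates are normal with the configured group means/SDs, binary
#' covariates Bernoulli with the configured group proportions, and
#' hemoglobin counts are drawn per sex so that anemia-group patients fall
#' below the WHO threshold (13 g/dL men, 12 g/dL women) with probability
#' `below_prob`.
#'
#' @param config A [sim_config()] object.
#' @return A cohort data.frame (one row per patient) with columns `id`,
#'   `group`, `sex`, the configured continuous and binary covariates, and
#'   `hb_count`.
#' @export
simulate_cohort <- function(config) {
  config <- validate_sim_config(config)
  ce <- config$cohort_effects
  if (ce$n_non_anemia < 1L || ce$n_anemia < 1L)
    stop("cohort group sizes must be positive", call. = FALSE)
  set.seed(substream_seeds(config$seed)[["cohort"]])
  n <- ce$n_non_anemia + ce$n_anemia
  group <- rep(c("non_anemia", "anemia"), c(ce$n_non_anemia, ce$n_anemia))
  out <- data.frame(id = sprintf("C%02d", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)

  bin <- ce$binary
  sex_row <- match("sex_male", bin$var)
  p_male <- if (is.na(sex_row)) c(0.75, 0.75) else
    c(bin$prop_non_anemia[sex_row], bin$prop_anemia[sex_row])
  out$sex <- ifelse(stats::runif(n) <
                      ifelse(group == "non_anemia", p_male[1], p_male[2]),
                    "male", "female")

  for (i in seq_len(nrow(ce$continuous))) {
    v <- ce$continuous[i, ]
    out[[v$var]] <- stats::rnorm(n,
      mean = ifelse(group == "non_anemia", v$mean_non_anemia, v$mean_anemia),
      sd = ifelse(group == "non_anemia", v$sd_non_anemia, v$sd_anemia))
  }
  for (i in seq_len(nrow(bin))) {
    v <- bin[i, ]
    if (v$var == "sex_male") next
    out[[v$var]] <- stats::runif(n) <
      ifelse(group == "non_anemia", v$prop_non_anemia, v$prop_anemia)
  }

  thr <- ifelse(out$sex == "male", 13, 12)
  hb <- numeric(n)
  for (i in seq_len(n)) {
    if (group[i] == "non_anemia") {
      hb[i] <- stats::rnorm(1, ce$hb$mean_non_anemia, ce$hb$sd_non_anemia)
    } else if (stats::runif(1) < ce$hb$below_prob) {
      # truncated below the sex-specific anemia threshold
      u <- stats::runif(1) *
        stats::pnorm(thr[i], ce$hb$mean_anemia, ce$hb$sd_anemia)
      hb[i] <- stats::qnorm(u, ce$hb$mean_anemia, ce$hb$sd_anemia)
    } else {
      hb[i] <- stats::rnorm(1, ce$hb$mean_anemia, ce$hb$sd_anemia)
    }
  }
  out$hb_count <- hb
  out
}

#' Simulate a two-timepoint expression matrix
#'
#' Generates FPKM-like non-negative values for `n_genes` genes over two
#' samples per patient. Per-gene baselines are gamma distributed;
#' log-scale noise is idiosyncratic N(0, `noise_sd`) except inside planted
#' modules, where genes share a latent per-sample factor giving pairwise
#' log-scale correlation `rho` (total module log-SD `module_log_sd`).
#' Planted DEGs multiply the timepoint-2 value so that the expected
#' timepoint-2 / timepoint-1 ratio equals the configured signed fold
#' change; planted concordant genes receive a sign-forced timepoint-2
#' multiplier per patient so that their ECS agrees with (or opposes) the
#' patient's outcome label. Per-sample library-size factors are log-normal
#' with mean 1 and CV `library_size_cv`.
#'
#' @param config A [sim_config()] object.
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(config) {
  config <- validate_sim_config(config)
  set.seed(substream_seeds(config$seed)[["expression"]])
  genes <- sim_gene_names(config)
  patients <- sim_patient_ids(config)
  outcomes <- sim_outcomes(config)
  samples <- data.frame(
    sample = as.vector(t(outer(patients, c("_T1", "_T2"), paste0))),
    patient = rep(patients, each = 2L),
    timepoint = rep(1:2, length(patients)),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  G <- config$n_genes

  baseline <- stats::rgamma(G, shape = config$baseline_shape,
                            scale = exp(config$baseline_log_mean) /
                              config$baseline_shape)
  lib <- if (config$library_size_cv > 0) {
    sdlog <- sqrt(log(1 + config$library_size_cv^2))
    stats::rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, ns)

  # module membership: disjoint consecutive blocks of the panel
  module_of <- integer(G)
  pos <- 0L
  for (m in seq_along(config$module_spec)) {
    sz <- as.integer(config$module_spec[[m]]$size)
    module_of[(pos + 1L):(pos + sz)] <- m
    pos <- pos + sz
  }

  lognoise <- matrix(stats::rnorm(G * ns, sd = config$noise_sd), G, ns)
  for (m in seq_along(config$module_spec)) {
    rho <- as.numeric(config$module_spec[[m]]$rho)
    idx <- which(module_of == m)
    z <- stats::rnorm(ns)                      # shared latent factor
    u <- matrix(stats::rnorm(length(idx) * ns), length(idx), ns)
    lognoise[idx, ] <- config$module_log_sd *
      (sqrt(rho) * matrix(z, length(idx), ns, byrow = TRUE) +
         sqrt(1 - rho) * u)
  }

  values <- baseline * exp(lognoise) *
    matrix(lib, G, ns, byrow = TRUE)
  dimnames(values) <- list(genes, samples$sample)

  t2 <- samples$timepoint == 2L
  if (!is.null(config$planted_degs)) {
    pd <- config$planted_degs
    for (i in seq_len(nrow(pd))) {
      mult <- if (pd$fc[i] >= 0) pd$fc[i] else 1 / abs(pd$fc[i])
      cols <- t2 & (is.na(pd$patient[i]) | samples$patient == pd$patient[i])
      values[pd$gene[i], cols] <- values[pd$gene[i], cols] * mult
    }
  }
  if (!is.null(config$planted_concordant)) {
    pc <- config$planted_concordant
    for (i in seq_len(nrow(pc))) {
      mags <- stats::runif(length(patients), config$concordant_fc_range[1],
                           config$concordant_fc_range[2])
      for (j in seq_along(patients)) {
        good <- outcomes$label[j] == "good"
        up <- if (pc$direction[i] == "positive") good else !good
        mult <- if (up) mags[j] else 1 / mags[j]
        col <- t2 & samples$patient == patients[j]
        values[pc$gene[i], col] <- values[pc$gene[i], col] * mult
      }
    }
  }

  em <- expression_matrix(values, samples)
  attr(em, "module_of") <- stats::setNames(module_of, genes)
  em
}

#' Simulate a qPCR plate of Ct values
#'
#' Draws cycle-threshold values for the configured target genes and a
#' reference gene over four sample groups (ISA, non_ISA, TIA, control):
#' `ct = ref_ct + baseline_dct + group shift + sample offset + noise`,
#' with the reference gene at `ref_ct + sample offset + noise`. The
#' per-sample offset emulates loading differences and cancels in the
#' reference correction.
#'
#' @param config A [sim_config()] object.
#' @return A Ct table `data.frame(sample, group, gene, ct, is_reference)`.
#' @export
simulate_qpcr <- function(config) {
  config <- validate_sim_config(config)
  qe <- config$qpcr_effects
  if (is.null(qe$reference) || !nzchar(qe$reference))
    stop("qPCR config must name a reference gene", call. = FALSE)
  set.seed(substream_seeds(config$seed)[["qpcr"]])
  groups <- rep(names(qe$group_sizes), qe$group_sizes)
  samp <- sprintf("S%02d", seq_along(groups))
  offs <- stats::rnorm(length(samp), sd = qe$sample_effect_sd)
  base_dct <- rep_len(qe$baseline_dct, length(qe$genes))
  rows <- list()
  for (s in seq_along(samp)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samp[s], group = groups[s], gene = qe$reference,
      ct = qe$ref_ct + offs[s] + stats::rnorm(1, sd = qe$noise_sd),
      is_reference = TRUE, stringsAsFactors = FALSE)
    for (g in seq_along(qe$genes)) {
      sh <- qe$shifts$shift[qe$shifts$gene == qe$genes[g] &
                              qe$shifts$group == groups[s]]
      if (!length(sh)) sh <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samp[s], group = groups[s], gene = qe$genes[g],
        ct = qe$ref_ct + base_dct[g] + sh + offs[s] +
          stats::rnorm(1, sd = qe$noise_sd),
        is_reference = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
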