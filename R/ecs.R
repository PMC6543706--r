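#' Expression Changed Score
#'
#' The relative expression change of a gene between the two timepoints:
#' `ECS = (E2 - E1) / E1`. Defined whenever `E1 > 0`, with minimum -1
#' (total loss of expression at timepoint 2); undefined (`NA`) when
#' `E1 = 0`. Scale invariant: multiplying both values by a constant does
#' not change the score.
#'
#' @param e1,e2 Non-negative expression values at timepoints 1 and 2
#'   (vectorized).
#' @return Numeric vector of ECS values (`NA` where `e1 = 0`).
#' @export
#' @examples
#' ecs(2, 8)   # 3
#' ecs(5, 0)   # -1
ecs <- function(e1, e2) {
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  ifelse(e1 > 0, (e2 - e1) / e1, NA_real_)
}

#' ECS table for a set of candidate genes
#'
#' One Expression Changed Score per gene per patient, computed from the
#' patient's timepoint-1 and timepoint-2 samples.
#'
#' @param matrix An [expression_matrix()] in which every patient has both
#'   timepoints.
#' @param genes Character vector of gene symbols present in the matrix
#'   (typically the ECHB-layer nodes).
#' @return `data.frame(gene, patient, e1, e2, ecs)`.
#' @export
ecs_table <- function(matrix, genes) {
  stopifnot(inherits(matrix, "expr_matrix"))
  bad <- setdiff(genes, rownames(matrix$values))
  if (length(bad))
    stop("gene(s) not in matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sm <- matrix$samples
  patients <- unique(sm$patient)
  for (p in patients)
    if (!all(1:2 %in% sm$timepoint[sm$patient == p]))
      stop("patient ", p, " is missing a timepoint", call. = FALSE)
  out <- expand.grid(gene = genes, patient = patients,
                     stringsAsFactors = FALSE)
  s1 <- sm$sample[match(paste(out$patient, 1), paste(sm$patient, sm$timepoint))]
  s2 <- sm$sample[match(paste(out$patient, 2), paste(sm$patient, sm$timepoint))]
  out$e1 <- matrix$values[cbind(out$gene, s1)]
  out$e2 <- matrix$values[cbind(out$gene, s2)]
  out$ecs <- ecs(out$e1, out$e2)
  out
}

#' Classify candidate genes by ECS-outcome concordance
#'
#' Formalizes the rank comparison between per-patient ECS values and
#' clinical outcome as sign concordance: a patient is
#' positively-concordant for a gene when a good outcome goes with a
#' positive ECS or a poor outcome with a negative ECS, and
#' negatively-concordant in the reverse cases (an ECS of exactly 0 counts
#' for neither). A gene is labeled `positive` when at least
#' `min_concordant` patients are positively-concordant, `negative` when at
#' least `min_concordant` are negatively-concordant, and `unclassified`
#' otherwise (including genes with fewer than `min_concordant` defined ECS
#' values).
#'
#' @param records ECS records from [ecs_table()].
#' @param outcomes `data.frame(patient, label)` with label in
#'   `{good, poor}` covering every patient in `records`.
#' @param min_concordant Minimum concordant patients for a directional
#'   label; defaults to `ceiling(3 * n_patients / 4)` (3 of 4 in the
#'   four-patient design).
#' @return `data.frame(gene, label, n_positive, n_negative, n_defined,
#'   total)`.
#' @export
classify_correlation <- function(records, outcomes, min_concordant = NULL) {
  stopifnot(all(c("gene", "patient", "ecs") %in% names(records)),
            all(c("patient", "label") %in% names(outcomes)))
  if (!all(outcomes$label %in% c("good", "poor")))
    stop("outcome labels must be 'good' or 'poor'", call. = FALSE)
  miss <- setdiff(unique(records$patient), outcomes$patient)
  if (length(miss))
    stop("missing outcome label for patient(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n_pat <- length(unique(records$patient))
  if (is.null(min_concordant)) min_concordant <- ceiling(3 * n_pat / 4)
  lab <- outcomes$label[match(records$patient, outcomes$patient)]
  good <- lab == "good"
  pos_conc <- !is.na(records$ecs) &
    ((good & records$ecs > 0) | (!good & records$ecs < 0))
  neg_conc <- !is.na(records$ecs) &
    ((good & records$ecs < 0) | (!good & records$ecs > 0))
  agg <- function(flag) tapply(flag, records$gene, sum)
  genes <- unique(records$gene)
  npos <- agg(pos_conc)[genes]
  nneg <- agg(neg_conc)[genes]
  ndef <- agg(!is.na(records$ecs))[genes]
  total <- agg(rep(TRUE, nrow(records)))[genes]
  label <- ifelse(ndef < min_concordant, "unclassified",
           ifelse(npos >= min_concordant, "positive",
           ifelse(nneg >= min_concordant, "negative", "unclassified")))
  data.frame(gene = genes, label = unname(label),
             n_positive = unname(as.integer(npos)),
             n_negative = unname(as.integer(nneg)),
             n_defined = unname(as.integer(ndef)),
             total = unname(as.integer(total)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dichotomize clinical outcome from discharge scores
#'
#' Default rule: a patient has a good outcome when the discharge mRS is at
#' most `mrs_good_max` OR the Barthel Index is at least `bi_good_min`.
#' The BI component captures patients whose mRS alone is borderline but
#' whose daily-living score indicates substantial recovery; both cut-offs
#' are configuration, not a clinical claim.
#'
#' @param record Data.frame with columns `patient`, `mrs` and (for the
#'   default rule) `bi`.
#' @param mrs_good_max mRS threshold (default 3).
#' @param bi_good_min Barthel Index threshold (default 60).
#' @return `data.frame(patient, label)` with label in `{good, poor}`.
#' @export
#' @examples
#' outcome_from_clinical(ref_patient_info())
outcome_from_clinical <- function(record, mrs_good_max = 3, bi_good_min = 60) {
  stopifnot(is.data.frame(record), "patient" %in% names(record))
  if (!"mrs" %in% names(record) || anyNA(record$mrs))
    stop("mRS is required for outcome dichotomization", call. = FALSE)
  if (!"bi" %in% names(record) || anyNA(record$bi))
    stop("BI is required by the default rule", call. = FALSE)
  good <- record$mrs <= mrs_good_max | record$bi >= bi_good_min
  data.frame(patient = record$patient,
             label = ifelse(good, "good", "poor"),
             stringsAsFactors = FALSE)
}
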