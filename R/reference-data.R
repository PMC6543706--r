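#' Baseline characteristics of the reference ischemic-stroke cohort
#'
#' Published summary statistics for a 28-patient non-acute ischemic-stroke
#' cohort divided by WHO anemia status (16 non-anemia, 12 anemia): group
#' means and SDs for the continuous characteristics (age, NIHSS, mRS,
#' Barthel Index, four myodynamia scores), affected counts for sex and ten
#' medical-history flags, and the reported two-group p-values. These are
#' the values the cohort-statistics functions are validated against and the
#' group structure the synthetic cohort generator emulates.
#'
#' Columns `mean_*`/`sd_*` are populated for continuous rows, `count_*`
#' for binary rows (count of males for sex, of affected patients for
#' history flags), `p_reported` is the published two-group p-value and
#' `regression_p_reported` the published Pr(>|t|) of the regression of the
#' characteristic on the hemoglobin count.
#'
#' @return A data.frame with one row per characteristic, in the published
#'   row order.
#' @export
ref_cohort_baseline <- function() {
  con <- function(char, m1, s1, m2, s2, p, rp)
    data.frame(characteristic = char, type = "continuous",
               mean_non_anemia = m1, sd_non_anemia = s1,
               mean_anemia = m2, sd_anemia = s2,
               count_non_anemia = NA_real_, count_anemia = NA_real_,
               p_reported = p, regression_p_reported = rp,
               stringsAsFactors = FALSE)
  bin <- function(char, c1, c2, p, rp)
    data.frame(characteristic = char, type = "binary",
               mean_non_anemia = NA_real_, sd_non_anemia = NA_real_,
               mean_anemia = NA_real_, sd_anemia = NA_real_,
               count_non_anemia = c1, count_anemia = c2,
               p_reported = p, regression_p_reported = rp,
               stringsAsFactors = FALSE)
  rbind(
    bin("sex_male", 12, 10, 0.9470, 0.858),
    con("age", 60.25, 11.1325, 70.1667, 9.0135, 0.0151, 0.0863),
    con("nihss", 7.75, 3.8730, 12.6667, 2.6054, 0.0005, 0.00081),
    con("mrs", 3.5625, 0.6292, 4.5833, 0.5149, 7.25e-05, 0.000236),
    con("bi", 55.3125, 21.5614, 19.5833, 14.6874, 1.97e-05, 0.000155),
    con("myo_ul_prox", 2.3934, 1.9767, 0.8333, 0.9614, 0.0114, 0.162),
    con("myo_ul_dist", 2.2125, 1.9544, 1.125, 1.5393, 0.1117, 0.17),
    con("myo_ll_prox", 3.2322, 1.6744, 1.775, 1.6864, 0.0327, 0.0545),
    con("myo_ll_dist", 3.10625, 1.8024, 1.6917, 1.7516, 0.0474, 0.0686),
    bin("hypertension", 12, 7, 0.5991, 0.751),
    bin("diabetes_mellitus", 3, 4, 0.6592, 0.654),
    bin("hyperlipemia", 3, 2, 1, 0.802),
    bin("hyperuricemia", 0, 1, 0.8831, 0.673),
    bin("cerebral_arteriosclerosis", 1, 4, 0.1760, 0.162),
    bin("atrial_fibrillation", 2, 2, 1, 0.997),
    bin("pulmonary_infection", 2, 9, 0.00311, 0.0223),
    bin("coronary_disease", 2, 1, 1, 0.335),
    bin("carotid_atherosclerosis", 2, 4, 0.38715, 0.527))
}

#' Group sizes of the reference cohort
#' @return Named integer vector `c(non_anemia = 16, anemia = 12)`.
#' @export
ref_cohort_sizes <- function() c(non_anemia = 16L, anemia = 12L)

#' Expression Changed Scores of the seven candidate biomarker genes
#'
#' Published ECS values, `(E2 - E1) / E1`, for the seven hemoglobin-related
#' candidate biomarker genes across the four RNA-seq patients (P1 and P3
#' had good outcomes; P2 and P4 poor), together with the published
#' outcome-correlation label of each gene.
#'
#' @return `data.frame(gene, P1, P2, P3, P4, label_reported)`.
#' @export
ref_candidate_ecs <- function() {
  data.frame(
    gene = c("ELANE", "FGF23", "HBB", "PIEZO1", "RASA4", "PRTN3", "CPM"),
    P1 = c(0.583441373, 0.195748708, 5.019638524, 0.132460873,
           3.743960021, 0.285708006, -0.366842748),
    P2 = c(-0.876154889, -0.068076233, -0.903588029, -0.130037547,
           -0.0797773, -0.89533385, 0.196248494),
    P3 = c(36.11814293, 1.585274991, 20.79802103, 0.45536621,
           1.743071554, 26.2326035, -0.308800687),
    P4 = c(-0.71205701, -0.384025361, -0.902093625, -0.478729345,
           -1, -0.767875709, -0.032850712),
    label_reported = c("positive", "positive", "positive", "positive",
                       "positive", "positive", "negative"),
    stringsAsFactors = FALSE)
}

#' Pairwise common differentially expressed genes of the reference study
#'
#' The published per-patient two-timepoint DEG intersections: genes shared
#' by patients P2 and P3, and by P2 and P4. Their joint intersection is the
#' seed gene of the candidate subnetwork (HBB).
#'
#' @return Named list of character vectors.
#' @export
ref_common_deg_sets <- function() {
  list(P2_P3 = c("PRKCSH", "HBD", "HBB"),
       P2_P4 = c("DHPS", "CFD", "IRF9", "FTH1P10", "HBB"))
}

#' Clinical information of the four reference RNA-seq patients
#'
#' Discharge scores of the four two-timepoint RNA-seq patients, used to
#' demonstrate and test the outcome dichotomization rule (P1 and P3 had
#' better outcomes than P2 and P4).
#'
#' @return `data.frame(patient, age, nihss, mrs, bi, label_reported)`.
#' @export
ref_patient_info <- function() {
  data.frame(patient = c("P1", "P2", "P3", "P4"),
             age = c(51, 62, 71, 86),
             nihss = c(2, 14, 9, 10),
             mrs = c(2, 5, 4, 4),
             bi = c(95, 15, 75, 40),
             label_reported = c("good", "poor", "good", "poor"),
             stringsAsFactors = FALSE)
}
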