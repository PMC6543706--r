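#' Signed fold change between two timepoints
#'
#' The ratio between the two timepoints with the sign convention used for
#' recovery analysis: increases are reported as `e2 / e1` (positive),
#' decreases as `-(e1 / e2)` (negative), so the magnitude is always >= 1.
#' If exactly one value is zero the result is a signed infinity; if both
#' are zero it is undefined (`NA`).
#'
#' @param e1,e2 Non-negative expression values at timepoints 1 and 2
#'   (vectorized).
#' @return Numeric vector of signed fold changes (`Inf`, `-Inf`, or `NA`
#'   for zero-expression sentinels).
#' @export
#' @examples
#' signed_fold_change(2, 8)   #  4
#' signed_fold_change(8, 2)   # -4
signed_fold_change <- function(e1, e2) {
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  out <- ifelse(e1 == 0 & e2 == 0, NA_real_,
         ifelse(e1 == 0, Inf,
         ifelse(e2 == 0, -Inf,
         ifelse(e2 >= e1, e2 / e1, -(e1 / e2)))))
  unname(out)
}

# deterministic half-up rounding (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Call differentially expressed genes between two timepoints of a patient
#'
#' Desk-scale stand-in for an alignment-level differential test on one
#' patient's two samples: expression values are scaled to pseudo-counts
#' (`value * scale_to_counts`, rounded half-up) and each gene's
#' timepoint-2 count is compared against the library-size-ratio null by a
#' conditional Poisson test, i.e. an exact binomial test of `c2` out of
#' `c1 + c2` against `p0 = L2 / (L1 + L2)` where `L1`, `L2` are the
#' samples' total pseudo-counts. P-values are Benjamini-Hochberg adjusted
#' across tested genes and a gene is called when `q <= q_threshold`.
#' Genes with zero pseudo-counts at both timepoints are not testable and
#' are reported with `tested = FALSE`.
#'
#' @param matrix An [expression_matrix()].
#' @param patient Patient ID present in the matrix with both timepoints.
#' @param q_threshold FDR threshold in (0, 1) for calling a gene.
#' @param scale_to_counts Positive factor mapping expression values to
#'   pseudo-counts.
#' @return A data.frame with one row per gene: `gene`, `patient`, `e1`,
#'   `e2`, `signed_fc`, `p`, `q`, `tested`, `called`.
#' @export
call_degs <- function(matrix, patient, q_threshold = 0.05,
                      scale_to_counts = 10) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)", call. = FALSE)
  sm <- matrix$samples
  s1 <- sm$sample[sm$patient == patient & sm$timepoint == 1L]
  s2 <- sm$sample[sm$patient == patient & sm$timepoint == 2L]
  if (length(s1) != 1L || length(s2) != 1L)
    stop("patient ", patient, " must have exactly timepoints 1 and 2",
         call. = FALSE)
  e1 <- matrix$values[, s1]
  e2 <- matrix$values[, s2]
  c1 <- round_half_up(e1 * scale_to_counts)
  c2 <- round_half_up(e2 * scale_to_counts)
  L1 <- sum(c1); L2 <- sum(c2)
  if (L1 + L2 == 0) stop("all-zero matrix: nothing to test", call. = FALSE)
  p0 <- L2 / (L1 + L2)
  tested <- (c1 + c2) > 0
  p <- rep(NA_real_, length(e1))
  p[tested] <- vapply(which(tested), function(i) {
    stats::binom.test(c2[i], c1[i] + c2[i], p = p0)$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(e1))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(gene = rownames(matrix$values), patient = patient,
             e1 = unname(e1), e2 = unname(e2),
             signed_fc = signed_fold_change(e1, e2),
             p = unname(p), q = unname(q), tested = tested,
             called = !is.na(q) & q <= q_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersection of per-patient DEG sets
#'
#' The common differentially expressed genes across two or more patients:
#' the exact intersection of the given symbol sets. The shared genes form
#' the seed set of the candidate (CHB) subnetwork.
#'
#' @param deg_sets List of at least two character vectors of gene symbols.
#' @return Character vector of genes present in every set (order of the
#'   first set).
#' @export
#' @examples
#' common_degs(list(c("PRKCSH", "HBD", "HBB"),
#'                  c("DHPS", "CFD", "IRF9", "FTH1P10", "HBB")))
common_degs <- function(deg_sets) {
  if (!is.list(deg_sets) || length(deg_sets) < 2)
    stop("need at least two DEG sets", call. = FALSE)
  Reduce(intersect, deg_sets)
}
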