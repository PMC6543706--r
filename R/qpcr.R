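#' Reference-corrected Ct difference
#'
#' `delta Ct = Ct(target) - Ct(reference)` for one sample; the first
#' normalization step of relative quantification.
#'
#' @param ct_gene,ct_ref Finite cycle-threshold values (vectorized).
#' @return Numeric vector of delta-Ct values.
#' @export
delta_ct <- function(ct_gene, ct_ref) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_ref)))
    stop("Ct values must be finite", call. = FALSE)
  ct_gene - ct_ref
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each target gene and sample: technical replicates are averaged on
#' the Ct scale, the sample's reference-gene mean Ct is subtracted
#' (delta Ct), the per-gene mean delta Ct of the calibrator group is
#' subtracted (delta-delta Ct), and relative expression is
#' `base^(-ddct)` (amplification efficiency fixed at `base = 2` unless a
#' standard curve says otherwise). Adding a constant to every Ct of a
#' sample leaves the result unchanged, and the calibrator group's mean
#' ddct is 0 per gene by construction.
#'
#' @param table Ct table: `data.frame(sample, group, gene, ct,
#'   is_reference)`; every sample needs at least one reference
#'   measurement.
#' @param calibrator_group Group used as calibrator (default `"control"`).
#' @param base Amplification efficiency base (default 2).
#' @return `data.frame(gene, sample, group, delta_ct, ddct, rel)`.
#' @export
relative_expression <- function(table, calibrator_group = "control",
                                base = 2) {
  stopifnot(all(c("sample", "group", "gene", "ct", "is_reference") %in%
                  names(table)))
  if (any(table$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ref <- table[table$is_reference, ]
  if (!nrow(ref)) stop("missing reference gene", call. = FALSE)
  ref_ct <- tapply(ref$ct, ref$sample, mean)
  tg <- table[!table$is_reference, ]
  no_ref <- setdiff(unique(tg$sample), names(ref_ct))
  if (length(no_ref))
    stop("sample(s) without a reference measurement: ",
         paste(no_ref, collapse = ", "), call. = FALSE)
  # average technical replicates on the Ct scale
  key <- paste(tg$sample, tg$gene, sep = "\r")
  ct_mean <- tapply(tg$ct, key, mean)
  uq <- !duplicated(key)
  out <- data.frame(gene = tg$gene[uq], sample = tg$sample[uq],
                    group = tg$group[uq], stringsAsFactors = FALSE)
  out$delta_ct <- unname(ct_mean[key[uq]]) -
    unname(ref_ct[out$sample])
  cal <- out$group == calibrator_group
  out$ddct <- NA_real_
  for (g in unique(out$gene)) {
    sel <- out$gene == g
    if (!any(sel & cal))
      stop("no calibrator-group measurement for gene ", g, call. = FALSE)
    out$ddct[sel] <- out$delta_ct[sel] - mean(out$delta_ct[sel & cal])
  }
  out$rel <- base^(-out$ddct)
  out
}

#' Wilcoxon rank-sum comparison of relative expression between two groups
#'
#' Two-sided Wilcoxon rank-sum test on one gene's relative-expression
#' values: exact enumeration when the combined sample size is at most 12
#' and there are no ties, otherwise the normal approximation with tie and
#' continuity correction (via [stats::wilcox.test()]).
#'
#' @param rel Output of [relative_expression()].
#' @param g1,g2 Group labels to compare.
#' @param gene Target gene symbol.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) path;
#'   default `NULL` picks by the n <= 12 / no-ties rule.
#' @return List with `statistic` (rank-sum W), `p.value`, `method`,
#'   `n1`, `n2`.
#' @export
wilcoxon_group_test <- function(rel, g1, g2, gene, exact = NULL) {
  x <- rel$rel[rel$group == g1 & rel$gene == gene]
  y <- rel$rel[rel$group == g2 & rel$gene == gene]
  if (!length(x) || !length(y))
    stop("empty group in comparison", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = ht$method, n1 = length(x), n2 = length(y))
}

#' Rank sample groups by mean relative expression
#'
#' Orders the four sample classes by descending mean relative expression
#' of one gene, the trend summary used to validate candidate biomarkers
#' (e.g. ISA > non_ISA > TIA > control for up-regulated genes). Ties are
#' broken by group name (byte order, locale independent) and flagged.
#'
#' @param rel Output of [relative_expression()].
#' @param gene Target gene symbol.
#' @param groups Required groups (default the four sample classes).
#' @return List with `ranking` (character vector, highest first), `means`
#'   (named, in ranking order) and `tied` flag.
#' @export
group_rank_profile <- function(rel, gene,
                               groups = c("ISA", "non_ISA", "TIA",
                                          "control")) {
  sel <- rel$gene == gene
  if (!any(sel)) stop("gene not in table: ", gene, call. = FALSE)
  miss <- setdiff(groups, unique(rel$group[sel]))
  if (length(miss))
    stop("missing group(s): ", paste(miss, collapse = ", "), call. = FALSE)
  m <- tapply(rel$rel[sel], rel$group[sel], mean)[groups]
  ord <- order(-m, names(m), method = "radix")  # byte order: locale-stable
  list(ranking = names(m)[ord], means = m[ord],
       tied = anyDuplicated(m) > 0)
}

#' Bar plot of group mean relative expression for one gene
#'
#' Mean relative expression per sample class with SD error bars, on the
#' 2^(-ddCt) scale.
#'
#' @param rel Output of [relative_expression()].
#' @param gene Target gene symbol.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the named vector of group means.
#' @export
plot_relative_expression <- function(rel, gene, ...) {
  sel <- rel$gene == gene
  if (!any(sel)) stop("gene not in table: ", gene, call. = FALSE)
  m <- tapply(rel$rel[sel], rel$group[sel], mean)
  s <- tapply(rel$rel[sel], rel$group[sel], stats::sd)
  bp <- graphics::barplot(m, ylim = c(0, max(m + s, na.rm = TRUE) * 1.1),
                          ylab = "relative expression (2^-ddCt)",
                          main = gene, ...)
  graphics::arrows(bp, m - pmin(s, m, na.rm = TRUE), bp, m + s,
                   angle = 90, code = 3, length = 0.05)
  invisible(m)
}
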