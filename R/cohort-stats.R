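#' Welch two-sample t-test from group summary statistics
#'
#' Unequal-variance (Welch) t-test computed directly from per-group mean,
#' SD and n, as needed when only published summaries are available:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p. Set `pooled = TRUE` for the
#' classical equal-variance form.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return List with `statistic`, `df`, `p.value`, `method`.
#' @export
#' @examples
#' welch_t_from_summary(60.25, 11.1325, 16, 70.1667, 9.0135, 12)$p.value
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2, pooled = FALSE) {
  if (n1 < 2 || n2 < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(list(statistic = 0, df = if (pooled) n1 + n2 - 2 else NA_real_,
                  p.value = 1, method = "degenerate (both SDs zero)"))
    stop("both SDs zero with unequal means: t undefined", call. = FALSE)
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Two-sample t (pooled variance) from summaries"
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    method <- "Welch two-sample t from summaries"
  }
  t <- (m1 - m2) / se
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df), method = method)
}

#' Welch two-sample t-test from raw values
#'
#' Convenience wrapper over [stats::t.test()] returning the same fields as
#' [welch_t_from_summary()]; by construction identical to the summary form
#' applied to the lists' means/SDs/lengths.
#'
#' @param x1,x2 Numeric vectors, each of length >= 2.
#' @inheritParams welch_t_from_summary
#' @return List with `statistic`, `df`, `p.value`, `method`.
#' @export
welch_t_from_raw <- function(x1, x2, pooled = FALSE) {
  if (length(x1) < 2 || length(x2) < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
    return(welch_t_from_summary(mean(x1), 0, length(x1),
                                mean(x2), 0, length(x2), pooled = pooled))
  ht <- stats::t.test(x1, x2, var.equal = pooled)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, method = ht$method)
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates-corrected Pearson chi-square for the 2x2 table `[a b; c d]`:
#' `chi2 = n (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1,
#' upper-tail p. A table with a zero margin carries no information about
#' association; by convention it returns p = 1 with `zero_margin = TRUE`
#' and a warning. Set `correct = FALSE` for the uncorrected statistic.
#'
#' @param a,b,c,d Non-negative cell counts (row 1: a, b; row 2: c, d).
#' @param correct Apply the Yates continuity correction (default TRUE).
#' @return List with `statistic`, `df`, `p.value`, `method`, `zero_margin`.
#' @export
#' @examples
#' chi2_2x2_yates(2, 14, 9, 3)$p.value
chi2_2x2_yates <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("table is empty", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    warning("zero margin: association undefined, returning p = 1")
    return(list(statistic = 0, df = 1, p.value = 1,
                method = "chi-square (zero margin convention)",
                zero_margin = TRUE))
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  chi <- n * num^2 / prod(margins)
  list(statistic = chi, df = 1,
       p.value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       method = if (correct) "Pearson chi-square with Yates correction"
                else "Pearson chi-square",
       zero_margin = FALSE)
}

#' Simple linear regression of an outcome on hemoglobin count
#'
#' Ordinary least squares of `outcome` on `hb` (intercept + slope) via
#' [stats::lm()]; reports the slope t-statistic and its two-sided
#' `Pr(>|t|)` on n - 2 degrees of freedom.
#'
#' @param hb Numeric predictor (hemoglobin counts), not constant.
#' @param outcome Numeric response of the same length (>= 3).
#' @return List with `slope`, `statistic`, `df`, `p.value`, `method`.
#' @export
hb_regression <- function(hb, outcome) {
  if (length(hb) != length(outcome) || length(hb) < 3)
    stop("hb and outcome must have equal length >= 3", call. = FALSE)
  if (stats::sd(hb) == 0)
    stop("constant predictor: regression undefined", call. = FALSE)
  fit <- stats::lm(outcome ~ hb)
  cf <- summary(fit)$coefficients
  list(slope = cf["hb", "Estimate"], statistic = cf["hb", "t value"],
       df = length(hb) - 2, p.value = cf["hb", "Pr(>|t|)"],
       method = "OLS slope t-test (outcome ~ hb)")
}

#' Baseline comparison table for a two-group stroke cohort
#'
#' Reproduces the standard baseline-characteristics table: per
#' characteristic, group summaries (mean and SD for continuous variables,
#' affected count and percentage for binary ones), the two-group test p
#' (Welch t for continuous, continuity-corrected chi-square for binary),
#' and the `Pr(>|t|)` of the OLS regression of the characteristic on the
#' hemoglobin count.
#'
#' @param cohort Cohort data.frame as produced by [simulate_cohort()] (or
#'   read with [read_cohort_csv()]): columns `id`, `group` in
#'   `{non_anemia, anemia}`, `sex`, `hb_count`, plus numeric and logical
#'   covariates.
#' @param pooled Use pooled-variance t-tests instead of Welch.
#' @param yates Apply the continuity correction in the 2x2 tests.
#' @return A data.frame with one row per characteristic: group summaries,
#'   `statistic`, `p`, `regression_p` and a `zero_margin` flag.
#' @export
baseline_table <- function(cohort, pooled = FALSE, yates = TRUE) {
  stopifnot(all(c("id", "group", "sex", "hb_count") %in% names(cohort)))
  g1 <- cohort$group == "non_anemia"
  g2 <- cohort$group == "anemia"
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("each group needs at least 2 patients", call. = FALSE)
  hb <- cohort$hb_count
  vars <- setdiff(names(cohort), c("id", "group", "hb_count"))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (v == "sex") x <- x == "male"
    if (is.logical(x)) {
      a <- sum(x[g1]); b <- sum(!x[g1]); c2 <- sum(x[g2]); d <- sum(!x[g2])
      ct <- withCallingHandlers(
        chi2_2x2_yates(a, b, c2, d, correct = yates),
        warning = function(w) invokeRestart("muffleWarning"))
      reg <- hb_regression(hb, as.numeric(x))
      data.frame(characteristic = if (v == "sex") "sex_male" else v,
                 type = "binary",
                 mean_non_anemia = NA_real_, sd_non_anemia = NA_real_,
                 mean_anemia = NA_real_, sd_anemia = NA_real_,
                 count_non_anemia = a, pct_non_anemia = 100 * a / sum(g1),
                 count_anemia = c2, pct_anemia = 100 * c2 / sum(g2),
                 statistic = ct$statistic, p = ct$p.value,
                 regression_p = reg$p.value, zero_margin = ct$zero_margin,
                 stringsAsFactors = FALSE)
    } else {
      tt <- welch_t_from_raw(x[g1], x[g2], pooled = pooled)
      reg <- hb_regression(hb, x)
      data.frame(characteristic = v, type = "continuous",
                 mean_non_anemia = mean(x[g1]), sd_non_anemia = stats::sd(x[g1]),
                 mean_anemia = mean(x[g2]), sd_anemia = stats::sd(x[g2]),
                 count_non_anemia = NA_real_, pct_non_anemia = NA_real_,
                 count_anemia = NA_real_, pct_anemia = NA_real_,
                 statistic = tt$statistic, p = tt$p.value,
                 regression_p = reg$p.value, zero_margin = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
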