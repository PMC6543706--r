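test_that("summary-based and raw-data Welch tests are the same test", {
  set.seed(31)
  for (i in 1:10) {
    x1 <- rnorm(7, 1, 2); x2 <- rnorm(5)
    a <- welch_t_from_raw(x1, x2)
    b <- welch_t_from_summary(mean(x1), sd(x1), 7, mean(x2), sd(x2), 5)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    bp <- welch_t_from_summary(mean(x1), sd(x1), 7, mean(x2), sd(x2), 5,
                               pooled = TRUE)
    expect_equal(welch_t_from_raw(x1, x2, pooled = TRUE)$p.value,
                 bp$p.value, tolerance = 1e-12)
  }
})

test_that("Welch p matches numerical integration of the t density", {
  x1 <- c(1.2, 3.4, 2.2); x2 <- c(5.0, 4.1, 6.3)
  res <- welch_t_from_raw(x1, x2)
  oracle <- 2 * stats::integrate(function(u) stats::dt(u, df = res$df),
                                 abs(res$statistic), Inf)$value
  expect_equal(res$p.value, oracle, tolerance = 1e-6)
})

test_that("Welch test: group swap flips t and keeps p; degenerate inputs", {
  a <- welch_t_from_summary(10, 2, 8, 12, 3, 9)
  b <- welch_t_from_summary(12, 3, 9, 10, 2, 8)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, -b$statistic)
  id <- welch_t_from_summary(5, 1.5, 10, 5, 1.5, 10)
  expect_equal(id$statistic, 0)
  expect_equal(id$p.value, 1)
  expect_equal(welch_t_from_summary(3, 0, 5, 3, 0, 6)$p.value, 1)
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
  expect_error(welch_t_from_raw(c(1, 2), 3), "n >= 2")
  expect_equal(welch_t_from_raw(c(2, 5, 1), c(1, 2, 5))$p.value, 1)
})

test_that("Yates chi-square matches chisq.test and is below uncorrected", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    mine <- chi2_2x2_yates(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
    raw <- chi2_2x2_yates(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                          correct = FALSE)
    expect_lte(mine$statistic, raw$statistic)
    expect_gte(mine$p.value, raw$p.value)
  }
})

test_that("chi-square degenerate tables: correction floors at zero, zero margin", {
  expect_equal(chi2_2x2_yates(3, 13, 2, 10)$p.value, 1)
  expect_equal(chi2_2x2_yates(5, 5, 5, 5)$statistic, 0)
  expect_warning(res <- chi2_2x2_yates(0, 16, 0, 12), "zero margin")
  expect_equal(res$p.value, 1)
  expect_true(res$zero_margin)
  expect_error(chi2_2x2_yates(-1, 2, 3, 4), "non-negative")
})

test_that("regression slope test matches hand-solved normal equations", {
  hb <- c(12, 12, 14, 15, 15)   # duplicated predictor values
  y <- c(8, 6, 5, 3, 4)
  res <- hb_regression(hb, y)
  xc <- hb - mean(hb); slope <- sum(xc * y) / sum(xc^2)
  fit <- mean(y) + slope * xc
  se <- sqrt(sum((y - fit)^2) / 3 / sum(xc^2))
  tval <- slope / se
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$statistic, tval, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(-abs(tval), 3), tolerance = 1e-12)
})

test_that("regression: perfect linear fit and error contracts", {
  hb <- 1:10
  expect_lt(suppressWarnings(hb_regression(hb, 2 * hb + 1)$p.value), 1e-12)
  expect_error(hb_regression(rep(3, 5), 1:5), "constant predictor")
  expect_error(hb_regression(1:4, 1:3), "equal length")
})

test_that("regression p is uniform under the null", {
  set.seed(99)
  p <- replicate(500, hb_regression(rnorm(12), rnorm(12))$p.value)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("baseline table reproduces the reference categorical p-values", {
  # cohort hand-built to match the published marginal counts of the
  # 10 history flags and the sex split
  b <- ref_cohort_baseline()
  bb <- b[b$type == "binary", ]
  n1 <- 16; n2 <- 12
  cohort <- data.frame(id = sprintf("C%02d", 1:(n1 + n2)),
                       group = rep(c("non_anemia", "anemia"), c(n1, n2)),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(bb))) {
    v <- bb$characteristic[i]
    x <- c(rep(TRUE, bb$count_non_anemia[i]),
           rep(FALSE, n1 - bb$count_non_anemia[i]),
           rep(TRUE, bb$count_anemia[i]),
           rep(FALSE, n2 - bb$count_anemia[i]))
    if (v == "sex_male") {
      cohort$sex <- ifelse(x, "male", "female")
    } else cohort[[v]] <- x
  }
  cohort$hb_count <- c(rnorm(n1, 14.5), rnorm(n2, 11))
  tab <- baseline_table(cohort)
  for (i in seq_len(nrow(bb))) {
    got <- tab$p[tab$characteristic == bb$characteristic[i]]
    expect_equal(got, bb$p_reported[i], tolerance = 0.05,
                 label = bb$characteristic[i])
  }
})

test_that("baseline table flags all-false columns via the zero-margin convention", {
  cohort <- data.frame(id = sprintf("C%02d", 1:8),
                       group = rep(c("non_anemia", "anemia"), each = 4),
                       sex = rep(c("male", "female"), 4),
                       flag = rep(FALSE, 8),
                       hb_count = c(rnorm(4, 14), rnorm(4, 11)),
                       stringsAsFactors = FALSE)
  tab <- baseline_table(cohort)
  row <- tab[tab$characteristic == "flag", ]
  expect_equal(row$p, 1)
  expect_true(row$zero_margin)
})

test_that("a null-effect cohort rarely shows significant characteristics", {
  # equal group means/proportions everywhere: expect no excess of
  # significant rows beyond the nominal rate
  eff <- default_cohort_effects()
  eff$continuous$mean_anemia <- eff$continuous$mean_non_anemia
  eff$continuous$sd_anemia <- eff$continuous$sd_non_anemia
  eff$binary$prop_anemia <- eff$binary$prop_non_anemia
  eff$hb <- list(mean_non_anemia = 13, sd_non_anemia = 1,
                 mean_anemia = 13, sd_anemia = 1, below_prob = 0)
  hits <- 0L; total <- 0L
  for (s in 1:40) {
    cfg <- sim_config(seed = s, cohort_effects = eff)
    tab <- baseline_table(simulate_cohort(cfg))
    hits <- hits + sum(tab$p < 0.05)
    total <- total + nrow(tab)
  }
  # binary rows are conservative (Yates + discreteness), so the overall
  # rate sits below the nominal 5%
  expect_lt(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})
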