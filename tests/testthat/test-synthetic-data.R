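test_that("generators are byte-deterministic under a fixed seed and
           independent across sub-streams", {
  cfg <- sim_config(seed = 7, n_genes = 50, n_hb_genes = 20,
                    module_spec = list(list(size = 5, rho = 0.5)))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1$values, e2$values)
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # regenerating one table does not depend on whether others were drawn
  co <- simulate_cohort(cfg)
  simulate_expression(cfg)
  expect_identical(co, simulate_cohort(cfg))
  # different seeds give different data
  cfg2 <- sim_config(seed = 8, n_genes = 50, n_hb_genes = 20,
                     module_spec = list(list(size = 5, rho = 0.5)))
  expect_false(identical(e1$values, simulate_expression(cfg2)$values))
})

test_that("config validation rejects inconsistent structure", {
  expect_error(sim_config(n_patients_good = 0), "positive")
  expect_error(sim_config(n_genes = 10, n_hb_genes = 20), "n_hb_genes")
  expect_error(sim_config(n_hb_genes = 10, n_genes = 20,
                          module_spec = list(list(size = 6, rho = 0.5),
                                             list(size = 6, rho = 0.5))),
               "overlap")
  expect_error(sim_config(planted_degs = data.frame(gene = "G9999",
                                                    fc = 2)),
               "outside the matrix")
  expect_error(sim_config(planted_degs = data.frame(gene = "G0001",
                                                    fc = 0.5)),
               "fc")
  expect_error(sim_config(planted_concordant =
                            data.frame(gene = "G0001", direction = "up")),
               "direction")
})

test_that("null cohort covariates give uniform Welch p-values", {
  eff <- default_cohort_effects()
  eff$continuous <- data.frame(var = "age", mean_non_anemia = 60,
                               sd_non_anemia = 10, mean_anemia = 60,
                               sd_anemia = 10)
  eff$binary <- eff$binary[eff$binary$var == "sex_male", ]
  p <- vapply(1:500, function(s) {
    co <- simulate_cohort(sim_config(seed = s, cohort_effects = eff))
    welch_t_from_raw(co$age[co$group == "non_anemia"],
                     co$age[co$group == "anemia"])$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("empirical Welch power matches the noncentral-t oracle", {
  b <- ref_cohort_baseline()
  x <- b[b$characteristic == "age", ]
  eff <- default_cohort_effects()
  eff$continuous <- data.frame(var = "age",
                               mean_non_anemia = x$mean_non_anemia,
                               sd_non_anemia = x$sd_non_anemia,
                               mean_anemia = x$mean_anemia,
                               sd_anemia = x$sd_anemia)
  eff$binary <- eff$binary[eff$binary$var == "sex_male", ]
  n1 <- 16; n2 <- 12
  rej <- vapply(1:1000, function(s) {
    co <- simulate_cohort(sim_config(seed = s, cohort_effects = eff))
    welch_t_from_raw(co$age[co$group == "non_anemia"],
                     co$age[co$group == "anemia"])$p.value < 0.05
  }, logical(1))
  # closed-form oracle: noncentral t with Welch df from population SDs
  se2 <- x$sd_non_anemia^2 / n1 + x$sd_anemia^2 / n2
  ncp <- (x$mean_non_anemia - x$mean_anemia) / sqrt(se2)
  df <- se2^2 / ((x$sd_non_anemia^2 / n1)^2 / (n1 - 1) +
                   (x$sd_anemia^2 / n2)^2 / (n2 - 1))
  crit <- qt(0.975, df)
  power <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  expect_lt(abs(mean(rej) - power),
            3 * sqrt(power * (1 - power) / 1000))
})

test_that("anemia-group hemoglobin falls below the sex-specific threshold", {
  cfg <- sim_config(seed = 3)
  co <- simulate_cohort(cfg)
  an <- co[co$group == "anemia", ]
  thr <- ifelse(an$sex == "male", 13, 12)
  expect_gte(mean(an$hb_count < thr), 0.75)
})

test_that("a noiseless unit-correlation module is an exact clique in r", {
  cfg <- sim_config(seed = 2, n_genes = 10, n_hb_genes = 5,
                    module_spec = list(list(size = 3, rho = 1)),
                    noise_sd = 0, library_size_cv = 0.1)
  em <- simulate_expression(cfg)
  v <- em$values[1:3, ]
  expect_equal(cor(v[1, ], v[2, ]), 1, tolerance = 1e-12)
  expect_equal(cor(v[1, ], v[3, ]), 1, tolerance = 1e-12)
  expect_equal(cor(v[2, ], v[3, ]), 1, tolerance = 1e-12)
})

test_that("noiseless planted fold changes are reproduced exactly", {
  cfg <- tiny_config(seed = 4, noise_sd = 0,
                     planted_degs = data.frame(
                       gene = c("G0001", "G0002"),
                       patient = c("P1", NA),
                       fc = c(4, -3)))
  em <- simulate_expression(cfg)
  d1 <- call_degs(em, "P1")
  expect_equal(d1$signed_fc[d1$gene == "G0001"], 4, tolerance = 1e-9)
  expect_equal(d1$signed_fc[d1$gene == "G0002"], -3, tolerance = 1e-9)
  d2 <- call_degs(em, "P2")
  expect_equal(d2$signed_fc[d2$gene == "G0001"], 1, tolerance = 1e-9)
  expect_equal(d2$signed_fc[d2$gene == "G0002"], -3, tolerance = 1e-9)
})

test_that("module correlation is recovered within Fisher-z error at n=50", {
  cfg <- sim_config(seed = 6, n_patients_good = 13, n_patients_poor = 12,
                    n_genes = 20, n_hb_genes = 10,
                    module_spec = list(list(size = 10, rho = 0.8)),
                    library_size_cv = 0)
  em <- simulate_expression(cfg)
  lv <- log(em$values[1:10, ])
  cm <- cor(t(lv))
  rbar <- mean(cm[upper.tri(cm)])
  # mean of 45 correlated sample r's; Fisher-z SE of one r at n=50
  z_se <- 1 / sqrt(50 - 3)
  expect_lt(abs(atanh(rbar) - atanh(0.8)), 3 * z_se)
})

test_that("planted concordant genes move with the outcome labels", {
  cfg <- tiny_config(seed = 9, noise_sd = 0,
                     planted_concordant = data.frame(
                       gene = c("G0003", "G0004"),
                       direction = c("positive", "negative")))
  em <- simulate_expression(cfg)
  et <- ecs_table(em, c("G0003", "G0004"))
  out <- sim_outcomes(cfg)
  lab <- out$label[match(et$patient, out$patient)]
  pos <- et$gene == "G0003"
  expect_true(all(sign(et$ecs[pos]) == ifelse(lab[pos] == "good", 1, -1)))
  expect_true(all(sign(et$ecs[!pos]) == ifelse(lab[!pos] == "good", -1, 1)))
})

test_that("noiseless qPCR plates give exact relative expression", {
  qe <- default_qpcr_effects(noise_sd = 0, sample_effect_sd = 0)
  qe$shifts$shift <- 0
  cfg <- sim_config(seed = 5, qpcr_effects = qe)
  rel <- relative_expression(simulate_qpcr(cfg))
  expect_equal(rel$rel, rep(1, nrow(rel)), tolerance = 1e-12)

  qe$shifts$shift <- ifelse(qe$shifts$group == "ISA", -1, 0)
  cfg <- sim_config(seed = 5, qpcr_effects = qe)
  rel <- relative_expression(simulate_qpcr(cfg))
  expect_equal(unname(tapply(rel$rel, rel$group, mean)[["ISA"]]), 2,
               tolerance = 1e-12)
})

test_that("ordered qPCR group shifts give the expected expression rank", {
  ok <- vapply(1:20, function(s) {
    qe <- default_qpcr_effects(noise_sd = 0.15)
    rel <- relative_expression(
      simulate_qpcr(sim_config(seed = s, qpcr_effects = qe)))
    identical(group_rank_profile(rel, "HBB")$ranking,
              c("ISA", "non_ISA", "TIA", "control")) &&
      identical(group_rank_profile(rel, "CPM")$ranking,
                c("control", "TIA", "non_ISA", "ISA"))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
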