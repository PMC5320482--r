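test_that("the default truth is deterministic with the planted sign structure", {
  t1 <- make_default_truth(3)
  t2 <- make_default_truth(3)
  expect_identical(t1, t2)
  expect_false(identical(t1$surface, make_default_truth(4)$surface))
  gcb <- vapply(t1$surface, `[[`, 1, "gcb_mg")
  expect_equal(sum(gcb < 0), 3L)   # negative GCB effect for 3 of 5 analytes
  expect_true(all(gcb[c("2,4-D", "thiabendazole")] > 0))
  for (a in t1$analytes) {
    beta <- t1$surface[[a]]
    # interior optimum in HCl, concave toluene, boundary optimum in GCB
    hcl_star <- -beta[["hcl_pct"]] / (2 * beta[["hcl_pct^2"]])
    expect_gt(hcl_star, -1)
    expect_lt(hcl_star, 1)
    expect_lt(beta[["toluene_pct^2"]], 0)
    expect_equal(beta[["gcb_mg^2"]], 0)
  }
})

test_that("noise-free DOE simulation is exact and fits recover the truth", {
  truth <- make_default_truth(1)
  ccd <- ccd_design(truth$factors[c("toluene_pct", "hcl_pct", "gcb_mg")],
                    n_center = 6)
  resp <- simulate_doe(ccd, truth, seed = 9, noise_sd = 0)
  for (a in truth$analytes) {
    y <- resp$response[resp$analyte == a]
    m <- fit_quadratic(ccd, y)
    expect_equal(unname(m$coef), unname(truth$surface[[a]]),
                 tolerance = 1e-8)
  }
  # same seed -> identical table; different seed -> same truth, new noise
  r1 <- simulate_doe(ccd, truth, seed = 5)
  r2 <- simulate_doe(ccd, truth, seed = 5)
  r3 <- simulate_doe(ccd, truth, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$response, r3$response))
  expect_true(all(r1$response >= 0 & r1$response <= 110))
})

test_that("screening simulation recovers the planted significant set", {
  truth <- make_default_truth(1)
  # raise effect-to-noise to at least 6 for the recovery check
  for (a in truth$analytes) {
    truth$screening_effects[[a]][c("toluene_pct", "hcl_pct")] <- c(3, 4.5)
  }
  truth$noise_sd <- 1
  pb <- pb_design(truth$factors, 3)
  hits <- 0
  nsim <- 500
  for (i in seq_len(nsim)) {
    resp <- simulate_doe(pb, truth, seed = i)
    tb <- screen_effects(pb, resp$response[resp$analyte == "carbendazim"])
    sig <- tb$factor[tb$significant]
    if (all(c("toluene_pct", "hcl_pct", "gcb_mg") %in% sig)) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.95)
})

test_that("calibration simulation encodes dilution-shrunk matrix effects", {
  truth <- make_default_truth(1)
  truth$calibration_cv <- 0
  sol <- simulate_calibration(truth, "carbendazim", "methanol")
  nd <- simulate_calibration(truth, "carbendazim", "citrus", "ND")
  d10 <- simulate_calibration(truth, "carbendazim", "citrus", "D10")
  cs <- fit_calibration(sol$level_ugL, sol$signal)
  expect_equal(cs$r_squared, 1, tolerance = 1e-12)
  me_nd <- matrix_effect(fit_calibration(nd$level_ugL, nd$signal), cs)
  me_d10 <- matrix_effect(fit_calibration(d10$level_ugL, d10$signal), cs)
  planted <- truth$me_factor["citrus", "carbendazim"]
  expect_equal(me_nd$me_percent, (planted - 1) * 100, tolerance = 1e-8)
  expect_lt(abs(me_d10$me_percent), abs(me_nd$me_percent))
  # shrink rule: D10 deviation is (1 - shrink) of the ND deviation
  expect_equal(me_d10$me_percent,
               (planted - 1) * (1 - truth$dilution_shrink) * 100,
               tolerance = 1e-8)
  # every matrix/analyte with non-unit factor improves on dilution
  for (mx in rownames(truth$me_factor)) {
    for (a in truth$analytes) {
      f <- truth$me_factor[mx, a]
      if (f != 1) {
        expect_lt(abs(1 + (f - 1) * (1 - truth$dilution_shrink) - 1),
                  abs(f - 1))
      }
    }
  }
  expect_error(simulate_calibration(truth, "carbendazim", "granite"),
               "unknown matrix")
})

test_that("recovery simulation has the planted mean and variance components", {
  truth <- make_default_truth(1)
  zero <- truth
  zero$sd_within <- 0
  zero$sd_between <- 0
  r0 <- recovery_summary(simulate_recovery(zero, "iprodione", "citrus"))
  expect_equal(r0$mean_recovery, zero$recovery_mean)
  expect_equal(r0$rsd_intra, 0)
  expect_equal(r0$rsd_inter, 0)
  means <- numeric(200)
  vars <- numeric(200)
  for (i in 1:200) {
    tab <- simulate_recovery(truth, "iprodione", "citrus", seed = i)
    means[i] <- mean(tab$recovery_pct)
    vars[i] <- var(tab$recovery_pct)
  }
  expect_equal(mean(means), truth$recovery_mean, tolerance = 0.01)
  # one-way layout, 3 days x 5 reps: E[S^2] = sd_w^2 + sd_b^2 (N - n)/(N - 1)
  # with N = 15 total and n = 5 per day
  expected_var <- truth$sd_within^2 + truth$sd_between^2 * (15 - 5) / 14
  expect_equal(mean(vars), expected_var, tolerance = 0.1)
})

test_that("survey simulation respects prevalence and censoring", {
  truth <- make_default_truth(1)
  none <- truth
  none$prevalence <- 0
  sv0 <- simulate_survey(none, seed = 2)
  expect_equal(nrow(sv0), 85L)
  expect_true(all(is.na(sv0$conc_ugkg)))
  all_pos <- truth
  all_pos$prevalence <- 1
  all_pos$loq[] <- 1e-9   # every residue quantifiable
  sv1 <- simulate_survey(all_pos, seed = 3)
  ss1 <- survey_summary(sv1, all_pos$commodity_counts, all_pos$loq)
  expect_equal(ss1$positive_pct, 100L)
  # binomial mean at the default 12% prevalence
  rates <- vapply(1:3000, function(i) {
    sv <- simulate_survey(truth, seed = i)
    ss <- survey_summary(sv, truth$commodity_counts, truth$loq)
    ss$positive_pct_raw
  }, numeric(1))
  expect_lt(abs(mean(rates) - 12), 0.5)
})
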