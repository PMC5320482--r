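test_that("standards-preparation uncertainty combines rectangular tolerances", {
  expect_equal(u_standards(purity = c(0.99, 0)), 0)
  expect_equal(u_standards(volumes = list(c(10, 0), c(1, 0))), 0)
  expect_equal(round(u_standards(purity = c(0.990, 0.005)), 5),
               round((0.005 / sqrt(3)) / 0.990, 5))
  expect_equal(round(u_standards(purity = c(0.990, 0.005)), 5), 0.00292)
  # RSS of independent steps; a single component passes through unchanged
  u1 <- u_standards(purity = c(1, sqrt(3) * 0.0015))
  expect_equal(u1, 0.0015)
  both <- u_standards(purity = c(1, sqrt(3) * 0.003),
                      mass = c(10, sqrt(3) * 0.04))
  expect_equal(both, sqrt(0.003^2 + 0.004^2))
  # temperature term adds in quadrature within a volumetric step
  v <- u_standards(volumes = list(c(10, 0, 0.02)))
  expect_equal(v, 0.002)
  expect_error(u_standards(mass = c(0, 0.1)), "zero nominal")
  expect_error(u_standards(purity = c(0.99, -0.1)), "negative tolerance")
})

test_that("calibration uncertainty follows the s_x0 closed form", {
  lv <- c(0.1, 1, 5, 10, 50, 100, 200)
  cc <- fit_calibration(lv, 50 + 10 * lv)
  expect_equal(u_calibration(cc, m = 3, x0 = 50), 0)
  set.seed(14)
  cc2 <- fit_calibration(lv, 50 + 10 * lv + rnorm(7, 0, 20))
  # closed-form check against the formula written out by hand
  u <- u_calibration(cc2, m = 2, x0 = 50)
  s_y <- cc2$residual_sd
  expect_equal(u, (s_y / abs(cc2$slope)) *
                 sqrt(1 / 2 + 1 / 7 + (50 - mean(lv))^2 /
                        sum((lv - mean(lv))^2)) / 50)
  # m -> infinity limit at x0 = x-bar
  u_inf <- u_calibration(cc2, m = 1e12, x0 = mean(lv))
  expect_equal(u_inf, (s_y / abs(cc2$slope)) * sqrt(1 / 7) / mean(lv),
               tolerance = 1e-5)
  expect_error(u_calibration(cc2, m = 1, x0 = 0), "positive")
})

test_that("calibration uncertainty matches a parametric-bootstrap oracle", {
  lv <- c(0.1, 1, 5, 10, 50, 100, 200)
  set.seed(15)
  cc <- fit_calibration(lv, 50 + 10 * lv + rnorm(7, 0, 15))
  x0 <- 50
  u <- u_calibration(cc, m = 1, x0 = x0)
  # regenerate calibrations and a fresh single measurement from the fitted
  # curve, re-estimate x0 each time, and compare SD(x0_hat)/x0
  set.seed(16)
  sims <- replicate(2000, {
    y <- cc$intercept + cc$slope * lv + rnorm(7, 0, cc$residual_sd)
    f <- lm(y ~ lv)
    y0 <- cc$intercept + cc$slope * x0 + rnorm(1, 0, cc$residual_sd)
    (y0 - coef(f)[1]) / coef(f)[2]
  })
  expect_equal(sd(sims) / x0, u, tolerance = 0.1)
})

test_that("precision and recovery components follow their closed forms", {
  expect_equal(u_precision(0.35), 0.0035)
  expect_equal(u_precision(0), 0)
  expect_equal(u_precision(5, of_mean = TRUE, n_assay = 4), 0.025)
  expect_equal(round(u_recovery(90, 9, 9), 4), 0.0333)
  expect_equal(u_recovery(90, 0, 9), 0)
  # doubling n divides by sqrt(2)
  expect_equal(u_recovery(90, 9, 18) * sqrt(2), u_recovery(90, 9, 9))
  expect_error(u_recovery(0, 9, 9), "positive")
})

test_that("combination is root-sum-square with the documented properties", {
  u <- c(0.0015, 0.0232, 0.0045, 0.0303)
  uc <- combine_uncertainty(u)
  expect_equal(round(uc, 4), 0.0385)
  expect_equal(expand_uncertainty(uc), 7.7)
  uc2 <- combine_uncertainty(c(0.0021, 0.0027, 0.0027, 0.0371))
  expect_equal(round(uc2, 4), 0.0374)
  expect_equal(combine_uncertainty(rep(0, 4)), 0)
  expect_error(combine_uncertainty(c(0.1, -0.1)), ">= 0")
  # u_c >= max component, <= sum, monotone in each component
  set.seed(17)
  for (i in 1:20) {
    v <- runif(4, 0, 0.05)
    uc <- combine_uncertainty(v)
    expect_gte(uc, max(v))
    expect_lte(uc, sum(v))
    v2 <- v + c(0.01, 0, 0, 0)
    expect_gt(combine_uncertainty(v2), uc)
  }
  # expansion is linear in k
  expect_equal(expand_uncertainty(0.04, k = 4, digits = NULL),
               2 * expand_uncertainty(0.04, k = 2, digits = NULL))
})

test_that("reported budgets recombine to the published table", {
  u <- validation_example("uncertainty")
  b <- lapply(seq_len(nrow(u)), function(i) {
    uncertainty_budget(u$u1[i], u$u2[i], u$u3[i], u$u4[i],
                       analyte = u$analyte[i])
  })
  names(b) <- u$analyte
  # U_c to 4 decimals where the published value is self-consistent
  expect_equal(round(b$thiabendazole$u_c, 4), 0.0385)
  expect_equal(round(b$iprodione$u_c, 4), 0.0374)
  expect_equal(round(b$prochloraz$u_c, 4), 0.0423)
  # expanded uncertainty row to 1 decimal
  expect_equal(b[["2,4-D"]]$u_exp_percent, 8.5)
  expect_equal(b$thiabendazole$u_exp_percent, 7.7)
  expect_equal(b$iprodione$u_exp_percent, 7.5)
  # five-analyte average expanded uncertainty
  expect_equal(round(mean(vapply(b, `[[`, 1, "u_exp_percent_raw")), 1), 7.6)
})
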