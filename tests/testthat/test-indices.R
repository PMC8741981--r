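test_that("dynamic driving pressure is pmax minus PEEP with a positive-pressure domain", {
  expect_equal(dynamic_driving_pressure(23.6, 6.0), 17.6)
  expect_equal(dynamic_driving_pressure(20.3 + 6.0, 6.0), 20.3)
  for (x in c(0.5, 7, 30)) {
    expect_equal(dynamic_driving_pressure(x, 0), x)
  }
  expect_error(dynamic_driving_pressure(6, 6), "must exceed")
  expect_error(dynamic_driving_pressure(10, -1), "non-negative")
})

test_that("dynamic compliance divides tidal volume by driving pressure", {
  expect_equal(dynamic_compliance(547, 17.6), 547 / 17.6)
  expect_equal(round(dynamic_compliance(547, 17.6), 2), 31.08)
  expect_equal(dynamic_compliance(100, 4), 25)
  expect_equal(dynamic_compliance(432, 1), 432)
  expect_error(dynamic_compliance(0, 5))
  expect_error(dynamic_compliance(500, 0))
})

test_that("simplified mechanical power is 0.098 * RR * VT(L) * Pmax", {
  expect_equal(mechanical_power(16.5, 0.547, 23.6), 0.098 * 16.5 * 0.547 * 23.6)
  expect_equal(round(mechanical_power(16.5, 0.547, 23.6), 2), 20.87)
  expect_equal(round(mechanical_power_mv(9.0, 23.6), 2), 20.82)
  expect_lt(mechanical_power(20, 1e-9, 30), 1e-6)
  expect_error(mechanical_power(0, 0.5, 20))
  expect_warning(mechanical_power(16, 547, 23.6), "mL")
})

test_that("predicted body weight follows the gender-specific height formula", {
  expect_equal(predicted_body_weight("male", 152.4), 50.0)
  expect_equal(predicted_body_weight("female", 152.4), 45.5)
  expect_equal(round(predicted_body_weight("male", 175), 2), 70.57)
  expect_error(predicted_body_weight("other", 170), "gender")
  expect_warning(predicted_body_weight("male", 100), "height")
})

test_that("power normalizations divide by PBW and compliance correctly", {
  expect_equal(round(pbw_normalized_mp(20.87, 70.57), 4), 0.2957)
  expect_equal(pbw_normalized_mp(3.7, 1), 3.7)
  expect_error(pbw_normalized_mp(-1, 70))
  mp <- mechanical_power(16.5, 0.547, 23.6)
  ltc <- dynamic_compliance(547, 17.6)
  expect_equal(ltc_normalized_mp(mp, ltc), 16.5 * 23.6 * 17.6,
               tolerance = 1e-12)
  expect_error(ltc_normalized_mp(20, 0))
})

test_that("compliance-normalized power equals RR * Pmax * dPaw for random settings", {
  set.seed(11)
  for (i in 1:50) {
    rr <- runif(1, 8, 35)
    vt <- runif(1, 0.25, 0.9)
    peep <- runif(1, 0, 10)
    pmax <- peep + runif(1, 5, 25)
    dp <- dynamic_driving_pressure(pmax, peep)
    mp <- mechanical_power(rr, vt, pmax)
    ltc <- dynamic_compliance(vt * 1000, dp)
    expect_equal(ltc_normalized_mp(mp, ltc), rr * pmax * dp,
                 tolerance = 1e-9)
  }
})

test_that("power index rescales by the PaCO2 ratio with an isocapnic fixpoint", {
  expect_equal(round(power_index(6853.44, 35, 1), 1), 5330.5)
  expect_equal(round(power_index(6853.44, 35, 2), 1), 4145.9)
  set.seed(5)
  for (i in 1:25) {
    x <- runif(1, 100, 10000)
    k <- sample(c(0.5, 1, 2, 3), 1)
    expect_equal(power_index(x, 45, exponent = k), x)
  }
  expect_error(power_index(6853, 35, exponent = -1))
  expect_error(power_index(0, 35, 1))
})

test_that("power index is monotone in PaCO2, base value and exponent", {
  set.seed(8)
  for (i in 1:30) {
    x <- runif(1, 500, 12000)
    p <- runif(1, 20, 60)
    # increasing in PaCO2 and in the base value
    expect_lt(power_index(x, p, 1), power_index(x, p + 1, 1))
    expect_lt(power_index(x, p, 1), power_index(x * 1.1, p, 1))
    # exponent direction flips at the isocapnic target
    if (p > 45) {
      expect_lt(power_index(x, p, 1), power_index(x, p, 2))
    } else if (p < 45) {
      expect_gt(power_index(x, p, 1), power_index(x, p, 2))
    }
  }
})

test_that("doubling tidal volume at fixed driving pressure doubles LTC and MP but not LTC-MP", {
  rr <- 15; peep <- 6; pmax <- 24
  dp <- dynamic_driving_pressure(pmax, peep)
  for (vt in c(0.4, 0.55)) {
    mp1 <- mechanical_power(rr, vt, pmax)
    mp2 <- mechanical_power(rr, 2 * vt, pmax)
    ltc1 <- dynamic_compliance(vt * 1000, dp)
    ltc2 <- dynamic_compliance(2 * vt * 1000, dp)
    expect_equal(mp2, 2 * mp1)
    expect_equal(ltc2, 2 * ltc1)
    expect_equal(ltc_normalized_mp(mp2, ltc2), ltc_normalized_mp(mp1, ltc1))
  }
})

test_that("ventilatory ratio matches its normalization and unit value", {
  expect_equal(round(ventilatory_ratio(9.0, 35.0, 70.57), 3), 1.190)
  pbw <- 62
  expect_equal(ventilatory_ratio(pbw * 100 / 1000, 37.5, pbw), 1.0)
  expect_error(ventilatory_ratio(0, 35, 60))
})

test_that("compute_panel composes the per-index operations and is deterministic", {
  co <- toy_cohort()
  panel <- compute_panel(co)
  expect_equal(nrow(panel), 3)
  a <- panel[panel$patient_id == "A", ]
  expect_equal(a$delta_paw, 17.6)
  expect_equal(a$ltc_dyn, 547 / 17.6)
  expect_equal(a$mp, mechanical_power(16.5, 0.547, 23.6))
  expect_equal(a$pbw, predicted_body_weight("male", 175))
  expect_equal(a$ltcdyn_mp, 16.5 * 23.6 * 17.6, tolerance = 1e-9)
  expect_equal(a$pi_1, a$ltcdyn_mp * 35 / 45)
  expect_equal(a$pi_2, a$ltcdyn_mp * (35 / 45)^2)
  expect_equal(a$vr, ventilatory_ratio(9.0, 35, a$pbw))
  expect_identical(panel, compute_panel(co))
})

test_that("compute_panel names the offending patient on invalid input", {
  co <- toy_cohort()
  co$pmax[2] <- co$peep[2]
  expect_error(compute_panel(co), "patient 'B'")
})

test_that("compute_panel reconstructs minute ventilation when absent", {
  co <- toy_cohort()
  co$minute_ventilation <- NULL
  panel <- compute_panel(co)
  expect_equal(panel$vr[1],
               ventilatory_ratio(16.5 * 547 / 1000, 35, panel$pbw[1]))
})

test_that("SBT outcome classification matches a disjunction oracle on a boundary grid", {
  eps <- 1e-9
  grid <- expand.grid(
    bf = c(35 - eps, 35, 35 + eps, NA),
    hr = c(130, 130 + eps, NA),
    sbp = c(160, 160 + eps, NA),
    spo2 = c(88 - eps, 88, NA),
    paco2 = c(45, 45 + eps, 48.9, NA)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (all(is.na(g))) {
      expect_error(classify_sbt_outcome(g$bf, g$hr, g$sbp, g$spo2, g$paco2))
    } else {
      expect_identical(
        classify_sbt_outcome(g$bf, g$hr, g$sbp, g$spo2, g$paco2),
        disjunction_outcome(g$bf, g$hr, g$sbp, g$spo2, g$paco2),
        info = paste(unlist(g), collapse = "/"))
    }
  }
})

test_that("SBT outcome uses strict cut-offs and the printed failure pattern", {
  # hypercapnia alone triggers failure
  expect_identical(classify_sbt_outcome(25, 95, 130, 95, 48.9), "failure")
  # all in range is success
  expect_identical(classify_sbt_outcome(20, 90, 120, 95, 36.3), "success")
  # exact boundary values do not trigger
  expect_identical(classify_sbt_outcome(35, 130, 160, 88, 45.0), "success")
  # missing blood gas but tachypnoea
  expect_identical(classify_sbt_outcome(40, NA, NA, NA, NA), "failure")
  expect_error(classify_sbt_outcome(NA, NA, NA, NA, NA), "missing")
})
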