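test_that("transforms follow the declared per-term rules", {
  cs <- smart2_coefficients()
  rec <- full_record(hscrp = 2.0, egfr = 77)
  z <- transform_record(rec, cs)
  expect_equal(z[["hscrp"]], log(2.0))
  expect_equal(z[["egfr"]], 5929)
  expect_equal(z[["non_hdl"]], log(3.3))
  expect_equal(z[["years_since_first_ascvd"]], 1.8^2)
  expect_equal(z[["sex"]], 1)

  # full 13-term map against an independently hand-built table
  rec2 <- full_record(age = 70, sex = 0, current_smoking = 1,
                      systolic_bp = 150, non_hdl = 4.2, diabetes = 1,
                      cad = 1, cevd = 1, pad = 0, aaa = 0,
                      years_since_first_ascvd = 5, egfr = 60, hscrp = 6.5)
  z2 <- transform_record(rec2, cs)
  hand <- c(age = 70, sex = 0, current_smoking = 1, systolic_bp = 150,
            non_hdl = 1.4350845253, diabetes = 1, cad = 1, cevd = 1,
            pad = 0, aaa = 0, years_since_first_ascvd = 25, egfr = 3600,
            hscrp = 1.8718021769)
  expect_equal(z2[names(hand)], hand, tolerance = 1e-9)

  # values below the positivity floor are floored with a warning
  expect_warning(z3 <- transform_record(full_record(hscrp = 0.001), cs),
                 "floor")
  expect_equal(z3[["hscrp"]], log(0.01))

  # a record lacking a named term is a schema mismatch
  expect_error(transform_record(data.frame(age = 60), toy_coefset()),
               "schema mismatch")
})

test_that("linear predictor breakdown sums to its total and is 0 at means", {
  cs <- toy_coefset()
  lp <- linear_predictor(toy_record(age = 70, hscrp = 4), cs)
  expect_s3_class(lp, "lp_breakdown")
  expect_equal(sum(lp$terms) + lp$offset, lp$total, tolerance = 1e-12)
  lp0 <- linear_predictor(toy_record(age = 60, hscrp = 2), cs)
  expect_equal(lp0$total, 0, tolerance = 1e-12)
})

test_that("risk at the centering means equals 1 - S0 and region factors scale the hazard", {
  cs <- toy_coefset(region_factors = list(europe_low = 1, europe_high = 2))
  rec <- toy_record(age = 60, hscrp = 2)
  for (h in c(2, 6, 10)) {
    r <- predict_risk(rec, cs, "europe_low", h)
    expect_equal(r$risk, 1 - cs$baseline_survival[[as.character(h)]],
                 tolerance = 1e-12)
  }
  r1 <- predict_risk(rec, cs, "europe_low", 10)$risk
  r2 <- predict_risk(rec, cs, "europe_high", 10)$risk
  expect_equal(-log(1 - r2), 2 * -log(1 - r1), tolerance = 1e-12)
  expect_error(predict_risk(rec, cs, "atlantis", 10), "region")
  expect_error(predict_risk(rec, cs, "europe_low", 40), "extrapolation")
  # step rule between knots: horizon 7 uses the 6-year knot
  expect_equal(predict_risk(rec, cs, "europe_low", 7)$risk,
               predict_risk(rec, cs, "europe_low", 6)$risk)
})

test_that("antithrombotic offset multiplies the cumulative hazard by exactly 0.81", {
  cs <- smart2_coefficients()
  for (rec in list(full_record(), full_record(age = 75, hscrp = 9,
                                              egfr = 45))) {
    for (h in c(2, 3, 6, 10)) {
      ru <- predict_risk(rec, cs, "europe_low", h,
                         treat_antithrombotic = FALSE)$risk
      rt <- predict_risk(rec, cs, "europe_low", h,
                         treat_antithrombotic = TRUE)$risk
      expect_equal(log(1 - rt) / log(1 - ru), 0.81, tolerance = 1e-12)
    }
  }
})

test_that("risk moves in the clinically expected direction per predictor", {
  cs <- smart2_coefficients()
  base <- full_record()
  r0 <- predict_risk(base, cs, "europe_low", 10)$risk
  expect_gt(predict_risk(full_record(age = 75), cs)$risk, r0)
  expect_gt(predict_risk(full_record(current_smoking = 1), cs)$risk, r0)
  expect_gt(predict_risk(full_record(non_hdl = 5.5), cs)$risk, r0)
  expect_gt(predict_risk(full_record(hscrp = 8), cs)$risk, r0)
  expect_lt(predict_risk(full_record(egfr = 95), cs)$risk, r0)
  expect_true(r0 > 0 && r0 < 1)
})

test_that("batch prediction preserves order and matches a per-record loop", {
  cs <- smart2_coefficients()
  coh <- generate_covariates(200, seed = 31)
  risks <- batch_predict(coh, cs, "europe_low", 10)
  loop <- vapply(seq_len(nrow(coh)), function(i)
    predict_risk(coh[i, , drop = FALSE], cs, "europe_low", 10)$risk, 0)
  expect_equal(as.numeric(risks), loop, tolerance = 1e-12)
  expect_equal(mean(as.numeric(risks)), attr(risks, "summary")$mean,
               tolerance = 1e-12)

  perm <- sample(nrow(coh))
  risks_p <- batch_predict(coh[perm, ], cs, "europe_low", 10)
  expect_equal(as.numeric(risks_p), as.numeric(risks)[perm], tolerance = 1e-12)

  expect_warning(empty <- batch_predict(coh[0, ], cs), "empty")
  expect_length(empty, 0)
})

test_that("record-level failures are collected, not raised", {
  cs <- toy_coefset()
  df <- data.frame(age = c(60, NA, 70), hscrp = c(2, 3, 4),
                   antithrombotic_use = c(0, 0, 0))
  risks <- batch_predict(df, cs, "europe_low", 10)
  expect_true(is.na(risks[2]))
  expect_true(is.finite(risks[1]) && is.finite(risks[3]))
})
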