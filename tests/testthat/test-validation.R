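test_that("Aalen-Johansen matches the hand oracle and reduces to 1 - KM", {
  fx <- fixture_suite()$aj6
  for (h in c(1, 3.5, 4, 6)) {
    aj <- suppressWarnings(aalen_johansen(fx$data, h))
    expect_equal(aj$estimate, unname(fx$oracle$cif_at[[as.character(h)]]),
                 tolerance = 1e-12)
    expect_equal(aj$estimate, bf_aj_cif(fx$data$time, fx$data$cause, h),
                 tolerance = 1e-12)
  }

  # no competing events: CIF = 1 - KM at every event time
  d <- rand_crisk_data(120, 51)
  keep <- d$cause != 2
  df <- data.frame(time = d$time[keep], cause = d$cause[keep])
  km <- survival::survfit(survival::Surv(time, cause == 1) ~ 1, data = df)
  for (h in stats::quantile(df$time[df$cause == 1], c(.2, .5, .9))) {
    aj <- aalen_johansen(df, h)
    i <- findInterval(h, km$time)
    expect_equal(aj$estimate, 1 - km$surv[i], tolerance = 1e-12)
  }

  # conservation: cause-1 + cause-2 + event-free survival = 1
  d2 <- rand_crisk_data(150, 52)
  aj2 <- aalen_johansen(data.frame(time = d2$time, cause = d2$cause), 5)
  with(aj2$curve, expect_equal(cif + cif_death + surv, rep(1, length(cif)),
                               tolerance = 1e-12))

  # horizon before the first event
  expect_warning(aj0 <- aalen_johansen(fx$data, 0.5), "precedes")
  expect_equal(aj0$estimate, 0)
})

test_that("discrimination equals exhaustive pair counting on small data", {
  # uncensored <= 12 subjects: plain pair-count equivalence
  set.seed(61)
  risks <- runif(12)
  d <- rand_crisk_data(12, 61)
  # remove censoring to make the pair count transparent
  cause <- ifelse(d$cause == 0, 1, d$cause)
  out <- data.frame(time = d$time, cause = cause)
  expect_equal(cumulative_cstat(risks, out, 6)$estimate,
               bf_cumulative_c(risks, out$time, out$cause, 6),
               tolerance = 1e-12)
  expect_equal(incident_auc(risks, out, 6)$estimate,
               bf_incident_c(risks, out$time, out$cause, 6),
               tolerance = 1e-12)

  # censored instances against the same oracles
  for (seed in c(62, 63)) {
    dd <- rand_crisk_data(12, seed)
    rr <- stats::runif(12)
    oo <- data.frame(time = dd$time, cause = dd$cause)
    expect_equal(cumulative_cstat(rr, oo, 5)$estimate,
                 bf_cumulative_c(rr, oo$time, oo$cause, 5), tolerance = 1e-10)
    expect_equal(incident_auc(rr, oo, 5)$estimate,
                 bf_incident_c(rr, oo$time, oo$cause, 5), tolerance = 1e-10)
  }
})

test_that("discrimination boundary and invariance properties hold", {
  d <- rand_crisk_data(80, 71)
  out <- data.frame(time = d$time, cause = d$cause)
  const <- rep(0.3, 80)
  expect_equal(cumulative_cstat(const, out, 5)$estimate, 0.5)
  expect_equal(incident_auc(const, out, 5)$estimate, 0.5)

  risks <- stats::runif(80)
  a <- cumulative_cstat(risks, out, 5)$estimate
  b <- cumulative_cstat(stats::plogis(5 * risks - 2), out, 5)$estimate
  expect_equal(a, b, tolerance = 1e-12)
  ia <- incident_auc(risks, out, 5)$estimate
  ib <- incident_auc(risks^3, out, 5)$estimate
  expect_equal(ia, ib, tolerance = 1e-12)

  # perfect separation
  out2 <- data.frame(time = c(1, 2, 3, 11, 12, 13, 14),
                     cause = c(1, 1, 1, 0, 0, 0, 0))
  r2 <- c(.9, .8, .7, .1, .2, .3, .05)
  expect_equal(cumulative_cstat(r2, out2, 10)$estimate, 1)

  # single event time: incident-integrated equals cumulative
  out3 <- data.frame(time = c(2, 2, 2, 11, 11, 12, 13),
                     cause = c(1, 1, 1, 0, 0, 0, 0))
  r3 <- c(.8, .6, .3, .4, .2, .1, .5)
  expect_equal(incident_auc(r3, out3, 10)$estimate,
               cumulative_cstat(r3, out3, 10)$estimate, tolerance = 1e-12)

  no_cases <- data.frame(time = rep(c(11, 12), length.out = 7),
                         cause = rep(0, 7))
  expect_error(cumulative_cstat(r3, no_cases, 10), "undefined")
})

test_that("octile calibration partitions the cohort and is replication-invariant", {
  set.seed(81)
  coh <- simulate_cohort(400, seed = 81)
  risks <- batch_predict(coh, smart2_coefficients(), "europe_low", 10)
  tab <- calibration_octiles(as.numeric(risks), coh, 10)
  expect_equal(nrow(tab$bins), 8L)
  expect_equal(sum(tab$bins$n), 400L)
  expect_true(all(diff(tab$bins$mean_predicted) >= 0))

  # doubled data: identical observed incidences
  idx <- rep(seq_len(400), each = 2)
  tab2 <- calibration_octiles(as.numeric(risks)[idx],
                              as.data.frame(coh)[idx, c("time", "cause")], 10)
  expect_equal(tab2$bins$observed, tab$bins$observed, tolerance = 1e-12)
  expect_equal(tab2$bins$mean_predicted, tab$bins$mean_predicted,
               tolerance = 1e-12)

  # degenerate risks collapse with a warning
  expect_warning(tab3 <- calibration_octiles(rep(0.2, 400), coh, 10),
                 "collapsed")
  expect_equal(nrow(tab3$bins), 1L)
})

test_that("a well-calibrated model tracks observed incidence across octiles", {
  coh <- simulate_cohort(20000, seed = 82)
  prof <- generator_profile()
  # risks from the generating model itself
  lp <- smart2risk:::profile_linear_predictor(coh, prof)
  H0 <- -log(1 - prof$baseline$p * (1 - exp(-prof$baseline$lambda * 10)))
  risks <- 1 - exp(-H0 * exp(lp))
  tab <- calibration_octiles(risks, coh, 10)
  gap <- abs(tab$bins$mean_predicted - tab$bins$observed)
  expect_gte(sum(gap < 0.02), 7L)
  expect_equal(tab$eo_ratio, 1, tolerance = 0.05)
})

test_that("calibration slope is 1 for the true model and scales inversely", {
  coh <- simulate_cohort(4000, seed = 83)
  lp <- smart2risk:::profile_linear_predictor(coh, generator_profile())
  s1 <- calibration_slope(lp, coh)
  expect_equal(s1$slope, 1, tolerance = 0.1)
  s2 <- calibration_slope(2 * lp, coh)
  expect_equal(s2$slope, s1$slope / 2, tolerance = 1e-6)
  expect_error(calibration_slope(rep(1, nrow(coh)), coh), "variance")
})

test_that("out-of-sample evaluation of an overfitted model shrinks the slope", {
  shrunk <- 0L
  reps <- 60
  spec <- model_spec(c("x1", "x2", "x3"))
  for (s in seq_len(reps)) {
    set.seed(900 + s)
    gen <- function(n) {
      X <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("x1", "x2", "x3")))
      t1 <- stats::rexp(n, 0.2 * exp(0.3 * X[, 1]))
      t2 <- stats::rexp(n, 0.08)
      cc <- stats::runif(n, 1, 10)
      data.frame(time = pmin(t1, t2, cc),
                 cause = ifelse(t1 <= pmin(t2, cc), 1,
                                ifelse(t2 <= cc, 2, 0)), X)
    }
    train <- gen(70); test <- gen(300)
    eng <- tryCatch(
      smart2risk:::fg_engine(train$time, train$cause,
                             as.matrix(train[c("x1", "x2", "x3")])),
      error = function(e) NULL)
    if (is.null(eng) || !eng$converged) next
    lp_new <- as.matrix(test[c("x1", "x2", "x3")]) %*% eng$coefficients
    sl <- tryCatch(calibration_slope(as.vector(lp_new), test),
                   error = function(e) NULL)
    if (is.null(sl)) next
    shrunk <- shrunk + (sl$slope < 1)
  }
  expect_gte(shrunk / reps, 0.9)
})

test_that("cross-validation is deterministic and pessimistic relative to apparent fit", {
  coh <- simulate_cohort(700, seed = 91)
  cv1 <- crossvalidate(coh, k = 5, seed = 7, horizon = 10)
  cv2 <- crossvalidate(coh, k = 5, seed = 7, horizon = 10)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$cstat$estimate, cv2$cstat$estimate, tolerance = 1e-12)
  expect_equal(cv1$slope$slope, cv2$slope$slope, tolerance = 1e-12)

  # optimism: mean CV C <= mean apparent C over replicates (small cohorts)
  diffs <- numeric(0)
  spec3 <- model_spec(c("x1", "x2"))
  for (s in 1:25) {
    d <- rand_crisk_data(220, 1200 + s, p_cov = 2)
    df <- d$df
    fit <- smart2risk:::fg_engine(df$time, df$cause, d$X)
    lp_app <- as.vector(d$X %*% fit$coefficients)
    app <- cumulative_cstat(lp_app, df, 6)$estimate
    cv <- tryCatch({
      folds <- integer(220)
      set.seed(s)
      for (cz in unique(df$cause)) {
        idx <- which(df$cause == cz)
        folds[idx] <- sample(rep_len(1:5, length(idx)))
      }
      lp_oof <- numeric(220)
      for (f in 1:5) {
        eng <- smart2risk:::fg_engine(df$time[folds != f],
                                      df$cause[folds != f],
                                      d$X[folds != f, , drop = FALSE])
        lp_oof[folds == f] <- d$X[folds == f, , drop = FALSE] %*%
          eng$coefficients
      }
      cumulative_cstat(lp_oof, df, 6)$estimate
    }, error = function(e) NA_real_)
    if (is.finite(cv)) diffs <- c(diffs, app - cv)
  }
  expect_gt(mean(diffs), 0)
})

test_that("random-effects pooling behaves at its boundary cases", {
  one <- structure(
    list(estimate = 0.7, variant = "cumulative", horizon = 10, se = 0.02,
         ci = c(0.66, 0.74), n = 100, events = 30),
    class = "discrimination_result")
  expect_warning(p1 <- meta_pool(list(one)), "prediction interval")
  expect_equal(p1$pooled, 0.7)
  expect_equal(p1$prediction_interval, p1$ci)

  same <- replicate(4, one, simplify = FALSE)
  p2 <- meta_pool(same)
  expect_equal(p2$tau2, 0)
  expect_equal(p2$pooled, 0.7)
  expect_true(p2$prediction_interval[1] <= p2$ci[1] &&
                p2$prediction_interval[2] >= p2$ci[2])

  # heterogeneous studies: agreement with the reference implementation
  yi <- c(0.64, 0.70, 0.74, 0.68)
  sei <- c(0.02, 0.03, 0.025, 0.015)
  df <- data.frame(estimate = yi, se = sei, horizon = 10)
  ours <- meta_pool(df)
  ref <- metafor::rma(yi = yi, sei = sei, method = "DL")
  expect_equal(ours$pooled, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
})

test_that("the DL tau-squared estimator recovers known heterogeneity", {
  set.seed(1001)
  tau2_true <- 0.01
  est <- replicate(300, {
    k <- 3
    yi <- 0.7 + stats::rnorm(k, 0, sqrt(tau2_true)) +
      stats::rnorm(k, 0, 0.02)
    meta_pool(data.frame(estimate = yi, se = rep(0.02, k), horizon = 10))$tau2
  })
  expect_lt(abs(mean(est) - tau2_true), 0.004)
})
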