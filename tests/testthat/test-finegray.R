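test_that("censoring weights are 1 without censoring and match hand KM ratios", {
  d <- data.frame(time = c(1, 2, 3, 4), cause = c(1, 2, 1, 2))
  w <- censoring_weights(d)
  W <- w$weight_matrix()
  expect_true(all(W[d$time >= 1, 1] == 1))
  expect_true(all(W %in% c(0, 1)))       # no censoring: weights 0/1 only

  fx <- fixture_suite()$aj6
  w6 <- censoring_weights(fx$data)
  expect_equal(w6$Gminus(2.9), fx$oracle$G_at[["2.9"]])
  expect_equal(w6$Gminus(3.000001), fx$oracle$G_at[["3"]])
  expect_equal(w6$Gminus(5.9), fx$oracle$G_at[["5.9"]])
  W6 <- w6$weight_matrix()                # columns at event times 1, 4
  expect_equal(unname(W6[2, 2]), fx$oracle$w_comp2_at4)  # t=2 death at t=4
  expect_equal(unname(w6$weight_matrix(5.5)[5, 1]),
               fx$oracle$w_comp5_at5.5)
})

test_that("weights and G are invariant to record replication", {
  fx <- fixture_suite()$aj6$data
  w1 <- censoring_weights(fx)
  w2 <- censoring_weights(rbind(fx, fx))
  tt <- c(0.5, 1, 2.5, 3.5, 4, 5.5)
  expect_equal(w1$Gminus(tt), w2$Gminus(tt))
  expect_equal(w1$weight_matrix(), w2$weight_matrix()[seq_len(nrow(fx)), ])
})

test_that("Newton-Raphson matches the brute-force likelihood oracle", {
  fx <- fixture_suite()$lik12
  eng <- smart2risk:::fg_engine(fx$data$time, fx$data$cause,
                                cbind(x = fx$data$x))
  expect_equal(unname(eng$coefficients), fx$oracle$coefficient,
               tolerance = 1e-4)
  expect_true(eng$converged)

  # property loop: random <= 15-record, 1-2 covariate instances
  for (seed in c(21, 22, 23)) {
    d <- rand_crisk_data(13, seed, p_cov = 1)
    eng1 <- smart2risk:::fg_engine(d$time, d$cause, d$X)
    expect_equal(unname(eng1$coefficients),
                 bf_fg_maximize(d$time, d$cause, d$X), tolerance = 1e-4)
  }
  d2 <- rand_crisk_data(15, 31, p_cov = 2)
  eng2 <- smart2risk:::fg_engine(d2$time, d2$cause, d2$X)
  expect_equal(unname(eng2$coefficients),
               unname(bf_fg_maximize(d2$time, d2$cause, d2$X)),
               tolerance = 1e-4)
})

test_that("offsets enter as fixed terms and shift the estimate accordingly", {
  d <- rand_crisk_data(120, 5, p_cov = 2)
  off <- 0.5 * d$X[, 2]
  eng_off <- smart2risk:::fg_engine(d$time, d$cause, d$X[, 1, drop = FALSE],
                                    offset = off)
  b_bf <- bf_fg_maximize(d$time, d$cause, d$X[, 1, drop = FALSE],
                         offset = off)
  expect_equal(unname(eng_off$coefficients), b_bf, tolerance = 1e-4)
})

test_that("null-model predicted CIF equals Aalen-Johansen at every event time", {
  d <- rand_crisk_data(80, 8)
  eng0 <- smart2risk:::fg_engine(d$time, d$cause, NULL)
  cif <- 1 - exp(-eng0$baseline$cumhaz)
  aj <- vapply(eng0$baseline$time, function(h)
    bf_aj_cif(d$time, d$cause, h), 0)
  expect_equal(cif, aj, tolerance = 1e-12)
})

test_that("with no competing events the fit reduces to a Breslow Cox model", {
  d <- rand_crisk_data(150, 9, p_cov = 2)
  keep <- d$cause != 2
  df <- data.frame(time = d$time[keep], status = d$cause[keep] == 1,
                   d$X[keep, ])
  eng <- smart2risk:::fg_engine(df$time, ifelse(df$status, 1, 0),
                                as.matrix(df[c("x1", "x2")]))
  cph <- survival::coxph(survival::Surv(time, status) ~ x1 + x2, data = df,
                         ties = "breslow", control =
                           survival::coxph.control(eps = 1e-10, iter.max = 50))
  expect_lt(max(abs(unname(eng$coefficients) - unname(coef(cph)))), 1e-8)
})

test_that("coefficients agree with the independent cmprsk implementation", {
  d <- rand_crisk_data(250, 12, p_cov = 2)
  eng <- smart2risk:::fg_engine(d$time, d$cause, d$X)
  cr <- cmprsk::crr(d$time, d$cause, d$X)
  expect_equal(unname(eng$coefficients), unname(cr$coef), tolerance = 1e-5)
})

test_that("time scaling and covariate shifts leave coefficients unchanged", {
  d <- rand_crisk_data(100, 14, p_cov = 2)
  eng <- smart2risk:::fg_engine(d$time, d$cause, d$X)
  eng_t <- smart2risk:::fg_engine(d$time * 3.7, d$cause, d$X)
  expect_lt(max(abs(eng$coefficients - eng_t$coefficients)), 1e-8)
  eng_s <- smart2risk:::fg_engine(d$time, d$cause, sweep(d$X, 2, c(5, -2)))
  expect_equal(eng$coefficients, eng_s$coefficients, tolerance = 1e-7)
})

test_that("collinear designs raise an error naming the offending term", {
  d <- rand_crisk_data(50, 15, p_cov = 1)
  X <- cbind(a = d$X[, 1], b = 2 * d$X[, 1])
  expect_error(smart2risk:::fg_engine(d$time, d$cause, X), "collinear")
})

test_that("fit_fine_gray on a cohort exposes the full interface", {
  coh <- simulate_cohort(600, seed = 44)
  fit <- fit_fine_gray(coh)
  expect_s3_class(fit, "fine_gray_fit")
  expect_true(fit$converged)
  expect_equal(length(fit$coefficients), 13L)
  # covariance symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-10)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  # baseline cumulative hazard non-decreasing from 0
  expect_true(all(diff(fit$baseline_cumhaz$cumhaz) >= 0))
  expect_gt(fit$baseline_cumhaz$cumhaz[1], 0)
  # summary table and export
  tab <- summary(fit)
  expect_true(all(c("term", "shr", "lower95", "upper95", "p") %in% names(tab)))
  out <- tempfile()
  export_fit_summary(fit, out)
  expect_true(file.exists(paste0(out, ".txt")))
  expect_true(file.exists(paste0(out, ".json")))
})

test_that("predict_cif honours the step baseline and the offset ratio", {
  coh <- simulate_cohort(800, seed = 45)
  fit <- fit_fine_gray(coh)
  rec <- full_record(antithrombotic_use = 0)
  r0 <- predict_cif(fit, rec, 8)
  rec1 <- full_record(antithrombotic_use = 1)
  r1 <- predict_cif(fit, rec1, 8)
  expect_equal(log(1 - r1) / log(1 - r0), 0.81, tolerance = 1e-12)
  expect_error(predict_cif(fit, rec, max(coh$time) + 5), "beyond")

  # record at the centering means with no offset reproduces the baseline
  mu <- fit$centering_means
  rec_mu <- data.frame(age = mu[["age"]], sex = mu[["sex"]],
                       current_smoking = mu[["current_smoking"]],
                       systolic_bp = mu[["systolic_bp"]],
                       non_hdl = exp(mu[["non_hdl"]]),
                       diabetes = mu[["diabetes"]], cad = mu[["cad"]],
                       cevd = mu[["cevd"]], pad = mu[["pad"]],
                       aaa = mu[["aaa"]],
                       years_since_first_ascvd =
                         sqrt(mu[["years_since_first_ascvd"]]),
                       egfr = sqrt(mu[["egfr"]]),
                       hscrp = exp(mu[["hscrp"]]),
                       antithrombotic_use = 0)
  bl <- fit$baseline_cumhaz
  h <- bl$time[length(bl$time) %/% 2]
  expect_equal(predict_cif(fit, rec_mu, h),
               1 - exp(-bl$cumhaz[length(bl$time) %/% 2]), tolerance = 1e-10)
})

test_that("parameter recovery holds on simulated data from known coefficients", {
  reps <- 12
  hits <- 0L; total <- 0L
  for (s in seq_len(reps)) {
    set.seed(700 + s)
    n <- 1500
    x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.4)
    eta <- 0.5 * x1 - 0.4 * x2
    p <- 0.4; lam <- 0.15
    ee <- exp(eta)
    pi1 <- 1 - (1 - p)^ee
    is1 <- stats::runif(n) < pi1
    Fv <- stats::runif(n)[is1] * pi1[is1]
    tt <- numeric(n)
    tt[is1] <- -log(1 - (1 - (1 - Fv)^(1 / ee[is1])) / p) / lam
    tt[!is1] <- stats::rexp(sum(!is1), 0.08)
    cens <- stats::runif(n, 2, 14)
    time <- pmin(tt, cens)
    cause <- ifelse(tt <= cens, ifelse(is1, 1, 2), 0)
    eng <- smart2risk:::fg_engine(time, cause, cbind(x1 = x1, x2 = x2))
    se <- sqrt(diag(eng$vcov))
    hits <- hits + sum(abs(eng$coefficients - c(0.5, -0.4)) < 3 * se)
    total <- total + 2L
  }
  expect_gte(hits / total, 0.95)
})
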