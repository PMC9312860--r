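# Frozen default constants of the synthetic derivation profile. The per-unit
# coefficients convert the published quartile-contrast subdistribution hazard
# ratios (age 1.61, SBP 1.02 per 10 mmHg, non-HDL 1.28, years-since 1.18,
# eGFR 0.87, hsCRP 1.25; binary predictors direct) to the transformed scale
# using the default profile's quartiles; centering means are the profile
# means of the transformed terms. Event-model constants are calibrated once
# so that the default profile reproduces the derivation cohort's event
# profile (~1706 ASCVD events and ~978 non-CVD deaths among n = 8355 over a
# median 8.2 years of follow-up). See the methods vignette.
.smart2_defaults <- list(
  coefficients = c(
    age = 0.040440150,
    sex = log(1.33),
    current_smoking = log(1.41),
    systolic_bp = 0.0019802627,
    non_hdl = 0.53809943,
    diabetes = log(1.37),
    cad = log(1.34),
    cevd = log(1.42),
    pad = log(1.25),
    aaa = log(1.39),
    years_since_first_ascvd = 0.015420709,
    egfr = -3.7254169e-05,
    hscrp = 0.15117899
  ),
  centering_means = c(
    age = 60.850789,
    sex = 0.74,
    current_smoking = 0.30,
    systolic_bp = 139.12142,
    non_hdl = 1.1933807,        # mean of log(non-HDL)
    diabetes = 0.18,
    cad = 0.62,
    cevd = 0.29,
    pad = 0.17,
    aaa = 0.08,
    years_since_first_ascvd = 13.360105,  # mean of years^2
    egfr = 6252.3852,                      # mean of eGFR^2
    hscrp = 0.69738021                     # mean of log(hsCRP)
  ),
  baseline = list(p = 0.355, lambda = 0.08),
  competing_rate = 0.0172,
  censoring = list(fu_min = 2.5, fu_max = 21, dropout_rate = 0.004)
)

#' Default synthetic derivation-cohort generator profile
#'
#' Covariate marginals emulate the derivation population (age 61 +/- 9
#' truncated to 40-80, 74% male, 30% current smokers, SBP 139 +/- 20, 18%
#' diabetes, disease territories CAD 62% / CeVD 29% / PAD 17% / AAA 8% with
#' at least one guaranteed by construction, eGFR 77 +/- 18, hsCRP
#' log-normal with median 2.0 and IQR 1.0-4.4, 78% antithrombotic use).
#' Continuous marginals whose derivation distributions are not public
#' (non-HDL cholesterol, years since first ASCVD diagnosis) use log-normal
#' forms chosen once for the package (see the methods vignette). A Gaussian
#' copula ties age to eGFR (rho -0.4) and to years since diagnosis
#' (rho +0.2); all other covariates are independent. Cause-1 event times
#' follow the Fine-Gray subdistribution
#' `F1(t|X) = 1 - (1 - p(1 - exp(-lambda t)))^exp(eta)` (mass-at-infinity
#' construction), the competing non-CVD death time is exponential, and
#' censoring combines a uniform administrative follow-up window with
#' exponential dropout, together tuned to the derivation follow-up profile
#' (median ~8.2 y, IQR ~4.2-12.5).
#'
#' @param ... overrides for any profile element (see the function body for
#'   the element names; every element is a plain R value, so a profile is
#'   fully serializable and `(profile, seed)` reproduces a dataset).
#' @return object of class `generator_profile`.
#' @export
generator_profile <- function(...) {
  d <- .smart2_defaults
  prof <- list(
    age = list(mean = 61, sd = 9, lo = 40, hi = 80),
    systolic_bp = list(mean = 139, sd = 20, lo = 80, hi = 250),
    egfr = list(mean = 77, sd = 18, lo = 15, hi = 150),
    non_hdl = list(meanlog = log(3.3), sdlog = 0.34, lo = 0.5, hi = 12),
    hscrp = list(meanlog = log(2.0), sdlog = 1.10, lo = 0.1, hi = 50),
    years_since_first_ascvd = list(meanlog = log(1.8), sdlog = 1.0,
                                   lo = 0, hi = 15),
    p_male = 0.74, p_smoking = 0.30, p_diabetes = 0.18,
    p_antithrombotic = 0.78,
    p_territories = c(cad = 0.62, cevd = 0.29, pad = 0.17, aaa = 0.08),
    cor_age_egfr = -0.4, cor_age_years = 0.2,
    coefficients = d$coefficients,
    centering_means = d$centering_means,
    offset_hr = 0.81,
    baseline = d$baseline,
    competing_rate = d$competing_rate,
    censoring = d$censoring,
    version = "1"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(prof))
  if (length(unknown)) stop("unknown profile element(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  prof[names(dots)] <- dots
  for (f in c("coefficients", "centering_means", "p_territories")) {
    prof[[f]] <- unlist(prof[[f]])
  }
  if (is.null(names(prof$p_territories))) {
    names(prof$p_territories) <- c("cad", "cevd", "pad", "aaa")
  }
  for (f in c("baseline", "censoring")) prof[[f]] <- as.list(prof[[f]])
  validate_profile(prof)
  structure(prof, class = "generator_profile")
}

validate_profile <- function(p) {
  probs <- c(p$p_male, p$p_smoking, p$p_diabetes, p$p_antithrombotic,
             p$p_territories)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]",
                                       call. = FALSE)
  if (all(p$p_territories <= 0)) {
    stop("profile error: all disease-territory probabilities are zero",
         call. = FALSE)
  }
  for (v in c("age", "systolic_bp", "egfr")) {
    if (p[[v]]$sd < 0) stop(v, ": dispersion must be >= 0", call. = FALSE)
  }
  for (v in c("non_hdl", "hscrp", "years_since_first_ascvd")) {
    if (p[[v]]$sdlog < 0) stop(v, ": dispersion must be >= 0", call. = FALSE)
  }
  bp <- p$baseline
  if (bp$p <= 0 || bp$p >= 1) {
    stop("profile error: baseline subdistribution mass p must lie in (0,1)",
         call. = FALSE)
  }
  if (bp$lambda <= 0 || p$competing_rate <= 0) {
    stop("rates must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.generator_profile <- function(x, ...) {
  cat("Synthetic derivation-cohort generator profile (version", x$version, ")\n")
  cat(sprintf("  baseline F1(t|0) = %.3g (1 - exp(-%.3g t)); competing rate %.3g; dropout %.3g over follow-up window [%.3g, %.3g] y\n",
              x$baseline$p, x$baseline$lambda, x$competing_rate,
              x$censoring$dropout_rate, x$censoring$fu_min, x$censoring$fu_max))
  invisible(x)
}

#' Save / load a generator profile
#'
#' Versioned JSON documents; `(profile, seed)` fully reproduces a dataset.
#' @param profile a [generator_profile()].
#' @param path JSON file path.
#' @export
save_generator_profile <- function(profile, path) {
  doc <- c(list(format = "smart2risk/generator-profile"),
           unclass(profile))
  # named vectors must become JSON objects, not bare arrays
  for (f in c("coefficients", "centering_means", "p_territories")) {
    doc[[f]] <- as.list(doc[[f]])
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_generator_profile
#' @export
load_generator_profile <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "smart2risk/generator-profile")) {
    stop("not a generator-profile document", call. = FALSE)
  }
  doc$format <- NULL
  do.call(generator_profile, doc)
}

# quantile samplers for truncated marginals (sd 0 collapses to the location)
qtrunc_norm <- function(u, spec) {
  if (spec$sd == 0) return(rep(spec$mean, length(u)))
  plo <- stats::pnorm(spec$lo, spec$mean, spec$sd)
  phi <- stats::pnorm(spec$hi, spec$mean, spec$sd)
  stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
}
qtrunc_lnorm <- function(u, spec) {
  if (spec$sdlog == 0) return(rep(exp(spec$meanlog), length(u)))
  plo <- stats::plnorm(spec$lo, spec$meanlog, spec$sdlog)
  phi <- stats::plnorm(spec$hi, spec$meanlog, spec$sdlog)
  stats::qlnorm(plo + u * (phi - plo), spec$meanlog, spec$sdlog)
}

# Deflate independent territory probabilities so that after forcing one
# territory on no-disease draws the marginals match the targets.
territory_internal_probs <- function(targ) {
  qv <- pmin(pmax(targ, 0), 0.999)
  active <- targ > 0
  for (i in 1:200) {
    pnone <- prod(1 - qv[active])
    share <- ifelse(active, qv / sum(qv[active]), 0)
    marg <- qv + pnone * share
    qv <- pmax(qv - (marg - targ), ifelse(active, 1e-4, 0))
  }
  qv
}

#' Generate a synthetic covariate cohort
#'
#' Deterministic given `(profile, seed)`: marginals match the profile
#' within sampling error and every record carries at least one established
#' disease territory by construction.
#'
#' @param n number of patients.
#' @param profile a [generator_profile()].
#' @param seed integer seed.
#' @return an [ascvd_cohort()] without outcome columns (a data.frame of
#'   predictors).
#' @export
generate_covariates <- function(n, profile = generator_profile(), seed = 1) {
  stopifnot(n >= 1)
  validate_profile(profile)
  set.seed(seed)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- profile$cor_age_egfr
  R[1, 3] <- R[3, 1] <- profile$cor_age_years
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  U <- stats::pnorm(Z)

  df <- data.frame(
    age = qtrunc_norm(U[, 1], profile$age),
    egfr = qtrunc_norm(U[, 2], profile$egfr),
    years_since_first_ascvd = qtrunc_lnorm(U[, 3],
                                           profile$years_since_first_ascvd),
    systolic_bp = qtrunc_norm(stats::runif(n), profile$systolic_bp),
    non_hdl = qtrunc_lnorm(stats::runif(n), profile$non_hdl),
    hscrp = qtrunc_lnorm(stats::runif(n), profile$hscrp),
    sex = stats::rbinom(n, 1, profile$p_male),
    current_smoking = stats::rbinom(n, 1, profile$p_smoking),
    diabetes = stats::rbinom(n, 1, profile$p_diabetes),
    antithrombotic_use = stats::rbinom(n, 1, profile$p_antithrombotic)
  )
  qv <- territory_internal_probs(profile$p_territories)
  terr <- matrix(0L, n, length(qv),
                 dimnames = list(NULL, names(profile$p_territories)))
  for (j in seq_along(qv)) terr[, j] <- stats::rbinom(n, 1, qv[j])
  none <- rowSums(terr) == 0
  if (any(none)) {
    active <- which(qv > 0)
    pick <- active[sample.int(length(active), sum(none), replace = TRUE,
                              prob = qv[active])]
    terr[cbind(which(none), pick)] <- 1
  }
  df$cad <- terr[, "cad"]; df$cevd <- terr[, "cevd"]
  df$pad <- terr[, "pad"]; df$aaa <- terr[, "aaa"]
  class(df) <- c("ascvd_cohort", "data.frame")
  attr(df, "label") <- sprintf("synthetic (seed %d)", seed)
  df
}

# True linear predictor (offset included, uncentered offset) of a profile.
profile_linear_predictor <- function(cohort, profile) {
  spec <- smart2_model_spec(profile$offset_hr)
  Z <- build_terms(as.data.frame(cohort), spec)
  Xc <- sweep(Z, 2L, profile$centering_means[colnames(Z)], `-`)
  as.vector(Xc %*% profile$coefficients[colnames(Z)]) +
    log(profile$offset_hr) * as.numeric(cohort$antithrombotic_use)
}

#' Simulate competing-risk outcomes for a covariate cohort
#'
#' Cause-1 (ASCVD) event times are drawn from the Fine-Gray subdistribution
#' `F1(t|X) = 1 - (1 - p(1 - exp(-lambda t)))^exp(eta)` via the
#' mass-at-infinity construction, so the generated data satisfy exactly the
#' model the estimation engine fits. Conditional on not experiencing the
#' ASCVD event, the non-CVD death time is exponential. Censoring is the
#' minimum of a uniform administrative follow-up time and exponential
#' dropout.
#'
#' @param cohort covariate cohort from [generate_covariates()].
#' @param profile the same [generator_profile()].
#' @param seed optional integer seed (omit to continue the current RNG
#'   stream).
#' @return the cohort with `time` and `cause` columns appended.
#' @export
simulate_outcomes <- function(cohort, profile = generator_profile(),
                              seed = NULL) {
  validate_profile(profile)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  p <- profile$baseline$p; lam <- profile$baseline$lambda
  eta <- profile_linear_predictor(cohort, profile)
  ee <- exp(eta)
  pi1 <- 1 - (1 - p)^ee
  is1 <- stats::runif(n) < pi1
  Tev <- numeric(n)
  # cause-1: invert the conditional subdistribution
  V <- stats::runif(n)
  Fv <- V[is1] * pi1[is1]
  arg <- 1 - (1 - (1 - Fv)^(1 / ee[is1])) / p
  Tev[is1] <- -log(pmax(arg, 1e-15)) / lam
  Tev[!is1] <- stats::rexp(sum(!is1), rate = profile$competing_rate)
  cens <- pmin(
    stats::runif(n, profile$censoring$fu_min, profile$censoring$fu_max),
    stats::rexp(n, rate = profile$censoring$dropout_rate)
  )
  time <- pmin(Tev, cens)
  cause <- ifelse(Tev <= cens, ifelse(is1, 1L, 2L), 0L)
  out <- as.data.frame(cohort)
  out$time <- pmax(time, 1e-6)
  out$cause <- cause
  class(out) <- c("ascvd_cohort", "data.frame")
  attr(out, "label") <- attr(cohort, "label")
  out
}

#' Simulate a complete synthetic derivation-style cohort
#'
#' Covariates plus outcomes in one deterministic call.
#'
#' @inheritParams generate_covariates
#' @return an [ascvd_cohort()] with `time` and `cause`.
#' @export
simulate_cohort <- function(n = 8355, profile = generator_profile(),
                            seed = 1) {
  cov <- generate_covariates(n, profile, seed)
  simulate_outcomes(cov, profile)
}
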