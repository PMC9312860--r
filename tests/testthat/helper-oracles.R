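# Independent brute-force oracles, deliberately written as naive double
# loops so they share no code path with the package implementations.

# Left-continuous censoring Kaplan-Meier, G(t-).
bf_Gminus <- function(time, cause) {
  function(t) {
    g <- 1
    for (u in sort(unique(time[cause == 0]))) {
      if (u < t) g <- g * (1 - sum(time == u & cause == 0) / sum(time >= u))
    }
    g
  }
}

# Risk-set weight matrix (events by subjects), built by the naive
# definition; it does not depend on the coefficients, so the likelihood
# below can reuse it across a grid search.
bf_fg_weights <- function(time, cause) {
  Gm <- bf_Gminus(time, cause)
  ev <- which(cause == 1)
  W <- matrix(0, length(ev), length(time))
  for (k in seq_along(ev)) {
    ti <- time[ev[k]]
    for (j in seq_along(time)) {
      W[k, j] <- if (time[j] >= ti) 1
                 else if (cause[j] == 2) Gm(ti) / Gm(time[j]) else 0
    }
  }
  list(ev = ev, W = W)
}

# IPCW-weighted Fine-Gray partial log-likelihood, direct evaluation.
bf_fg_loglik <- function(beta, time, cause, X, offset = NULL, wts = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(offset)) offset <- numeric(n)
  if (is.null(wts)) wts <- bf_fg_weights(time, cause)
  eta <- as.vector(X %*% beta) + offset
  ll <- 0
  for (k in seq_along(wts$ev)) {
    denom <- 0
    for (j in seq_len(n)) denom <- denom + wts$W[k, j] * exp(eta[j])
    ll <- ll + eta[wts$ev[k]] - log(denom)
  }
  ll
}

# Grid + refinement maximizer for 1 or 2 coefficients.
bf_fg_maximize <- function(time, cause, X, offset = NULL) {
  X <- as.matrix(X)
  wts <- bf_fg_weights(time, cause)
  f <- function(b) bf_fg_loglik(b, time, cause, X, offset, wts)
  if (ncol(X) == 1L) {
    gr <- seq(-4, 4, 0.01)
    ll <- vapply(gr, f, 0)
    b0 <- gr[which.max(ll)]
    stats::optimize(f, c(b0 - 0.02, b0 + 0.02), maximum = TRUE,
                    tol = 1e-9)$maximum
  } else {
    gr <- as.matrix(expand.grid(seq(-3, 3, 0.1), seq(-3, 3, 0.1)))
    ll <- apply(gr, 1, f)
    b0 <- gr[which.max(ll), ]
    stats::optim(b0, function(b) -f(b), method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$par
  }
}

# Aalen-Johansen cause-1 CIF by the explicit product-sum recursion.
bf_aj_cif <- function(time, cause, horizon) {
  ut <- sort(unique(time[cause != 0]))
  S <- 1; cif <- 0
  for (u in ut) {
    if (u > horizon) break
    nrisk <- sum(time >= u)
    d1 <- sum(time == u & cause == 1)
    d2 <- sum(time == u & cause == 2)
    cif <- cif + S * d1 / nrisk
    S <- S * (1 - (d1 + d2) / nrisk)
  }
  cif
}

# Exhaustive weighted pair-count oracle for the cumulative/dynamic
# C-statistic at a horizon: cases are cause-1 events by the horizon
# (weight 1/G(t-)), controls are horizon survivors (weight 1/G(horizon-))
# and prior competing deaths (weight 1/G(t-)); ties in risk count half.
bf_cumulative_c <- function(risks, time, cause, horizon) {
  Gm <- bf_Gminus(time, cause)
  num <- 0; den <- 0
  for (i in seq_along(risks)) {
    if (!(cause[i] == 1 && time[i] <= horizon)) next
    a <- 1 / Gm(time[i])
    for (j in seq_along(risks)) {
      w <- if (time[j] > horizon) 1 / Gm(horizon)
           else if (cause[j] == 2 && time[j] <= horizon) 1 / Gm(time[j])
           else 0
      if (w <= 0) next
      conc <- if (risks[i] > risks[j]) 1 else if (risks[i] == risks[j]) 0.5 else 0
      num <- num + a * w * conc
      den <- den + a * w
    }
  }
  num / den
}

# Exhaustive oracle for the incident/dynamic integrated concordance: at
# each event time cases are the failures at that time, controls are later
# survivors (weight 1) plus prior competing deaths (weight G(t-)/G(s-));
# pair-count aggregation over event times.
bf_incident_c <- function(risks, time, cause, horizon) {
  Gm <- bf_Gminus(time, cause)
  num <- 0; den <- 0
  for (tk in sort(unique(time[cause == 1 & time <= horizon]))) {
    for (i in which(cause == 1 & time == tk)) {
      for (j in seq_along(risks)) {
        w <- if (time[j] > tk) 1
             else if (cause[j] == 2 && time[j] == tk) 1
             else if (cause[j] == 2 && time[j] < tk) Gm(tk) / Gm(time[j])
             else 0
        if (w <= 0) next
        conc <- if (risks[i] > risks[j]) 1 else if (risks[i] == risks[j]) 0.5 else 0
        num <- num + w * conc
        den <- den + w
      }
    }
  }
  num / den
}

# Small three-cause dataset generator for property loops (continuous times,
# so tie conventions never matter).
rand_crisk_data <- function(n, seed, p_cov = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p_cov), n, p_cov,
              dimnames = list(NULL, paste0("x", seq_len(p_cov))))
  t1 <- stats::rexp(n, 0.2 * exp(0.4 * X[, 1]))
  t2 <- stats::rexp(n, 0.1)
  cc <- stats::runif(n, 0.5, 8)
  time <- pmin(t1, t2, cc)
  cause <- ifelse(t1 <= pmin(t2, cc), 1L, ifelse(t2 <= cc, 2L, 0L))
  list(time = time, cause = cause, X = X,
       df = data.frame(time = time, cause = cause, X))
}

# A tiny transparent coefficient set for identity-style checks.
toy_coefset <- function(region_factors = list(europe_low = 1)) {
  coefficient_set(
    coefficients = c(age = 0.04, hscrp = 0.15),
    transforms = c(age = "identity", hscrp = "log"),
    centering_means = c(age = 60, hscrp = log(2)),
    baseline_survival = c(`2` = 0.97, `6` = 0.90, `10` = 0.80),
    offset_hr = 0.81,
    region_factors = region_factors,
    id = "toy"
  )
}

toy_record <- function(age = 65, hscrp = 3, antithrombotic_use = 0) {
  data.frame(age = age, hscrp = hscrp,
             antithrombotic_use = antithrombotic_use)
}

# Complete 13-predictor record at chosen values.
full_record <- function(...) {
  rec <- data.frame(age = 61, sex = 1, current_smoking = 0, systolic_bp = 139,
                    non_hdl = 3.3, diabetes = 0, cad = 1, cevd = 0, pad = 0,
                    aaa = 0, years_since_first_ascvd = 1.8, egfr = 77,
                    hscrp = 2.0, antithrombotic_use = 1)
  over <- list(...)
  rec[names(over)] <- over
  rec
}
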