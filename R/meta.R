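#' Random-effects pooling of cohort discrimination results
#'
#' DerSimonian-Laird random-effects meta-analysis of per-cohort estimates
#' (C-statistics or other approximately normal quantities): method-of-
#' moments between-cohort variance tau^2, inverse-variance random-effects
#' weights, a 95% confidence interval for the pooled mean, and a 95%
#' prediction interval using a t distribution with k-2 degrees of freedom
#' (k >= 3); with fewer cohorts the CI is reported as the prediction
#' interval with a warning.
#'
#' @param results list of `discrimination_result` objects, or a data.frame
#'   with columns `estimate` and `se`.
#' @return object of class `pooled_estimate`: `pooled`, `se`, `tau2`, `ci`,
#'   `prediction_interval`, `k`, and the per-cohort `inputs`.
#' @export
meta_pool <- function(results) {
  if (inherits(results, "discrimination_result")) results <- list(results)
  if (is.data.frame(results)) {
    yi <- results$estimate; sei <- results$se
    horizons <- results$horizon
  } else {
    if (length(results) == 0L) stop("empty input", call. = FALSE)
    yi <- vapply(results, function(r) r$estimate, numeric(1))
    sei <- vapply(results, function(r) r$se, numeric(1))
    horizons <- vapply(results, function(r)
      if (is.null(r$horizon)) NA_real_ else r$horizon, numeric(1))
  }
  k <- length(yi)
  if (any(!is.finite(sei)) || any(sei < 0)) {
    stop("non-finite standard errors", call. = FALSE)
  }
  if (length(unique(stats::na.omit(horizons))) > 1L) {
    warning("pooling results evaluated at different horizons")
  }
  vi <- sei^2
  if (k == 1L) {
    tau2 <- 0
    pooled <- yi[1]; se <- sei[1]
  } else {
    wi <- 1 / pmax(vi, 1e-12)
    ybar <- sum(wi * yi) / sum(wi)
    Q <- sum(wi * (yi - ybar)^2)
    denom <- sum(wi) - sum(wi^2) / sum(wi)
    tau2 <- max(0, (Q - (k - 1)) / denom)
    wstar <- 1 / (vi + tau2)
    pooled <- sum(wstar * yi) / sum(wstar)
    se <- sqrt(1 / sum(wstar))
  }
  ci <- pooled + c(-1.96, 1.96) * se
  if (k >= 3L) {
    tq <- stats::qt(0.975, df = k - 2)
    pi_ <- pooled + c(-tq, tq) * sqrt(tau2 + se^2)
  } else {
    warning("fewer than 3 cohorts: reporting the CI as the prediction interval")
    pi_ <- ci
  }
  structure(list(pooled = pooled, se = se, tau2 = tau2, ci = ci,
                 prediction_interval = pi_, k = k,
                 inputs = data.frame(estimate = yi, se = sei)),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Random-effects pooled estimate over %d cohort(s): %.4f (95%% CI %.4f-%.4f)\n",
              x$k, x$pooled, x$ci[1], x$ci[2]))
  cat(sprintf("  tau^2 = %.5f; 95%% prediction interval %.4f-%.4f\n",
              x$tau2, x$prediction_interval[1], x$prediction_interval[2]))
  invisible(x)
}
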