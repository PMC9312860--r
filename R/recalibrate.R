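#' Expected/observed ratio in a recalibration cohort
#'
#' Divides the mean predicted risk by the observed ASCVD cumulative
#' incidence at the horizon, the latter estimated by Aalen-Johansen (never
#' the Kaplan-Meier complement). Also solves for the multiplicative
#' constant `c` on the baseline cumulative hazard that makes the mean
#' post-recalibration predicted risk equal the observed incidence: because
#' `mean(1 - exp(-c * H_i))` is nonlinear in `c`, the reciprocal of the raw
#' E/O ratio is only approximately that constant, so `c` is found by a
#' bracketed 1-d root search (tolerance 1e-8). Both are reported.
#'
#' @param risks predicted risks for the recalibration cohort.
#' @param outcomes aligned data.frame with `time` and `cause`.
#' @param horizon years.
#' @param label cohort label carried into reports.
#' @return object of class `recalibration_result`: `eo_ratio`, `factor`
#'   (the solved constant), `mean_predicted`, `observed` (+ CI), `horizon`,
#'   `n`, `label`.
#' @export
expected_observed_ratio <- function(risks, outcomes, horizon,
                                    label = "recalibration cohort") {
  outcomes <- as.data.frame(outcomes)
  stopifnot(length(risks) == nrow(outcomes))
  if (!any(outcomes$cause == 1 & outcomes$time <= horizon)) {
    stop("no ASCVD events by the horizon in the recalibration data",
         call. = FALSE)
  }
  obs <- aalen_johansen(outcomes, horizon)
  if (obs$estimate <= 0) {
    stop("undefined ratio: observed cumulative incidence is zero",
         call. = FALSE)
  }
  mean_pred <- mean(risks)
  eo <- mean_pred / obs$estimate
  H <- -log(pmax(1 - risks, 1e-15))    # per-subject cumulative hazards
  target <- obs$estimate
  f <- function(cc) mean(1 - exp(-cc * H)) - target
  lo <- 1e-6; hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-8)
  structure(list(eo_ratio = eo, factor = root$root,
                 mean_predicted = mean_pred,
                 observed = obs$estimate,
                 observed_ci = c(obs$lower, obs$upper),
                 horizon = horizon, n = nrow(outcomes), label = label),
            class = "recalibration_result")
}

#' @export
print.recalibration_result <- function(x, ...) {
  cat(sprintf("E/O in '%s' (n = %d, %.3g y): mean predicted %.4f / observed %.4f = %.4f\n",
              x$label, x$n, x$horizon, x$mean_predicted, x$observed,
              x$eo_ratio))
  cat(sprintf("  solved baseline-hazard factor: %.6f\n", x$factor))
  invisible(x)
}

#' Recalibrate the baseline hazard to a region
#'
#' Returns a new coefficient set whose region factor for `region` is the
#' solved multiplicative constant of a [expected_observed_ratio()] result
#' (or a pooled factor from [pool_factors()]), so that the mean predicted
#' risk in the recalibration data equals the observed cumulative incidence
#' (the fixed-point property: recomputing the E/O after recalibration gives
#' 1 to within the root-search tolerance). The original set is unmodified.
#' Only the baseline shifts; coefficients, and hence the rank ordering of
#' individual risks, are untouched.
#'
#' @param coefset a [coefficient_set()].
#' @param result a `recalibration_result`, or a single positive number (a
#'   pooled factor).
#' @param region region id from [region_registry()].
#' @param horizon if supplied, the factor is stored keyed to this horizon
#'   (regions validated at several horizons keep separate factors);
#'   otherwise it applies to all horizons.
#' @return a new `coefficient_set`.
#' @export
recalibrate <- function(coefset, result, region, horizon = NULL) {
  factor <- if (inherits(result, "recalibration_result")) result$factor
            else as.numeric(result)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0", call. = FALSE)
  if (!region %in% region_registry()$region) {
    stop("unknown region id: ", region, call. = FALSE)
  }
  out <- coefset
  existing <- out$region_factors[[region]]
  if (is.null(horizon)) {
    out$region_factors[[region]] <- factor
  } else {
    key <- as.character(horizon)
    if (is.null(existing) || is.null(names(existing))) existing <- numeric(0)
    existing[key] <- factor
    out$region_factors[[region]] <- existing
  }
  validate_coefficient_set(out)
  out
}

#' Pool recalibration factors across cohorts of one region
#'
#' Unweighted arithmetic mean of the cohort factors (the published
#' procedure averages cohort recalibration factors when a region has
#' several recalibration cohorts); an n-weighted mean is available as an
#' option.
#'
#' @param results list of `recalibration_result` objects.
#' @param weighted use cohort-size weights.
#' @param component `"factor"` (solved constant, default) or `"eo_ratio"`.
#' @return the pooled factor, with the inputs attached as an attribute.
#' @export
pool_factors <- function(results, weighted = FALSE,
                         component = c("factor", "eo_ratio")) {
  component <- match.arg(component)
  if (inherits(results, "recalibration_result")) results <- list(results)
  if (length(results) == 0L) stop("empty input", call. = FALSE)
  f <- vapply(results, function(r) r[[component]], numeric(1))
  n <- vapply(results, function(r) r$n, numeric(1))
  pooled <- if (weighted) sum(f * n) / sum(n) else mean(f)
  structure(pooled,
            inputs = data.frame(
              label = vapply(results, function(r) r$label, character(1)),
              n = n, value = f))
}
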