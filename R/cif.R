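#' Aalen-Johansen cumulative incidence of ASCVD under competing risks
#'
#' Nonparametric cause-1 cumulative incidence function, the estimator the
#' calibration machinery uses throughout (never the Kaplan-Meier
#' complement, which overestimates incidence in the presence of competing
#' non-CVD death). Confidence limits use the log(-log) transform.
#'
#' @param outcomes data.frame with `time` and `cause` (0/1/2), or an
#'   [ascvd_cohort()].
#' @param horizon time in years at which to report the estimate.
#' @param conf_level confidence level.
#' @return object of class `aj_estimate`: `estimate`, `lower`, `upper`,
#'   `horizon`, `n`, `n_events`, and the full step `curve` (time, cif,
#'   se, plus the cause-2 CIF and overall survival).
#' @export
aalen_johansen <- function(outcomes, horizon, conf_level = 0.95) {
  time <- outcomes$time; cause <- outcomes$cause
  if (!any(cause != 0)) stop("at least one event is required", call. = FALSE)
  st <- factor(cause, levels = 0:2, labels = c("censor", "ascvd", "death"))
  fit <- survival::survfit(survival::Surv(time, st) ~ 1)
  states <- fit$states
  i1 <- which(states == "ascvd")
  i2 <- which(states == "death")
  i0 <- which(states == "(s0)")
  curve <- data.frame(time = fit$time,
                      cif = fit$pstate[, i1],
                      se = fit$std.err[, i1],
                      cif_death = fit$pstate[, i2],
                      surv = fit$pstate[, i0])

  ev_times <- time[cause == 1]
  if (length(ev_times) == 0L || horizon < min(ev_times)) {
    warning("horizon precedes the first ASCVD event; estimate is 0")
    out <- list(estimate = 0, lower = 0, upper = 0)
  } else {
    i <- findInterval(horizon + 1e-12, curve$time)
    est <- curve$cif[i]; se <- curve$se[i]
    if (est <= 0 || est >= 1 || !is.finite(se) || se == 0) {
      out <- list(estimate = est, lower = est, upper = est)
    } else {
      # log(-log) CI on the CIF scale
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      lg <- log(-log(est))
      se_lg <- se / (abs(est * log(est)))
      out <- list(estimate = est,
                  lower = exp(-exp(lg + z * se_lg)),
                  upper = exp(-exp(lg - z * se_lg)))
    }
  }
  structure(c(out, list(horizon = horizon, n = length(time),
                        n_events = sum(cause == 1 & time <= horizon),
                        curve = curve)),
            class = "aj_estimate")
}

#' @export
print.aj_estimate <- function(x, ...) {
  cat(sprintf("Aalen-Johansen ASCVD cumulative incidence at %.3g y: %.4f (95%% CI %.4f-%.4f), n = %d, events = %d\n",
              x$horizon, x$estimate, x$lower, x$upper, x$n, x$n_events))
  invisible(x)
}
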