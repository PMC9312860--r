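# Shared helper: weighted concordance of one case risk vector against a
# weighted control set. Returns per-case concordant weight (ties count 1/2)
# and, via side accumulation, per-control sums.
.weighted_conc <- function(case_risk, ctrl_risk, ctrl_w) {
  # for each case, sum of control weights with ctrl_risk < case_risk plus
  # half the weight of ties
  o <- order(ctrl_risk)
  r <- ctrl_risk[o]; w <- ctrl_w[o]
  cw <- c(0, cumsum(w))
  lt <- findInterval(case_risk, r, left.open = TRUE)   # # ctrl risks < case
  le <- findInterval(case_risk, r)                     # # ctrl risks <= case
  W_lt <- cw[lt + 1]
  W_le <- cw[le + 1]
  W_lt + (W_le - W_lt) / 2
}

new_discrimination_result <- function(estimate, variant, horizon, se, n,
                                      events, extra = list()) {
  z <- 1.96
  ci <- c(max(0, estimate - z * se), min(1, estimate + z * se))
  structure(c(list(estimate = estimate, variant = variant, horizon = horizon,
                   se = se, ci = ci, n = n, events = events), extra),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("%s competing-risk C/AUC at %.3g y: %.4f (95%% CI %.4f-%.4f), n = %d, events = %d\n",
              x$variant, x$horizon, x$estimate, x$ci[1], x$ci[2], x$n,
              x$events))
  invisible(x)
}

#' Incident/dynamic time-dependent discrimination under competing risks
#'
#' At each ASCVD event time `t` up to the horizon, cases are the subjects
#' failing at `t` and controls are the subjects still under observation
#' after `t` together with subjects who died of non-CVD causes before `t`,
#' the latter retained with the Fine-Gray IPCW risk-set weight
#' `G(t-)/G(s-)`. The time-specific AUCs are aggregated over `[0, horizon]`
#' with pair-count weights, giving an integrated concordance reported as
#' the C-statistic. The variance is a DeLong-type two-sample component
#' decomposition (approximate under weighting).
#'
#' @param risks numeric vector of predicted risks (any strictly monotone
#'   transform of the model's linear predictor gives the same value).
#' @param outcomes data.frame with `time`, `cause` aligned with `risks`.
#' @param horizon years.
#' @return a `discrimination_result` with the per-time AUC curve attached.
#' @export
incident_auc <- function(risks, outcomes, horizon) {
  time <- outcomes$time; cause <- outcomes$cause
  stopifnot(length(risks) == length(time))
  n <- length(risks)
  case_times <- sort(unique(time[cause == 1 & time <= horizon]))
  if (length(case_times) == 0L) {
    stop("undefined: no ASCVD events by the horizon", call. = FALSE)
  }
  km <- survival::survfit(survival::Surv(time, cause == 0) ~ 1)
  Gm <- make_left_step(km$time, km$surv)
  g_at <- Gm(time)

  num_tot <- 0; den_tot <- 0
  num_case <- numeric(n); den_case <- numeric(n)
  num_ctrl <- numeric(n); den_ctrl <- numeric(n)
  auc_t <- numeric(length(case_times)); w_t <- numeric(length(case_times))

  for (k in seq_along(case_times)) {
    t_k <- case_times[k]
    cases <- which(cause == 1 & time == t_k)
    at_risk <- which(time > t_k)
    comp <- which(cause == 2 & time <= t_k & time > 0)
    comp <- setdiff(comp, at_risk)
    w_comp <- ifelse(g_at[comp] > 0, Gm(t_k) / g_at[comp], 0)
    # competing deaths at exactly t_k are still in the risk set, weight 1
    w_comp[time[comp] >= t_k] <- 1
    ctrl <- c(at_risk, comp)
    w_ctrl <- c(rep(1, length(at_risk)), w_comp)
    keep <- w_ctrl > 0
    ctrl <- ctrl[keep]; w_ctrl <- w_ctrl[keep]
    if (length(ctrl) == 0L) { auc_t[k] <- NA; next }
    conc <- .weighted_conc(risks[cases], risks[ctrl], w_ctrl)
    Wsum <- sum(w_ctrl)
    num_k <- sum(conc); den_k <- length(cases) * Wsum
    num_tot <- num_tot + num_k; den_tot <- den_tot + den_k
    auc_t[k] <- num_k / den_k; w_t[k] <- den_k
    num_case[cases] <- num_case[cases] + conc
    den_case[cases] <- den_case[cases] + Wsum
    # per-control concordance against this case set (for the variance)
    conc_ctrl <- length(cases) - .weighted_conc(risks[ctrl],
                                                risks[cases],
                                                rep(1, length(cases)))
    num_ctrl[ctrl] <- num_ctrl[ctrl] + w_ctrl * conc_ctrl
    den_ctrl[ctrl] <- den_ctrl[ctrl] + w_ctrl * length(cases)
  }
  est <- num_tot / den_tot
  se <- .component_se(num_case, den_case, num_ctrl, den_ctrl)
  new_discrimination_result(
    est, "incident", horizon, se, n, sum(cause == 1 & time <= horizon),
    extra = list(auc_curve = data.frame(time = case_times, auc = auc_t,
                                        weight = w_t)))
}

.component_se <- function(num_case, den_case, num_ctrl, den_ctrl) {
  v10 <- num_case[den_case > 0] / den_case[den_case > 0]
  v01 <- num_ctrl[den_ctrl > 0] / den_ctrl[den_ctrl > 0]
  va <- if (length(v10) > 1) stats::var(v10) / length(v10) else 0
  vb <- if (length(v01) > 1) stats::var(v01) / length(v01) else 0
  sqrt(va + vb)
}

#' Cumulative/dynamic competing-risk-adjusted C-statistic
#'
#' Cases are subjects with an ASCVD event by the horizon; controls are
#' subjects still event-free at the horizon plus subjects with a competing
#' non-CVD death by the horizon. Inverse-probability-of-censoring weights
#' (`1/G(t-)` at the relevant time) make the estimate consistent under
#' independent censoring; competing-event subjects are always retained as
#' controls, never censored.
#'
#' @inheritParams incident_auc
#' @return a `discrimination_result`.
#' @export
cumulative_cstat <- function(risks, outcomes, horizon) {
  time <- outcomes$time; cause <- outcomes$cause
  stopifnot(length(risks) == length(time))
  n <- length(risks)
  km <- survival::survfit(survival::Surv(time, cause == 0) ~ 1)
  Gm <- make_left_step(km$time, km$surv)

  case <- which(cause == 1 & time <= horizon)
  if (length(case) == 0L) stop("undefined: no ASCVD events by the horizon",
                               call. = FALSE)
  ctrl_free <- which(time > horizon)
  ctrl_comp <- which(cause == 2 & time <= horizon)
  if (length(ctrl_free) + length(ctrl_comp) == 0L) {
    stop("undefined: no controls at the horizon", call. = FALSE)
  }
  a <- 1 / Gm(time[case]); a[!is.finite(a)] <- 0
  w_free <- rep(1 / Gm(horizon), length(ctrl_free))
  w_comp <- 1 / Gm(time[ctrl_comp]); w_comp[!is.finite(w_comp)] <- 0
  ctrl <- c(ctrl_free, ctrl_comp)
  w <- c(w_free, w_comp)
  keep_c <- w > 0; ctrl <- ctrl[keep_c]; w <- w[keep_c]
  keep_a <- a > 0; case <- case[keep_a]; a <- a[keep_a]

  conc <- .weighted_conc(risks[case], risks[ctrl], w)   # per case
  Wsum <- sum(w); Asum <- sum(a)
  est <- sum(a * conc) / (Asum * Wsum)
  # component variance
  conc_ctrl <- Asum - .weighted_conc(risks[ctrl], risks[case], a)
  v10 <- conc / Wsum
  v01 <- conc_ctrl / Asum
  se <- sqrt(stats::var(v10) / length(v10) + stats::var(v01) / length(v01))
  new_discrimination_result(est, "cumulative", horizon, se, n, length(case))
}
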