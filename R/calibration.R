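#' Calibration table over octiles of predicted risk
#'
#' Partitions the cohort into eight equal-sized bins by predicted risk
#' (ties broken by stable input order), and reports per bin the number of
#' patients, mean predicted risk, and the observed Aalen-Johansen ASCVD
#' cumulative incidence at the horizon with its confidence interval - the
#' table behind predicted-vs-observed calibration plots. With fewer than 8
#' distinct risk values, bins collapse (with a warning) to the distinct
#' values.
#'
#' @inheritParams incident_auc
#' @return object of class `calibration_table`: data.frame `bins` with
#'   columns `bin`, `n`, `mean_predicted`, `observed`, `lower`, `upper`,
#'   plus attributes `eo_ratio` (overall expected/observed) and `horizon`.
#' @export
calibration_octiles <- function(risks, outcomes, horizon) {
  n <- length(risks)
  stopifnot(n == nrow(as.data.frame(outcomes)))
  if (n < 16L) stop("at least 16 subjects are required", call. = FALSE)
  n_distinct <- length(unique(risks))
  if (n_distinct < 8L) {
    warning(sprintf("only %d distinct risk values: bins collapsed", n_distinct))
    grp <- match(risks, sort(unique(risks)))
  } else {
    o <- order(risks, seq_len(n))     # stable tie-break by input order
    grp <- integer(n)
    grp[o] <- ceiling(seq_len(n) / (n / 8))
    grp <- pmin(grp, 8L)
  }
  outcomes <- as.data.frame(outcomes)
  bins <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    aj <- tryCatch(
      suppressWarnings(aalen_johansen(outcomes[idx, , drop = FALSE], horizon)),
      error = function(e) list(estimate = 0, lower = 0, upper = 0))
    data.frame(bin = g, n = length(idx), mean_predicted = mean(risks[idx]),
               observed = aj$estimate, lower = aj$lower, upper = aj$upper)
  }))
  overall <- aalen_johansen(outcomes, horizon)
  structure(list(bins = bins, horizon = horizon,
                 eo_ratio = mean(risks) / overall$estimate,
                 mean_predicted = mean(risks),
                 observed = overall$estimate),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration by octiles of predicted risk at %.3g y (overall E/O %.3f)\n",
              x$horizon, x$eo_ratio))
  print(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Calibration slope of a linear predictor
#'
#' The coefficient of the (out-of-sample) linear predictor in a
#' single-covariate Fine-Gray refit on the evaluation data. A slope of 1
#' indicates neither over- nor under-fitting; overfitted models show
#' slopes below 1 on fresh data.
#'
#' @param lp numeric linear-predictor vector.
#' @param outcomes data.frame with `time` and `cause` aligned with `lp`.
#' @return list with `slope`, `se` and 95% `ci`.
#' @export
calibration_slope <- function(lp, outcomes) {
  if (stats::var(lp) <= 0) {
    stop("undefined: linear predictor has zero variance", call. = FALSE)
  }
  X <- matrix(lp - mean(lp), ncol = 1, dimnames = list(NULL, "lp"))
  eng <- fg_engine(outcomes$time, outcomes$cause, X)
  se <- sqrt(eng$vcov[1, 1])
  list(slope = unname(eng$coefficients[1]), se = se,
       ci = unname(eng$coefficients[1]) + c(-1.96, 1.96) * se,
       converged = eng$converged)
}
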