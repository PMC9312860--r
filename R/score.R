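# Floor for log-transformed measurements; values below it are floored with a
# warning (log transform requires positivity; measurements this small are at
# or below assay detection limits anyway).
.LOG_FLOOR <- 0.01

#' Transform a patient record to score terms
#'
#' Applies the per-term transformation declared in the coefficient set
#' (identity, natural log, or square) to each predictor the set names.
#' Binary flags map to 0/1 (`sex` maps male to 1). Values below 0.01 under a
#' log transform are floored at 0.01 with a warning.
#'
#' @param record one-row data.frame or list of predictor values (see
#'   [ascvd_cohort()] for names and units); may also be a multi-row cohort,
#'   in which case a matrix is returned.
#' @param coefset a [coefficient_set()].
#' @return named numeric of transformed term values (or an n-by-p matrix).
#' @export
transform_record <- function(record, coefset) {
  rec <- as.data.frame(record)
  terms <- names(coefset$coefficients)
  absent <- setdiff(terms, names(rec))
  if (length(absent)) {
    stop("schema mismatch: record lacks term(s) named by the coefficient set: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(rec), length(terms),
                dimnames = list(NULL, terms))
  for (trm in terms) {
    x <- as.numeric(rec[[trm]])
    tr <- coefset$transforms[[trm]]
    out[, trm] <- switch(
      tr,
      identity = x,
      square = x^2,
      log = {
        if (any(x < .LOG_FLOOR, na.rm = TRUE)) {
          warning(sprintf("flooring %d value(s) of '%s' at %.2f before log transform",
                          sum(x < .LOG_FLOOR, na.rm = TRUE), trm, .LOG_FLOOR))
          x <- pmax(x, .LOG_FLOOR)
        }
        log(x)
      },
      stop("unknown transform: ", tr, call. = FALSE)
    )
  }
  if (nrow(rec) == 1L) out[1L, ] else out
}

#' Centered linear predictor with per-term breakdown
#'
#' Computes `sum_j beta_j (z_j - m_j)` where `z` are transformed term values
#' and `m` the centering means, plus the fixed antithrombotic offset
#' contribution `log(offset_hr)` when the offset applies.
#'
#' @inheritParams transform_record
#' @param treat_antithrombotic logical; `NULL` (default) uses the record's
#'   own `antithrombotic_use` flag. Override for what-if prediction.
#' @return for a single record, a `lp_breakdown` list (`terms`: named
#'   per-term contributions; `offset`: offset contribution; `total`); for a
#'   cohort, a numeric vector of totals with the breakdown matrix attached
#'   as an attribute.
#' @export
linear_predictor <- function(record, coefset, treat_antithrombotic = NULL) {
  z <- transform_record(record, coefset)
  single <- is.null(dim(z))
  if (single) z <- matrix(z, 1L, dimnames = list(NULL, names(z)))
  terms <- names(coefset$coefficients)
  contrib <- sweep(z[, terms, drop = FALSE], 2L,
                   coefset$centering_means[terms], `-`)
  contrib <- sweep(contrib, 2L, coefset$coefficients[terms], `*`)
  rec <- as.data.frame(record)
  if (is.null(treat_antithrombotic)) {
    if (!coefset$offset_term %in% names(rec)) {
      stop("record lacks the offset flag '", coefset$offset_term,
           "'; supply treat_antithrombotic", call. = FALSE)
    }
    treat <- as.numeric(rec[[coefset$offset_term]])
  } else {
    treat <- rep_len(as.numeric(treat_antithrombotic), nrow(z))
  }
  off <- log(coefset$offset_hr) * treat
  total <- rowSums(contrib) + off
  if (single) {
    structure(list(terms = contrib[1L, ], offset = off[1L],
                   total = total[1L]), class = "lp_breakdown")
  } else {
    structure(total, breakdown = contrib, offset = off)
  }
}

#' @export
print.lp_breakdown <- function(x, ...) {
  df <- data.frame(term = c(names(x$terms), "offset"),
                   contribution = c(unname(x$terms), x$offset))
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("total linear predictor: %.6f\n", x$total))
  invisible(x)
}

#' Predict 10-year (or horizon-specific) recurrent-ASCVD risk
#'
#' Individual risk under the recalibrated score:
#' `risk = 1 - exp(-EO_region * Lambda0(horizon) * exp(LP))`
#' where `Lambda0 = -log S0` is the baseline cumulative subdistribution
#' hazard at the derivation centering point, `EO_region` the region's
#' multiplicative recalibration factor, and `LP` the centered linear
#' predictor including the antithrombotic offset `log(0.81)` when treatment
#' applies. Baseline knots are evaluated as a right-continuous step
#' function: a horizon between knots uses the last knot at or before it.
#'
#' @inheritParams linear_predictor
#' @param region region id from [region_registry()].
#' @param horizon prediction horizon in years; must not exceed the last
#'   baseline knot.
#' @return for a single record, a list with `risk`, `horizon`, `region` and
#'   the `breakdown`; for a cohort, a numeric risk vector.
#' @export
predict_risk <- function(record, coefset, region = "europe_low",
                         horizon = 10, treat_antithrombotic = NULL) {
  H0 <- baseline_cumhaz_at(coefset, horizon)
  eo <- region_factor(coefset, region, horizon)
  lp <- linear_predictor(record, coefset, treat_antithrombotic)
  if (inherits(lp, "lp_breakdown")) {
    risk <- 1 - exp(-eo * H0 * exp(lp$total))
    list(risk = risk, horizon = horizon, region = region, breakdown = lp)
  } else {
    1 - exp(-eo * H0 * exp(as.numeric(lp)))
  }
}

baseline_cumhaz_at <- function(coefset, horizon) {
  bs <- coefset$baseline_survival
  knots <- as.numeric(names(bs))
  o <- order(knots)
  knots <- knots[o]; bs <- bs[o]
  if (horizon > max(knots) + 1e-9) {
    stop(sprintf("horizon %.3g beyond last baseline knot (%.3g): extrapolation not supported",
                 horizon, max(knots)), call. = FALSE)
  }
  i <- findInterval(horizon + 1e-9, knots)
  if (i == 0L) {
    stop(sprintf("horizon %.3g precedes the first baseline knot (%.3g)",
                 horizon, min(knots)), call. = FALSE)
  }
  -log(bs[[i]])
}

#' Vectorized risk prediction over a cohort
#'
#' Order-preserving wrapper around [predict_risk()]. Record-level failures
#' (invalid values, schema mismatches) are collected into a row-indexed
#' error report attached as an attribute, never raised.
#'
#' @param cohort an [ascvd_cohort()] or plain data.frame of records.
#' @inheritParams predict_risk
#' @return numeric vector of risks (NA where a record failed) with
#'   attributes `errors` (data.frame `row`, `message`) and `summary`
#'   (mean risk and octile bounds).
#' @export
batch_predict <- function(cohort, coefset, region = "europe_low",
                          horizon = 10) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (n == 0L) {
    warning("empty cohort: returning empty risk vector")
    return(structure(numeric(0),
                     errors = data.frame(row = integer(0),
                                         message = character(0))))
  }
  risks <- rep(NA_real_, n)
  ok <- tryCatch({
    risks <- predict_risk(df, coefset, region, horizon)
    TRUE
  }, error = function(e) FALSE)
  errs <- data.frame(row = integer(0), message = character(0),
                     stringsAsFactors = FALSE)
  if (!ok || anyNA(risks)) {
    for (i in seq_len(n)) {
      res <- tryCatch(
        predict_risk(df[i, , drop = FALSE], coefset, region, horizon)$risk,
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        errs <- rbind(errs, data.frame(row = i, message = res,
                                       stringsAsFactors = FALSE))
        risks[i] <- NA_real_
      } else risks[i] <- res
    }
  }
  oct <- stats::quantile(risks, probs = seq(0, 1, 1 / 8), na.rm = TRUE)
  structure(risks, errors = errs,
            summary = list(mean = mean(risks, na.rm = TRUE),
                           octile_bounds = oct))
}
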