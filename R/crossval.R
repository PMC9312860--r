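#' K-fold cross-validated discrimination and calibration slope
#'
#' Internal validation by seeded, cause-stratified k-fold cross-validation:
#' each fold's model is fitted on the remaining folds, the out-of-fold
#' linear predictors and predicted horizon risks are concatenated, and the
#' pooled vector is scored once - the competing-risk C-statistic on the
#' pooled out-of-fold risks and the calibration slope of the pooled
#' out-of-fold linear predictor.
#'
#' @param data an [ascvd_cohort()] with complete predictors.
#' @param spec an [model_spec()].
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param horizon evaluation horizon in years.
#' @param variant discrimination variant, `"incident"` (integrated,
#'   default) or `"cumulative"`.
#' @return list with `cstat` (a `discrimination_result`), `slope` (from
#'   [calibration_slope()]), `folds` (assignment vector) and `lp_oof`,
#'   `risk_oof`.
#' @export
crossvalidate <- function(data, spec = smart2_model_spec(), k = 10,
                          seed = 1, horizon = 10,
                          variant = c("incident", "cumulative")) {
  variant <- match.arg(variant)
  df <- as.data.frame(data)
  n <- nrow(df)
  if (k < 2) stop("k must be >= 2", call. = FALSE)

  assign_folds <- function(s) {
    set.seed(s)
    folds <- integer(n)
    for (cz in unique(df$cause)) {
      idx <- which(df$cause == cz)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  }
  folds <- assign_folds(seed)
  ev_per_fold <- vapply(seq_len(k), function(f)
    sum(df$cause == 1 & folds == f), integer(1))
  if (any(ev_per_fold == 0L)) {
    folds <- assign_folds(seed + 1L)   # stratification retry
    ev_per_fold <- vapply(seq_len(k), function(f)
      sum(df$cause == 1 & folds == f), integer(1))
    if (any(ev_per_fold == 0L)) {
      stop("a fold has zero ASCVD events even after re-stratification",
           call. = FALSE)
    }
  }

  lp_oof <- numeric(n); risk_oof <- numeric(n)
  for (f in seq_len(k)) {
    train <- df[folds != f, , drop = FALSE]
    test <- df[folds == f, , drop = FALSE]
    fit <- fit_fine_gray(train, spec)
    Z <- build_terms(test, spec)
    Xc <- sweep(Z, 2L, fit$centering_means, `-`)
    lp <- as.vector(Xc %*% fit$coefficients)
    for (trm in names(spec$offset_terms)) {
      lp <- lp + spec$offset_terms[[trm]] * as.numeric(test[[trm]])
    }
    lp_oof[folds == f] <- lp
    risk_oof[folds == f] <- predict_cif(fit, test, horizon)
  }

  outcomes <- df[c("time", "cause")]
  cstat <- if (variant == "incident") {
    incident_auc(risk_oof, outcomes, horizon)
  } else {
    cumulative_cstat(risk_oof, outcomes, horizon)
  }
  slope <- calibration_slope(lp_oof, outcomes)
  list(cstat = cstat, slope = slope, folds = folds,
       lp_oof = lp_oof, risk_oof = risk_oof)
}
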