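#' Compare candidate transformations for a continuous predictor by AIC
#'
#' Refits the model with the named predictor entered as identity, log,
#' square, or a restricted cubic spline (3 knots at the 10th/50th/90th
#' percentiles), holding every other term of the specification fixed, and
#' returns the transform minimizing `AIC = 2k - 2 loglik` of the weighted
#' partial likelihood. Ties are broken toward identity.
#'
#' @param data an [ascvd_cohort()] with complete predictors.
#' @param predictor name of a continuous predictor (> 10 distinct values).
#' @param spec base [model_spec()]; the predictor must be one of its terms.
#' @return list with `selected` and the full `aic_table`.
#' @export
select_transformation <- function(data, predictor,
                                  spec = smart2_model_spec()) {
  df <- as.data.frame(data)
  x <- df[[predictor]]
  if (is.null(x)) stop("predictor not found: ", predictor, call. = FALSE)
  nd <- length(unique(x[!is.na(x)]))
  if (nd <= 2L) {
    stop("not applicable: '", predictor, "' is binary", call. = FALSE)
  }
  if (nd <= 10L) {
    stop("predictor must have more than 10 distinct values", call. = FALSE)
  }
  if (!predictor %in% spec$predictors) {
    stop("'", predictor, "' is not a term of the model specification",
         call. = FALSE)
  }

  fit_with <- function(transform) {
    if (transform == "spline") {
      Z <- build_terms(df, spec)
      kn <- stats::quantile(x, c(.1, .5, .9), names = FALSE)
      base_col <- match(predictor, colnames(Z))
      Z[, base_col] <- x
      Z <- cbind(Z, rcs_basis(x, kn))
      colnames(Z)[ncol(Z)] <- paste0(predictor, "_rcs1")
      Xc <- sweep(Z, 2L, colMeans(Z), `-`)
    } else {
      sp <- spec
      sp$transforms[[predictor]] <- transform
      Z <- build_terms(df, sp)
      Xc <- sweep(Z, 2L, colMeans(Z), `-`)
    }
    offset <- numeric(nrow(df))
    for (trm in names(spec$offset_terms)) {
      offset <- offset + spec$offset_terms[[trm]] * as.numeric(df[[trm]])
    }
    eng <- fg_engine(df$time, df$cause, Xc, offset)
    c(loglik = eng$loglik, k = ncol(Xc))
  }

  cands <- c("identity", "log", "square", "spline")
  tab <- t(vapply(cands, fit_with, numeric(2)))
  aic <- 2 * tab[, "k"] - 2 * tab[, "loglik"]
  tab <- data.frame(transform = cands, loglik = tab[, "loglik"],
                    df = tab[, "k"], aic = aic, row.names = NULL)
  # ties toward identity: order candidates with identity first, pick first min
  best <- tab$transform[order(round(tab$aic, 10))][1]
  if (abs(tab$aic[tab$transform == "identity"] - min(tab$aic)) < 1e-10) {
    best <- "identity"
  }
  list(selected = best, aic_table = tab)
}

# Restricted cubic spline nonlinear basis, 3 knots (one column).
rcs_basis <- function(x, knots) {
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  norm <- (k3 - k1)^2
  pp <- function(u) pmax(u, 0)^3
  b <- (pp(x - k1) - pp(x - k2) * (k3 - k1) / (k3 - k2) +
          pp(x - k3) * (k2 - k1) / (k3 - k2)) / norm
  matrix(b, ncol = 1)
}

#' Schoenfeld-type residual diagnostics for proportional subdistribution hazards
#'
#' Weighted Schoenfeld residuals `x_i - S1(t_i)/S0(t_i)` at each cause-1
#' event time (risk-set expectations under the IPCW weighting of the fit),
#' together with a per-term trend-slope test (slope of residual on event
#' time; a non-zero slope signals a time-varying coefficient) and a lowess
#' smoothed trend for plotting.
#'
#' @param fit a converged [fit_fine_gray()] result.
#' @param data ignored (the fit carries its design); kept for call symmetry.
#' @return object of class `schoenfeld_diagnostics`: `residuals`
#'   (data.frame: `time` plus one column per term), `trend` (term, slope,
#'   se, statistic, p), `smoothed` (list of lowess curves).
#' @export
schoenfeld_diagnostics <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "fine_gray_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  it <- fit$internals
  if (is.null(it)) stop("fit lacks stored internals", call. = FALSE)
  ev <- it$ev
  if (length(ev) < 3L) {
    stop("insufficient events: at least 3 cause-1 events required",
         call. = FALSE)
  }
  times <- it$t_s[ev]
  Mrow <- it$M[match(times, it$ut), , drop = FALSE]
  res <- it$X_s[ev, , drop = FALSE] - Mrow
  resid_df <- data.frame(time = times, res, check.names = FALSE)

  terms <- colnames(res)
  trend <- do.call(rbind, lapply(terms, function(trm) {
    fit_lm <- stats::lm(res[, trm] ~ times)
    sm <- summary(fit_lm)$coefficients
    data.frame(term = trm, slope = sm[2, 1], se = sm[2, 2],
               statistic = sm[2, 3], p = sm[2, 4])
  }))
  smoothed <- lapply(stats::setNames(terms, terms), function(trm) {
    stats::lowess(times, res[, trm])
  })
  structure(list(residuals = resid_df, trend = trend, smoothed = smoothed),
            class = "schoenfeld_diagnostics")
}

#' @export
print.schoenfeld_diagnostics <- function(x, ...) {
  cat(sprintf("Schoenfeld-type residuals at %d event times\n",
              nrow(x$residuals)))
  print(x$trend, row.names = FALSE, digits = 4)
  invisible(x)
}
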