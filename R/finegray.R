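#' Model specification for the Fine-Gray engine
#'
#' @param predictors character vector of predictor names to estimate
#'   coefficients for.
#' @param transforms named character of transforms (`"identity"`, `"log"`,
#'   `"square"`) per predictor; unnamed predictors default to identity.
#' @param offset_terms named list of fixed log-subdistribution-hazard
#'   coefficients, e.g. `list(antithrombotic_use = log(0.81))`. Offset terms
#'   enter the linear predictor with fixed coefficients and are excluded
#'   from estimation.
#' @param tie_rule tie handling; only `"breslow"` is provided (it matches
#'   the Breslow-type baseline estimator).
#' @return object of class `fg_model_spec`.
#' @export
model_spec <- function(predictors, transforms = NULL, offset_terms = list(),
                       tie_rule = "breslow") {
  tie_rule <- match.arg(tie_rule, "breslow")
  if (anyDuplicated(predictors)) stop("duplicate predictor terms", call. = FALSE)
  if (length(intersect(predictors, names(offset_terms)))) {
    stop("offset terms must be excluded from the estimated predictors",
         call. = FALSE)
  }
  tr <- stats::setNames(rep("identity", length(predictors)), predictors)
  if (!is.null(transforms)) {
    bad <- setdiff(unname(transforms), .transform_names)
    if (length(bad)) stop("unknown transform: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    tr[names(transforms)] <- unname(transforms)
  }
  structure(list(predictors = predictors, transforms = tr,
                 offset_terms = offset_terms, tie_rule = tie_rule),
            class = "fg_model_spec")
}

#' The default SMART2 model specification
#'
#' The 13 predictors of the recurrent-ASCVD score with the published
#' transformations (log for non-HDL cholesterol and hsCRP, square for years
#' since first ASCVD diagnosis and eGFR) and the fixed antithrombotic
#' offset at hazard ratio 0.81.
#'
#' @param offset_hr fixed antithrombotic hazard ratio.
#' @return an [model_spec()].
#' @export
smart2_model_spec <- function(offset_hr = 0.81) {
  model_spec(
    predictors = c("age", "sex", "current_smoking", "systolic_bp", "non_hdl",
                   "diabetes", "cad", "cevd", "pad", "aaa",
                   "years_since_first_ascvd", "egfr", "hscrp"),
    transforms = c(non_hdl = "log", hscrp = "log",
                   years_since_first_ascvd = "square", egfr = "square"),
    offset_terms = list(antithrombotic_use = log(offset_hr))
  )
}

#' Inverse-probability-of-censoring weights
#'
#' Estimates the censoring survivor curve G by Kaplan-Meier with censoring
#' as the event, and exposes the Fine-Gray risk-set weights: a subject
#' contributes weight 1 while event-free and uncensored; a subject with a
#' competing (non-CVD death) event at time s remains in the cause-1 risk
#' set thereafter with weight `G(t-)/G(s-)` at time `t > s`.
#'
#' @param data an [ascvd_cohort()] or data.frame with `time` and `cause`.
#' @return object of class `ipcw_weights` with the censoring curve, a
#'   left-continuous evaluator `Gminus(t)`, and `weight_matrix(times)`
#'   (subjects by times; intended for small data - it is dense).
#' @export
censoring_weights <- function(data) {
  time <- data$time; cause <- data$cause
  if (length(time) == 0L || all(time <= 0)) {
    stop("degenerate input: no positive follow-up times", call. = FALSE)
  }
  km <- survival::survfit(survival::Surv(time, cause == 0) ~ 1)
  Gminus <- make_left_step(km$time, km$surv)
  obj <- list(time = time, cause = cause,
              G = data.frame(time = km$time, surv = km$surv),
              Gminus = Gminus)
  obj$weight_matrix <- function(times = sort(unique(time[cause == 1]))) {
    W <- matrix(0, length(time), length(times),
                dimnames = list(NULL, signif(times, 8)))
    gt <- Gminus(times)
    gs <- Gminus(time)
    for (j in seq_along(times)) {
      t_j <- times[j]
      at_risk <- time >= t_j
      W[at_risk, j] <- 1
      comp <- cause == 2 & time < t_j
      W[comp, j] <- ifelse(gs[comp] > 0, gt[j] / gs[comp], 0)
    }
    W
  }
  class(obj) <- "ipcw_weights"
  obj
}

# Left-continuous step evaluator for a right-continuous survival curve:
# value at t is the curve's value just before t (1 before the first step).
make_left_step <- function(times, surv) {
  if (length(times) == 0L) return(function(t) rep(1, length(t)))
  f <- stats::stepfun(times, c(1, surv), right = TRUE)
  function(t) f(t)
}

#' @export
print.ipcw_weights <- function(x, ...) {
  cat(sprintf("IPCW censoring weights: %d subjects, G has %d steps\n",
              length(x$time), sum(diff(c(1, x$G$surv)) < 0)))
  invisible(x)
}

# --- core weighted partial-likelihood engine -------------------------------
#
# Newton-Raphson maximization of the IPCW-weighted Fine-Gray partial
# likelihood with Breslow tie handling. Risk-set sums are assembled from
# suffix sums (subjects still under observation) plus G(t-)-weighted prefix
# sums over prior competing events, so each iteration is O(n p^2).
fg_engine <- function(time, cause, X, offset = NULL,
                      tol_score = 1e-9, tol_loglik = 1e-12, max_iter = 100L,
                      keep_internals = FALSE) {
  n <- length(time)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(offset)) offset <- numeric(n)
  stopifnot(length(cause) == n, nrow(X) == n, length(offset) == n)
  if (!any(cause == 1)) stop("at least one cause-1 event is required", call. = FALSE)

  if (p > 0) {
    qr_x <- qr(X)
    if (qr_x$rank < p) {
      dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
      stop("singular information: collinear term(s): ",
           paste(dep, collapse = ", "), call. = FALSE)
    }
  }

  ord <- order(time)
  t_s <- time[ord]; c_s <- cause[ord]
  X_s <- X[ord, , drop = FALSE]; off_s <- offset[ord]

  km <- survival::survfit(survival::Surv(t_s, c_s == 0) ~ 1)
  Gminus <- make_left_step(km$time, km$surv)

  ev <- which(c_s == 1)
  ut <- unique(t_s[ev])                       # ascending
  nut <- length(ut)
  d_u <- as.numeric(table(factor(t_s[ev], levels = ut)))
  # sum of covariates over event subjects per unique event time
  if (p > 0) {
    Xev <- rowsum(X_s[ev, , drop = FALSE], group = match(t_s[ev], ut))
  }
  comp <- which(c_s == 2)
  t_comp <- t_s[comp]
  g_comp <- Gminus(t_comp)

  pos_all <- findInterval(ut, t_s, left.open = TRUE) + 1L   # first idx with t >= u
  cnt_comp <- findInterval(ut, t_comp, left.open = TRUE)    # # comp strictly < u
  Gm_u <- Gminus(ut)

  # flattened upper triangle indices for the information matrix
  if (p > 0) {
    tri <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    XX_s <- X_s[, tri[, 1], drop = FALSE] * X_s[, tri[, 2], drop = FALSE]
  }

  suffix_sum <- function(w) {        # S[k] = sum_{i>=k} w_i, with S[n+1] = 0
    c(rev(cumsum(rev(w))), 0)
  }
  suffix_sum_mat <- function(W) {
    nr <- nrow(W)
    S <- matrix(0, nr + 1L, ncol(W))
    for (j in seq_len(ncol(W))) S[seq_len(nr), j] <- rev(cumsum(rev(W[, j])))
    S
  }
  prefix_sum_mat <- function(W) {
    nr <- nrow(W)
    S <- matrix(0, nr + 1L, ncol(W))
    for (j in seq_len(ncol(W))) S[-1L, j] <- cumsum(W[, j])
    S
  }

  risk_sums <- function(e) {
    A0 <- suffix_sum(e)[pos_all]
    b <- ifelse(g_comp > 0, e[comp] / g_comp, 0)
    B0 <- c(0, cumsum(b))[cnt_comp + 1L]
    S0 <- A0 + Gm_u * B0
    out <- list(S0 = S0)
    if (p > 0) {
      Xe <- X_s * e
      A1 <- suffix_sum_mat(Xe)[pos_all, , drop = FALSE]
      B1 <- prefix_sum_mat(X_s[comp, , drop = FALSE] * b)[cnt_comp + 1L, , drop = FALSE]
      out$S1 <- A1 + Gm_u * B1
      XXe <- XX_s * e
      A2 <- suffix_sum_mat(XXe)[pos_all, , drop = FALSE]
      B2 <- prefix_sum_mat(XX_s[comp, , drop = FALSE] * b)[cnt_comp + 1L, , drop = FALSE]
      out$S2 <- A2 + Gm_u * B2
    }
    out
  }

  loglik_of <- function(e, S0) {
    sum(log(e[ev])) - sum(d_u * log(S0))
  }

  beta <- numeric(p)
  eta <- as.vector(if (p > 0) X_s %*% beta else numeric(n)) + off_s
  e <- exp(eta)
  rs <- risk_sums(e)
  ll <- loglik_of(e, rs$S0)
  iter <- 0L; converged <- FALSE; score_norm <- NA_real_
  info <- NULL; U <- NULL

  if (p == 0) {
    converged <- TRUE
  } else {
    build_info <- function(rs) {
      M <- rs$S1 / rs$S0
      info_flat <- colSums(rs$S2 * (d_u / rs$S0))
      info <- matrix(0, p, p)
      info[cbind(tri[, 1], tri[, 2])] <- info_flat
      info[cbind(tri[, 2], tri[, 1])] <- info_flat
      list(U = colSums(Xev) - colSums(d_u * M),
           info = info - crossprod(M, d_u * M))
    }
    repeat {
      gi <- build_info(rs)
      U <- gi$U; info <- gi$info
      score_norm <- max(abs(U))
      if (score_norm < tol_score) { converged <- TRUE; break }
      if (iter >= max_iter) break
      step <- tryCatch(solve(info, U), error = function(e2)
        stop("singular information matrix during Newton-Raphson", call. = FALSE))
      ll_old <- ll
      fac <- 1
      repeat {
        beta_new <- beta + fac * step
        eta <- as.vector(X_s %*% beta_new) + off_s
        e_new <- exp(eta)
        rs_new <- risk_sums(e_new)
        ll_new <- loglik_of(e_new, rs_new$S0)
        if (is.finite(ll_new) && (ll_new >= ll_old - 1e-12)) break
        fac <- fac / 2
        if (fac < 1e-10) { ll_new <- ll_old; beta_new <- beta; rs_new <- rs; e_new <- e; break }
      }
      iter <- iter + 1L
      delta_ll <- abs(ll_new - ll_old) / (abs(ll_old) + 1e-10)
      beta <- beta_new; e <- e_new; rs <- rs_new; ll <- ll_new
      if (delta_ll < tol_loglik) {
        gi <- build_info(rs)
        U <- gi$U; info <- gi$info
        score_norm <- max(abs(U))
        converged <- TRUE
        break
      }
    }
  }

  dL <- d_u / rs$S0
  # product-limit form of the baseline: reduces exactly to Aalen-Johansen
  # under the null model
  cumhaz <- cumsum(-log(pmax(1 - dL, 1e-300)))

  vcov <- if (p > 0) {
    tryCatch(solve(info), error = function(e2) matrix(NA_real_, p, p))
  } else matrix(numeric(0), 0, 0)

  out <- list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vcov,
    loglik = ll, iterations = iter, converged = converged,
    score_norm = score_norm,
    baseline = data.frame(time = ut, n_event = d_u, dhaz = dL, cumhaz = cumhaz),
    n_events_by_cause = c(censored = sum(cause == 0), ascvd = sum(cause == 1),
                          competing = sum(cause == 2)),
    Gminus = Gminus
  )
  if (keep_internals) {
    out$internals <- list(ord = ord, t_s = t_s, c_s = c_s, X_s = X_s,
                          ev = ev, ut = ut,
                          M = if (p > 0) rs$S1 / rs$S0 else NULL,
                          S0 = rs$S0)
  }
  out
}

#' Fit a Fine-Gray subdistribution-hazard model
#'
#' Maximizes the inverse-probability-of-censoring-weighted partial
#' likelihood of the Fine-Gray model for the ASCVD (cause 1) subdistribution
#' hazard by Newton-Raphson (all-zero start; convergence when the maximum
#' absolute score falls below `1e-9` or the relative log-likelihood change
#' below `1e-12`; at most 100 iterations; step-halving on decreases).
#' Competing-event subjects remain in the cause-1 risk set weighted by
#' `G(t-)/G(s-)` (left-continuous censoring Kaplan-Meier). Ties are handled
#' by the Breslow convention. Offset terms enter the linear predictor with
#' fixed coefficients. The covariance is the inverse observed information;
#' the baseline cumulative subdistribution hazard is the IPCW product-limit
#' estimator evaluated at the centering means (covariates are centered at
#' their transformed sample means before fitting).
#'
#' Non-convergence is reported in the returned object (`converged`,
#' `score_norm`, `iterations`), not raised as an error. A rank-deficient
#' design raises an error naming the collinear terms.
#'
#' @param data an [ascvd_cohort()]; predictors must be complete (see
#'   [impute_missing()]).
#' @param spec an [model_spec()]; defaults to the 13-predictor score
#'   specification.
#' @param tol_score,tol_loglik,max_iter convergence controls.
#' @return object of class `fine_gray_fit`.
#' @export
fit_fine_gray <- function(data, spec = smart2_model_spec(),
                          tol_score = 1e-9, tol_loglik = 1e-12,
                          max_iter = 100L) {
  df <- as.data.frame(data)
  if (!all(c("time", "cause") %in% names(df))) {
    stop("data must contain 'time' and 'cause'", call. = FALSE)
  }
  need <- c(spec$predictors, names(spec$offset_terms))
  absent <- setdiff(need, names(df))
  if (length(absent)) stop("data lacks predictor(s): ",
                           paste(absent, collapse = ", "), call. = FALSE)
  if (anyNA(df[need])) {
    stop("missing predictor values; run impute_missing() first", call. = FALSE)
  }

  Z <- build_terms(df, spec)
  mu <- colMeans(Z)
  Xc <- sweep(Z, 2L, mu, `-`)
  offset <- numeric(nrow(df))
  for (trm in names(spec$offset_terms)) {
    offset <- offset + spec$offset_terms[[trm]] * as.numeric(df[[trm]])
  }

  eng <- fg_engine(df$time, df$cause, Xc, offset,
                   tol_score = tol_score, tol_loglik = tol_loglik,
                   max_iter = max_iter, keep_internals = TRUE)
  structure(
    list(coefficients = eng$coefficients, vcov = eng$vcov,
         baseline_cumhaz = eng$baseline,
         centering_means = mu, spec = spec,
         loglik = eng$loglik, iterations = eng$iterations,
         converged = eng$converged, score_norm = eng$score_norm,
         n = nrow(df), n_events_by_cause = eng$n_events_by_cause,
         max_time = max(df$time),
         internals = eng$internals, Gminus = eng$Gminus),
    class = "fine_gray_fit")
}

# Transformed (uncentered) term matrix for the predictors of a model spec.
build_terms <- function(df, spec) {
  Z <- matrix(NA_real_, nrow(df), length(spec$predictors),
              dimnames = list(NULL, spec$predictors))
  for (trm in spec$predictors) {
    x <- as.numeric(df[[trm]])
    Z[, trm] <- switch(spec$transforms[[trm]],
                       identity = x,
                       square = x^2,
                       log = log(pmax(x, .LOG_FLOOR)))
  }
  Z
}

#' @export
print.fine_gray_fit <- function(x, ...) {
  cat(sprintf("Fine-Gray subdistribution hazard fit: n = %d (%d ASCVD events, %d competing deaths)\n",
              x$n, x$n_events_by_cause[["ascvd"]],
              x$n_events_by_cause[["competing"]]))
  print(summary_table(x), row.names = FALSE, digits = 4)
  cat(sprintf("loglik %.4f after %d iterations (%s, max|score| %.2e)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged", x$score_norm))
  invisible(x)
}

summary_table <- function(fit) {
  se <- sqrt(pmax(diag(fit$vcov), 0))
  b <- fit$coefficients
  data.frame(term = names(b), coefficient = unname(b), shr = exp(unname(b)),
             se = se, lower95 = exp(b - 1.96 * se),
             upper95 = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(b / se)))
}

#' @export
summary.fine_gray_fit <- function(object, ...) summary_table(object)

#' Export a fit summary
#'
#' Writes a human-readable text report and a machine-readable JSON twin of
#' the coefficient table (term, coefficient, subdistribution HR, SE, 95% CI,
#' p) plus convergence diagnostics.
#'
#' @param fit a [fit_fine_gray()] result.
#' @param path base path; writes `<path>.txt` and `<path>.json`.
#' @export
export_fit_summary <- function(fit, path) {
  tab <- summary_table(fit)
  txt <- c(sprintf("Fine-Gray fit: n=%d, events(ASCVD)=%d, competing=%d",
                   fit$n, fit$n_events_by_cause[["ascvd"]],
                   fit$n_events_by_cause[["competing"]]),
           utils::capture.output(print(tab, row.names = FALSE, digits = 6)),
           sprintf("loglik=%.6f iterations=%d converged=%s",
                   fit$loglik, fit$iterations, fit$converged))
  writeLines(txt, paste0(path, ".txt"))
  jsonlite::write_json(
    list(n = fit$n, n_events_by_cause = as.list(fit$n_events_by_cause),
         loglik = fit$loglik, iterations = fit$iterations,
         converged = fit$converged, table = tab),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Predict the cumulative incidence function from a fit or coefficient set
#'
#' For a `fine_gray_fit`, evaluates `1 - exp(-Lambda0(t) * exp(LP))` with
#' the estimated baseline cumulative subdistribution hazard (right-continuous
#' step function) and the centered linear predictor including offsets. For a
#' [coefficient_set()], uses the stored horizon-specific baseline survival
#' (step rule: last knot at or before the horizon).
#'
#' @param object a `fine_gray_fit` or `coefficient_set`.
#' @param record one-row data.frame, or a cohort for vectorized prediction.
#' @param horizon horizon in years.
#' @return numeric risk(s) in (0, 1).
#' @export
predict_cif <- function(object, record, horizon) {
  UseMethod("predict_cif")
}

#' @export
predict_cif.fine_gray_fit <- function(object, record, horizon) {
  if (horizon > object$max_time + 1e-9) {
    stop(sprintf("horizon %.3g beyond last baseline knot (%.3g)",
                 horizon, object$max_time), call. = FALSE)
  }
  df <- as.data.frame(record)
  Z <- build_terms(df, object$spec)
  Xc <- sweep(Z, 2L, object$centering_means, `-`)
  lp <- as.vector(Xc %*% object$coefficients)
  for (trm in names(object$spec$offset_terms)) {
    lp <- lp + object$spec$offset_terms[[trm]] * as.numeric(df[[trm]])
  }
  bl <- object$baseline_cumhaz
  i <- findInterval(horizon + 1e-12, bl$time)
  H0 <- if (i == 0L) 0 else bl$cumhaz[i]
  as.numeric(1 - exp(-H0 * exp(lp)))
}

#' @export
predict_cif.coefficient_set <- function(object, record, horizon) {
  H0 <- baseline_cumhaz_at(object, horizon)
  lp <- linear_predictor(record, object)
  total <- if (inherits(lp, "lp_breakdown")) lp$total else as.numeric(lp)
  1 - exp(-H0 * exp(total))
}
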