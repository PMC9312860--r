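# Canonical predictor schema. `continuous` fields may be imputed from
# derivation means; `binary` disease-history / treatment flags may not.
.predictors_continuous <- c(
  "age", "systolic_bp", "non_hdl", "years_since_first_ascvd", "egfr", "hscrp"
)
.predictors_binary <- c(
  "sex", "current_smoking", "diabetes", "cad", "cevd", "pad", "aaa",
  "antithrombotic_use"
)
.predictors_all <- c(.predictors_continuous, .predictors_binary)
.territories <- c("cad", "cevd", "pad", "aaa")

# mg/dL -> mmol/L divisor for cholesterol
.NON_HDL_MGDL_PER_MMOL <- 38.67

#' Construct a cohort dataset
#'
#' Bundles one row per patient: the 13 risk-score predictors, the
#' antithrombotic-use flag, and the survival outcome `(time, cause)` with
#' cause coded 0 = censored, 1 = ASCVD event (non-fatal MI, non-fatal stroke
#' or vascular death), 2 = non-cardiovascular death.
#'
#' @param data data.frame holding the predictor columns (`age`, `sex`
#'   ("male"/"female" or 0/1 male indicator), `current_smoking`,
#'   `systolic_bp` mmHg, `non_hdl` mmol/L, `diabetes`, `cad`, `cevd`, `pad`,
#'   `aaa`, `years_since_first_ascvd` years, `egfr` mL/min/1.73m2, `hscrp`
#'   mg/L, `antithrombotic_use`) and, unless supplied separately, `time`
#'   (years) and `cause`.
#' @param time,cause optional vectors overriding columns of `data`.
#' @param label cohort label carried through reports.
#' @param age_policy how to handle ages outside the supported 40-80 range:
#'   `"error"` (default) or `"clamp"` (clamp with a warning).
#' @param validate check invariants (at least one established disease
#'   territory, positive continuous values, valid cause codes).
#' @return object of class `ascvd_cohort` (a data.frame).
#' @export
ascvd_cohort <- function(data, time = NULL, cause = NULL, label = "cohort",
                         age_policy = c("error", "clamp"), validate = TRUE) {
  age_policy <- match.arg(age_policy)
  data <- as.data.frame(data)
  if (!is.null(time)) data$time <- time
  if (!is.null(cause)) data$cause <- cause
  missing_cols <- setdiff(c(.predictors_all, "time", "cause"), names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data$sex <- encode_binary(data$sex, "sex")
  for (v in setdiff(.predictors_binary, "sex")) {
    data[[v]] <- encode_binary(data[[v]], v)
  }
  if (validate) data <- validate_cohort(data, age_policy = age_policy)
  structure(data, label = label, class = c("ascvd_cohort", "data.frame"))
}

# Coerce a binary predictor to 0/1 keeping NA; sex accepts male/female labels.
encode_binary <- function(x, name) {
  if (is.character(x) || is.factor(x)) {
    x <- tolower(trimws(as.character(x)))
    if (name == "sex") {
      out <- ifelse(x %in% c("male", "m", "1"), 1,
                    ifelse(x %in% c("female", "f", "0"), 0, NA_real_))
    } else {
      out <- ifelse(x %in% c("1", "true", "yes", "y"), 1,
                    ifelse(x %in% c("0", "false", "no", "n"), 0, NA_real_))
    }
    return(out)
  }
  x <- as.numeric(x)
  x[!(x %in% c(0, 1)) & !is.na(x)] <- NA_real_
  x
}

#' Validate cohort invariants
#'
#' @inheritParams ascvd_cohort
#' @param data data.frame in canonical column layout.
#' @return the (possibly clamped) data.frame, invisibly usable.
#' @export
validate_cohort <- function(data, age_policy = c("error", "clamp")) {
  age_policy <- match.arg(age_policy)
  n <- nrow(data)
  if (n == 0L) stop("empty cohort: no parsable rows", call. = FALSE)

  terr <- as.matrix(data[.territories])
  no_terr <- rowSums(terr == 1, na.rm = TRUE) == 0 & rowSums(is.na(terr)) == 0
  if (any(no_terr)) {
    stop("rows without any established disease territory (cad/cevd/pad/aaa): ",
         paste(utils::head(which(no_terr), 5), collapse = ", "), call. = FALSE)
  }

  for (v in c("non_hdl", "hscrp", "egfr")) {
    bad <- !is.na(data[[v]]) & data[[v]] <= 0
    if (any(bad)) stop(sprintf("%s must be > 0 (rows %s)", v,
                               paste(utils::head(which(bad), 5), collapse = ", ")),
                       call. = FALSE)
  }
  bad <- !is.na(data$years_since_first_ascvd) & data$years_since_first_ascvd < 0
  if (any(bad)) stop("years_since_first_ascvd must be >= 0", call. = FALSE)

  out_of_range <- !is.na(data$age) & (data$age < 40 | data$age > 80)
  if (any(out_of_range)) {
    if (age_policy == "error") {
      stop(sprintf("age outside supported range [40, 80] in %d row(s); use age_policy = 'clamp' to clamp",
                   sum(out_of_range)), call. = FALSE)
    }
    warning(sprintf("clamping %d age value(s) into [40, 80]", sum(out_of_range)))
    data$age <- pmin(pmax(data$age, 40), 80)
  }

  if ("cause" %in% names(data)) {
    if (!all(data$cause %in% c(0, 1, 2))) {
      stop("cause must be coded 0 (censored), 1 (ASCVD) or 2 (non-CVD death)",
           call. = FALSE)
    }
    if (any(!is.finite(data$time) | data$time <= 0)) {
      stop("time must be finite and positive", call. = FALSE)
    }
  }
  data
}

#' @export
print.ascvd_cohort <- function(x, ...) {
  cat(sprintf("ASCVD cohort '%s': %d patients\n", attr(x, "label"), nrow(x)))
  if (all(c("time", "cause") %in% names(x))) {
    tab <- table(factor(x$cause, levels = 0:2))
    cat(sprintf("  censored %d | ASCVD events %d | non-CVD deaths %d\n",
                tab[1], tab[2], tab[3]))
    cat(sprintf("  median follow-up %.2f y (IQR %.2f-%.2f)\n",
                stats::median(x$time), stats::quantile(x$time, .25),
                stats::quantile(x$time, .75)))
  }
  rep <- attr(x, "read_report")
  if (!is.null(rep)) {
    cat(sprintf("  read report: %d coerced to missing, %d missing cells\n",
                rep$n_coerced, rep$n_missing))
  }
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Reads a UTF-8 delimited file (comma, semicolon or tab; auto-detected from
#' the header line), applies an optional column mapping, validates units and
#' converts unparseable cells to missing markers, counted in the attached
#' read report.
#'
#' @param path file path.
#' @param schema optional named list mapping canonical field names to file
#'   column names, e.g. `list(age = "AGE_YRS")`. Unmapped canonical names are
#'   looked up verbatim. The entry `non_hdl_unit = "mg/dL"` requests
#'   conversion of non-HDL cholesterol from mg/dL to mmol/L (divide by 38.67).
#' @param label cohort label.
#' @param age_policy passed to [ascvd_cohort()].
#' @return an [ascvd_cohort()] with attribute `read_report`
#'   (`n_coerced`, `n_missing`, per-column missing counts).
#' @export
read_cohort <- function(path, schema = list(), label = basename(path),
                        age_policy = c("error", "clamp")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- detect_delimiter(header)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           comment.char = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty input: zero parsable rows", call. = FALSE)

  unit_opts <- schema[grepl("_unit$", names(schema))]
  mapping <- schema[!grepl("_unit$", names(schema))]
  cols <- c(.predictors_all, "time", "cause")
  src <- vapply(cols, function(f) {
    if (!is.null(mapping[[f]])) mapping[[f]] else f
  }, character(1))
  absent <- cols[!src %in% names(raw)]
  if (length(absent)) {
    stop("schema error: required column(s) not found in file: ",
         paste(src[cols %in% absent], collapse = ", "), call. = FALSE)
  }

  out <- data.frame(row.names = seq_len(nrow(raw)))
  n_coerced <- 0L
  for (f in cols) {
    v <- raw[[src[[f]]]]
    if (f %in% c(.predictors_binary)) {
      parsed <- encode_binary(v, f)
    } else {
      parsed <- suppressWarnings(as.numeric(v))
    }
    n_coerced <- n_coerced + sum(!is.na(v) & is.na(parsed))
    out[[f]] <- parsed
  }
  if (!is.null(unit_opts$non_hdl_unit) &&
      tolower(unit_opts$non_hdl_unit) %in% c("mg/dl", "mgdl")) {
    out$non_hdl <- out$non_hdl / .NON_HDL_MGDL_PER_MMOL
  }
  cohort <- ascvd_cohort(out, label = label, age_policy = age_policy)
  miss <- vapply(cohort[.predictors_all], function(x) sum(is.na(x)), integer(1))
  attr(cohort, "read_report") <- list(
    n_coerced = n_coerced, n_missing = sum(miss), missing_by_column = miss
  )
  cohort
}

detect_delimiter <- function(header) {
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Write a cohort to delimited text
#'
#' Plain CSV writer; round-trips with [read_cohort()] to full double
#' precision.
#'
#' @param cohort an `ascvd_cohort`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[c(.predictors_all, "time", "cause")]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Impute missing predictor values with derivation means
#'
#' Missing continuous predictors are replaced by derivation-cohort mean
#' values on the original measurement scale (this is the single-imputation
#' behaviour of the published risk calculators). Binary disease-history and
#' treatment flags are never imputed: a missing flag is an error naming the
#' field.
#'
#' @param record one-row data.frame (or list) of predictors; or a full
#'   cohort, imputed row-wise.
#' @param means named numeric of derivation means on the original scale for
#'   the continuous predictors; defaults to the shipped synthetic derivation
#'   profile means (see [smart2_coefficients()]).
#' @return the record/cohort with missing continuous values filled in.
#' @export
impute_missing <- function(record, means = NULL) {
  if (is.null(means)) means <- attr(smart2_coefficients(), "imputation_means")
  is_cohort <- inherits(record, "ascvd_cohort") ||
    (is.data.frame(record) && nrow(record) > 1)
  rec <- as.data.frame(record)
  for (v in .predictors_binary) {
    if (v %in% names(rec) && anyNA(rec[[v]])) {
      stop(sprintf("binary predictor '%s' is missing and cannot be imputed", v),
           call. = FALSE)
    }
  }
  for (v in .predictors_continuous) {
    if (!v %in% names(rec)) next
    idx <- is.na(rec[[v]])
    if (any(idx)) {
      if (is.null(means[[v]]) || is.na(means[[v]])) {
        stop(sprintf("no imputation mean available for '%s'", v), call. = FALSE)
      }
      rec[[v]][idx] <- means[[v]]
    }
  }
  if (is_cohort && inherits(record, "ascvd_cohort")) {
    for (a in c("label", "read_report")) attr(rec, a) <- attr(record, a)
    class(rec) <- class(record)
  }
  rec
}
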