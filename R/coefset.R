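.transform_names <- c("identity", "log", "square")

#' Construct a coefficient set
#'
#' A coefficient set is the complete definition of a subdistribution-hazard
#' risk score: per-term log-subdistribution-hazard coefficients, the
#' transformation applied to each predictor before the coefficient, the
#' derivation means of the transformed terms (the centering point at which
#' the baseline survival is defined), horizon-specific baseline survival
#' S0(t), the fixed antithrombotic offset hazard ratio, and per-region
#' multiplicative recalibration factors on the baseline cumulative hazard.
#'
#' @param coefficients named numeric, log-subdistribution-hazard coefficient
#'   per predictor term (per unit of the transformed value).
#' @param transforms named character, one of `"identity"`, `"log"`,
#'   `"square"` per predictor named in `coefficients`.
#' @param centering_means named numeric, derivation mean of each transformed
#'   term (same names as `coefficients`).
#' @param baseline_survival named numeric, horizon (years, as names) to
#'   S0(horizon); strictly decreasing in the horizon, all values in (0,1).
#' @param offset_hr fixed antithrombotic-therapy hazard ratio (> 0).
#' @param offset_term predictor flag the offset attaches to.
#' @param region_factors named list or numeric: region id to recalibration
#'   factor (> 0); an entry may itself be a named numeric keyed by horizon.
#' @param baseline_convention `"survival"` if `baseline_survival` holds
#'   S0(t), `"cumhaz"` if it holds the baseline cumulative subdistribution
#'   hazard (converted to survival on construction).
#' @param id,version identifiers carried through files and logs.
#' @return object of class `coefficient_set`.
#' @export
coefficient_set <- function(coefficients, transforms, centering_means,
                            baseline_survival, offset_hr = 0.81,
                            offset_term = "antithrombotic_use",
                            region_factors = list(),
                            baseline_convention = c("survival", "cumhaz"),
                            id = "unnamed", version = "1") {
  baseline_convention <- match.arg(baseline_convention)
  coefficients <- unlist(coefficients)
  centering_means <- unlist(centering_means)
  transforms <- vapply(transforms, as.character, character(1))
  baseline_survival <- unlist(baseline_survival)
  if (baseline_convention == "cumhaz") {
    baseline_survival <- exp(-baseline_survival)
  }
  region_factors <- lapply(region_factors, unlist)
  x <- structure(
    list(coefficients = coefficients, transforms = transforms,
         centering_means = centering_means,
         baseline_survival = baseline_survival,
         offset_hr = offset_hr, offset_term = offset_term,
         region_factors = region_factors,
         id = id, version = version),
    class = "coefficient_set")
  validate_coefficient_set(x)
  x
}

#' @rdname coefficient_set
#' @param x a `coefficient_set`.
#' @export
validate_coefficient_set <- function(x) {
  stopifnot(inherits(x, "coefficient_set"))
  terms <- names(x$coefficients)
  if (is.null(terms) || anyDuplicated(terms)) {
    stop("coefficients must be uniquely named", call. = FALSE)
  }
  bad_tr <- setdiff(unname(x$transforms), .transform_names)
  if (length(bad_tr)) {
    stop("unknown transform name(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  for (trm in names(x$transforms)) {
    if (!trm %in% terms) {
      stop(sprintf("transform declared for '%s' but no coefficient", trm),
           call. = FALSE)
    }
  }
  missing_tr <- setdiff(terms, names(x$transforms))
  if (length(missing_tr)) {
    stop("terms without a declared transform: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  missing_mu <- setdiff(terms, names(x$centering_means))
  if (length(missing_mu)) {
    stop("terms without a centering mean: ",
         paste(missing_mu, collapse = ", "), call. = FALSE)
  }
  bs <- x$baseline_survival
  h <- as.numeric(names(bs))
  if (anyNA(h)) stop("baseline_survival names must be numeric horizons", call. = FALSE)
  bs <- bs[order(h)]
  if (any(bs <= 0 | bs >= 1)) {
    stop("baseline survival values must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(diff(bs) >= 0)) {
    stop("baseline survival must be strictly decreasing in the horizon",
         call. = FALSE)
  }
  if (!is.numeric(x$offset_hr) || x$offset_hr <= 0) {
    stop("offset_hr must be > 0", call. = FALSE)
  }
  if (any(unlist(x$region_factors) <= 0)) {
    stop("all region factors must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("Coefficient set '%s' (version %s)\n", x$id, x$version))
  df <- data.frame(
    term = names(x$coefficients),
    transform = unname(x$transforms[names(x$coefficients)]),
    coefficient = unname(x$coefficients),
    shr = exp(unname(x$coefficients)),
    centering_mean = unname(x$centering_means[names(x$coefficients)])
  )
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("offset: %s, HR %.4g\n", x$offset_term, x$offset_hr))
  cat("baseline survival:",
      paste(sprintf("S0(%s)=%.4f", names(x$baseline_survival),
                    x$baseline_survival), collapse = "  "), "\n")
  if (length(x$region_factors)) {
    cat("region factors:",
        paste(sprintf("%s=%s", names(x$region_factors),
                      vapply(x$region_factors, function(f)
                        paste(signif(f, 4), collapse = "/"), character(1))),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Save / load a coefficient set
#'
#' Coefficient sets are stored as versioned JSON documents. Numeric fields
#' are written at full double precision so that `load(save(x))` reproduces
#' `x` bit for bit; invariants are re-checked on load.
#'
#' @param x a [coefficient_set()].
#' @param path file path (JSON).
#' @export
save_coefficient_set <- function(x, path) {
  validate_coefficient_set(x)
  doc <- list(
    format = "smart2risk/coefficient-set",
    schema_version = "1.0",
    id = x$id, version = x$version,
    baseline_convention = "survival",
    coefficients = as.list(x$coefficients),
    transforms = as.list(x$transforms),
    centering_means = as.list(x$centering_means),
    baseline_survival = as.list(x$baseline_survival),
    offset_hr = x$offset_hr, offset_term = x$offset_term,
    region_factors = lapply(x$region_factors, as.list)
  )
  extra <- attr(x, "imputation_means")
  if (!is.null(extra)) doc$imputation_means <- as.list(extra)
  # 17 significant digits round-trip IEEE doubles bit for bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_coefficient_set
#' @export
load_coefficient_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "smart2risk/coefficient-set") {
    stop("not a coefficient-set document: ", path, call. = FALSE)
  }
  rf <- doc$region_factors
  if (is.null(rf)) rf <- list()
  rf <- lapply(rf, function(f) unlist(f))
  x <- coefficient_set(
    coefficients = unlist(doc$coefficients),
    transforms = unlist(doc$transforms),
    centering_means = unlist(doc$centering_means),
    baseline_survival = unlist(doc$baseline_survival),
    offset_hr = doc$offset_hr,
    offset_term = if (is.null(doc$offset_term)) "antithrombotic_use" else doc$offset_term,
    region_factors = rf,
    baseline_convention = if (identical(doc$baseline_convention, "cumhaz"))
      "cumhaz" else "survival",
    id = doc$id, version = as.character(doc$version)
  )
  if (!is.null(doc$imputation_means)) {
    attr(x, "imputation_means") <- unlist(doc$imputation_means)
  }
  x
}

#' The shipped default SMART2 coefficient set
#'
#' Loads the packaged default coefficient set for the SMART2 recurrent-ASCVD
#' score. The subdistribution hazard ratios for the binary predictors and
#' the antithrombotic offset (HR 0.81) are the published values; per-unit
#' coefficients for the transformed continuous predictors are converted from
#' the published quartile-contrast hazard ratios using the synthetic
#' derivation profile's quartiles, and the centering means and baseline
#' survival are derived from the packaged synthetic derivation profile (the
#' exact derivation-cohort values are not public). The file is therefore a
#' synthetic stand-in, suitable for methodological work, not clinical use.
#'
#' @return a [coefficient_set()].
#' @export
smart2_coefficients <- function() {
  path <- system.file("extdata", "smart2_synthetic_default.json",
                      package = "smart2risk")
  if (!nzchar(path)) stop("shipped coefficient set not found", call. = FALSE)
  load_coefficient_set(path)
}

#' Region registry
#'
#' The nine recalibration regions of the score: the four European risk
#' regions (grouped by age- and sex-standardised ASCVD mortality, as for
#' SCORE2) plus Asia (excluding Japan), Japan, Australia, North America and
#' Latin America. Region factors in a coefficient set are keyed by these
#' ids.
#'
#' @return data.frame with columns `region` (id) and `label`.
#' @export
region_registry <- function() {
  data.frame(
    region = c("europe_low", "europe_moderate", "europe_high",
               "europe_very_high", "asia_excl_japan", "japan", "australia",
               "north_america", "latin_america"),
    label = c("Europe, low risk", "Europe, moderate risk",
              "Europe, high risk", "Europe, very high risk",
              "Asia (excluding Japan)", "Japan", "Australia",
              "North America", "Latin America"),
    stringsAsFactors = FALSE
  )
}

# Look up the recalibration factor for (region, horizon); scalar entries
# apply to all horizons, named entries are keyed by horizon.
region_factor <- function(coefset, region, horizon) {
  if (!region %in% region_registry()$region) {
    stop("unknown region id: ", region, call. = FALSE)
  }
  f <- coefset$region_factors[[region]]
  if (is.null(f)) return(1)
  if (length(f) == 1L && is.null(names(f))) return(unname(f))
  key <- as.character(horizon)
  if (!is.null(names(f)) && key %in% names(f)) return(unname(f[[key]]))
  if (length(f) == 1L) return(unname(f[[1L]]))
  stop(sprintf("no recalibration factor for region '%s' at horizon %s",
               region, key), call. = FALSE)
}
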