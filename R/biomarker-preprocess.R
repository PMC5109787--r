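#' Classify and transform one biomarker column
#'
#' Applies the detectability rules for assay panels: columns with < 15%
#' undetectable values are treated as continuous (undetectables set to the
#' detection limit, missing values imputed with the median, optionally
#' log-transformed, then standardized to mean 0 / variance 1); columns with
#' 15-50% undetectables are dichotomized at their median; columns with
#' 50-90% undetectables are dichotomized at the detection limit (detectable
#' vs not); columns with > 90% undetectables are dropped. Boundary
#' convention: `[15, 50)` median-dichotomized, `[50, 90]` detection-limit
#' dichotomized, so the bins partition `[0, 100]`.
#'
#' @param values numeric vector; `NA` marks missing, `undetectable` marks
#'   below-detection measurements.
#' @param undetectable logical vector flagging undetectable entries.
#' @param detection_limit assay detection limit; required when any entry is
#'   undetectable.
#' @param log_transform `"auto"` (log-transform when skewness > 1), `"on"`,
#'   or `"off"`; continuous columns only. Values are shifted to stay
#'   positive before the log when needed.
#' @return list with `type` (`"continuous"`, `"median_dichotomized"`,
#'   `"detection_limit_dichotomized"`, or `"dropped"`), `values` (processed
#'   column, `NULL` when dropped), and `params` (decisions taken).
#' @export
classify_and_transform <- function(values, undetectable = rep(FALSE, length(values)),
                                   detection_limit = NA_real_,
                                   log_transform = c("auto", "on", "off")) {
  log_transform <- match.arg(log_transform)
  stopifnot(length(undetectable) == length(values))
  if (all(is.na(values) & !undetectable)) stop("column is entirely missing")
  if (any(undetectable) && is.na(detection_limit))
    stop("undetectable values present but no detection limit given")
  pct_undet <- 100 * mean(undetectable)
  if (pct_undet > 90) {
    return(list(type = "dropped", values = NULL,
                params = list(pct_undetectable = pct_undet)))
  }
  if (pct_undet >= 50) {
    v <- as.numeric(!undetectable)
    return(list(type = "detection_limit_dichotomized", values = v,
                params = list(pct_undetectable = pct_undet,
                              detection_limit = detection_limit)))
  }
  x <- values
  x[undetectable] <- detection_limit
  if (pct_undet >= 15) {
    med <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- med
    return(list(type = "median_dichotomized", values = as.numeric(x >= med),
                params = list(pct_undetectable = pct_undet, cutpoint = med)))
  }
  # continuous: impute, maybe log, standardize
  med <- stats::median(x, na.rm = TRUE)
  n_imputed <- sum(is.na(x))
  x[is.na(x)] <- med
  logged <- FALSE
  if (log_transform == "on" ||
      (log_transform == "auto" && e1071::skewness(x) > 1)) {
    shift <- if (min(x) <= 0) 1 - min(x) else 0
    x <- log(x + shift)
    logged <- TRUE
  }
  s <- stats::sd(x)
  if (s == 0) stop("column is constant after processing")
  x <- (x - mean(x)) / s
  list(type = "continuous", values = x,
       params = list(pct_undetectable = pct_undet, n_imputed = n_imputed,
                     log_transformed = logged))
}

parse_biomarker_column <- function(raw, sentinel = "<LOD") {
  raw <- trimws(as.character(raw))
  undet <- raw == sentinel & !is.na(raw)
  miss <- is.na(raw) | raw == ""
  vals <- suppressWarnings(as.numeric(raw))
  vals[undet | miss] <- NA_real_
  bad <- !miss & !undet & is.na(vals)
  if (any(bad)) stop("non-numeric entries that are neither blank nor '",
                     sentinel, "'")
  list(values = vals, undetectable = undet)
}

#' Build a modelling dataset from a biomarker table
#'
#' Applies [classify_and_transform()] to every biomarker column of a
#' subjects-by-biomarkers table (CSV path or `data.frame`), drops columns
#' failing the > 90% undetectability rule, and assembles the design matrix
#' together with a per-column processing manifest. Undetectable entries are
#' encoded with a sentinel string; missing entries are blank/`NA`.
#'
#' @param table CSV file path or `data.frame`.
#' @param outcome_column name of the 0/1 outcome column.
#' @param detection_limits named numeric vector of per-column detection
#'   limits (needed only for columns with undetectables).
#' @param sentinel string encoding undetectable measurements.
#' @param log_transform passed to [classify_and_transform()].
#' @return list with `X` (numeric design matrix), `y` (outcome vector), and
#'   `manifest` (`data.frame` of per-column decisions).
#' @export
build_design_matrix <- function(table, outcome_column,
                                detection_limits = numeric(0),
                                sentinel = "<LOD",
                                log_transform = "auto") {
  df <- if (is.character(table))
    utils::read.csv(table, stringsAsFactors = FALSE, colClasses = "character")
  else table
  if (!outcome_column %in% names(df)) stop("outcome column not found")
  y <- as.numeric(as.character(df[[outcome_column]]))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  markers <- setdiff(names(df), outcome_column)
  cols <- list()
  manifest <- list()
  for (nm in markers) {
    parsed <- parse_biomarker_column(df[[nm]], sentinel)
    dl <- if (nm %in% names(detection_limits)) detection_limits[[nm]] else NA_real_
    res <- classify_and_transform(parsed$values, parsed$undetectable, dl,
                                  log_transform)
    manifest[[length(manifest) + 1L]] <- data.frame(
      name = nm, type = res$type,
      pct_undetectable = res$params$pct_undetectable,
      log_transformed = isTRUE(res$params$log_transformed))
    if (res$type != "dropped") cols[[nm]] <- res$values
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, y = y, manifest = do.call(rbind, manifest))
}
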