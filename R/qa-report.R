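#' @include constructors.R utils.R
NULL

#' Parse a tolerance specification string
#'
#' Accepted forms mirror how tolerances are printed in QA tables:
#' `"> 59"`, `"< 47"`, `">= 1"`, `"<= 20"` and closed intervals
#' `"4.65-5.15"`. Strict operators are strict: a value on the boundary of
#' `"< 47"` fails; boundaries of `">="`/`"<="`/intervals pass.
#'
#' @param text tolerance string.
#' @return list with `op` (`gt`, `lt`, `ge`, `le`, `interval`) and
#'   `limit` (scalar) or `lo`/`hi`
#' @export
parseToleranceSpec <- function(text) {
  t <- gsub("\\s+", "", text)
  if (grepl("^>=", t)) return(list(op = "ge", limit = as.numeric(sub("^>=", "", t))))
  if (grepl("^<=", t)) return(list(op = "le", limit = as.numeric(sub("^<=", "", t))))
  if (grepl("^>", t)) return(list(op = "gt", limit = as.numeric(sub("^>", "", t))))
  if (grepl("^<", t)) return(list(op = "lt", limit = as.numeric(sub("^<", "", t))))
  m <- regmatches(t, regexec("^(-?[0-9.]+)-([0-9.]+)$", t))[[1]]
  if (length(m) == 3) {
    lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
    if (is.na(lo) || is.na(hi) || lo > hi)
      stop("config error: malformed interval tolerance: ", text)
    return(list(op = "interval", lo = lo, hi = hi))
  }
  stop("config error: malformed tolerance spec: ", text)
}

#' Evaluate a metric value against its tolerance
#'
#' @param value measured metric value.
#' @param tolerance a string (see [parseToleranceSpec()]) or an
#'   already-parsed list.
#' @param metric metric name.
#' @param date ISO-8601 date string or `Date` (optional).
#' @param units units string.
#' @param context free-text context (sequence, coil, echo index).
#' @return one-row data.frame (a QA record) with columns `date`, `metric`,
#'   `value`, `units`, `tolerance`, `pass`, `context`
#' @examples
#' evaluateTolerance(69.3, "> 59", metric = "SNR")$pass   # TRUE
#' evaluateTolerance(47, "< 47", metric = "uniformity")$pass  # FALSE
#' @export
evaluateTolerance <- function(value, tolerance, metric = "", date = NA,
                              units = "", context = "") {
  spec <- if (is.character(tolerance)) parseToleranceSpec(tolerance)
          else tolerance
  if (!is.list(spec) || is.null(spec$op))
    stop("config error: malformed tolerance spec")
  pass <- switch(spec$op,
    gt = value > spec$limit,
    lt = value < spec$limit,
    ge = value >= spec$limit,
    le = value <= spec$limit,
    interval = value >= spec$lo & value <= spec$hi,
    stop("config error: unknown tolerance operator: ", spec$op))
  tolText <- if (is.character(tolerance)) tolerance else
    switch(spec$op,
           gt = paste0("> ", spec$limit), lt = paste0("< ", spec$limit),
           ge = paste0(">= ", spec$limit), le = paste0("<= ", spec$limit),
           interval = paste0(spec$lo, "-", spec$hi))
  data.frame(date = as.character(date), metric = metric, value = value,
             units = units, tolerance = tolText, pass = pass,
             context = context, stringsAsFactors = FALSE)
}

parseIsoDates <- function(dates) {
  if (inherits(dates, "Date")) return(dates)
  out <- as.Date(as.character(dates), format = "%Y-%m-%d")
  if (anyNA(out)) stop("dates must be ISO-8601 (YYYY-MM-DD)")
  out
}

#' Longitudinal trend of a QA metric
#'
#' Ordinary least squares of value on date. With `normalize = TRUE` the
#' slope is expressed in percent of the baseline (the fitted value at the
#' first date) per day; either way the annualized slope multiplies by
#' 365.25. Sustained shifts are flagged by a two-sided CUSUM against the
#' mean and SD of the first `baselineN` sessions: the reported change
#' point is the first date after the last CUSUM zero preceding a
#' threshold crossing.
#'
#' @param values metric values.
#' @param dates ISO-8601 strings or `Date`, same length (>= 3, not all
#'   equal).
#' @param normalize report the slope as percent of baseline (default).
#' @param cusumThreshold decision threshold in baseline SDs (default 4).
#' @param cusumSlack allowance per step in baseline SDs (default 0.5).
#' @param baselineN sessions used for the CUSUM baseline (default 30,
#'   capped at half the series).
#' @return a [TrendResult-class]
#' @export
fitTrend <- function(values, dates, normalize = TRUE, cusumThreshold = 4,
                     cusumSlack = 0.5, baselineN = 30) {
  dates <- parseIsoDates(dates)
  if (length(values) < 3) stop("need >= 3 dated points")
  if (length(unique(dates)) == 1) stop("degenerate fit: all dates equal")
  t <- as.numeric(dates - min(dates))
  fit <- stats::lm.fit(cbind(1, t), values)
  slope <- fit$coefficients[2]
  baseline <- fit$coefficients[1]  # fitted value at the first date
  if (normalize) {
    if (baseline == 0) stop("cannot normalize: baseline is zero")
    slope <- slope / baseline * 100
  }
  mu <- mean(values)
  cov <- if (mu == 0) NA_real_ else
    sqrt(mean((values - mu)^2)) / abs(mu) * 100

  nb <- min(baselineN, floor(length(values) / 2))
  base <- values[seq_len(max(2, nb))]
  mu0 <- mean(base); sd0 <- stats::sd(base)
  changePoints <- as.Date(character())
  if (sd0 == 0) {
    dev <- which(values != mu0)
    if (length(dev)) changePoints <- dates[min(dev)]
  } else {
    z <- (values - mu0) / sd0
    for (sgn in c(1, -1)) {
      s <- 0; lastZero <- 0L
      for (i in seq_along(z)) {
        s <- max(0, s + sgn * z[i] - cusumSlack)
        if (s == 0) lastZero <- i
        if (s > cusumThreshold) {
          changePoints <- c(changePoints, dates[lastZero + 1L])
          break
        }
      }
    }
    changePoints <- sort(unique(changePoints))
  }
  new("TrendResult", slopePerDay = unname(slope),
      slopePerYear = unname(slope) * 365.25,
      intercept = unname(baseline), covPercent = cov,
      normalized = normalize, changePoints = changePoints)
}

#' Render a QA report as deterministic JSON
#'
#' Collects QA records and trend results into a JSON document with fixed
#' key order and number formatting, so identical inputs produce
#' byte-identical files. Failing records are listed separately.
#'
#' @param records data.frame of QA records (rows from
#'   [evaluateTolerance()]); may be empty.
#' @param trends named list of [TrendResult-class] (optional).
#' @param file path to write; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to file
#' @export
renderReport <- function(records = NULL, trends = list(), file = NULL) {
  if (is.null(records) || !nrow(records))
    records <- data.frame(date = character(), metric = character(),
                          value = numeric(), units = character(),
                          tolerance = character(), pass = logical(),
                          context = character(), stringsAsFactors = FALSE)
  records <- records[order(records$date, records$metric), , drop = FALSE]
  failures <- records[!records$pass, , drop = FALSE]
  trendList <- lapply(trends, function(tr) list(
    slope_per_day = tr@slopePerDay,
    slope_per_year = tr@slopePerYear,
    normalized = tr@normalized,
    cov_percent = tr@covPercent,
    change_points = as.character(tr@changePoints)))
  doc <- list(
    n_records = nrow(records),
    n_failures = nrow(failures),
    failures = failures,
    records = records,
    trends = trendList)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows", na = "null")
  if (is.null(file)) return(as.character(json))
  writeLines(as.character(json), file)
  invisible(as.character(json))
}

#' Write a QA record log as CSV (stable column order)
#'
#' @param records data.frame of QA records.
#' @param path CSV file path.
#' @return invisibly, the path
#' @export
writeQaLog <- function(records, path) {
  cols <- c("date", "metric", "value", "units", "tolerance", "pass", "context")
  utils::write.csv(records[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a QA record log written by [writeQaLog()]
#'
#' @param path CSV file path.
#' @return data.frame of QA records
#' @export
readQaLog <- function(path) {
  utils::read.csv(path, colClasses = c(
    date = "character", metric = "character", value = "numeric",
    units = "character", tolerance = "character", pass = "logical",
    context = "character"))
}

#' Load the default PIQT and distortion tolerance tables
#'
#' Tolerances for SNR, uniformity, slice profile FWHM/integral, pixel
#' size, linearity and per-DSV distortion, as shipped in
#' `inst/extdata/tolerances.json`.
#'
#' @return nested list keyed by test and sequence/echo
#' @export
defaultTolerances <- function() {
  jsonlite::fromJSON(system.file("extdata", "tolerances.json",
                                 package = "mrlqa", mustWork = TRUE),
                     simplifyVector = FALSE)
}
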