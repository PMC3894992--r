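# VFSeries construction, file formats and data-curation rules.

#' Construct a visual-field series
#'
#' @param times test times in years from the first retained test.
#' @param values Q x M sensitivity matrix (dB).
#' @param grid the \linkS4class{VisualFieldGrid}.
#' @param eyeId identifier.
#' @return a \linkS4class{VFSeries}.
#' @export
vfSeries <- function(times, values, grid, eyeId = "eye") {
  v <- if (is.matrix(values)) {
    storage.mode(values) <- "numeric"
    unname(values)
  } else {
    matrix(as.numeric(values), nrow = length(times))
  }
  new("VFSeries", times = as.numeric(times), values = v,
      grid = grid, eyeId = as.character(eyeId))
}

#' Read / write visual-field series files
#'
#' Two CSV layouts are supported and auto-detected: wide
#' (`eye_id, test_date_years, loc_0 ... loc_<M-1>`) and long
#' (`eye_id, time, location_index, dls`). The writer emits the long format.
#'
#' @param path CSV path.
#' @param grid the \linkS4class{VisualFieldGrid} columns refer to.
#' @return `readVfSeries` returns a list of \linkS4class{VFSeries} (one per
#'   eye_id in the file).
#' @export
readVfSeries <- function(path, grid) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- nLocations(grid)
  if (any(grepl("^loc_\\d+$", names(df)))) {
    cols <- paste0("loc_", 0:(m - 1))
    if (!all(cols %in% names(df)))
      stop("wide series file must have columns loc_0 .. loc_", m - 1)
    out <- lapply(split(df, df$eye_id), function(d) {
      d <- d[order(d$test_date_years), , drop = FALSE]
      vfSeries(d$test_date_years, as.matrix(d[, cols]), grid,
               eyeId = d$eye_id[1])
    })
  } else {
    need <- c("eye_id", "time", "location_index", "dls")
    if (!all(need %in% names(df)))
      stop("long series file must have columns ", paste(need, collapse = ", "))
    out <- lapply(split(df, df$eye_id), function(d) {
      tm <- sort(unique(d$time))
      v <- matrix(NA_real_, length(tm), m)
      v[cbind(match(d$time, tm), d$location_index + 1L)] <- d$dls
      if (anyNA(v)) stop("missing per-location values in series for eye ",
                         d$eye_id[1], " (the model assumes complete fields)")
      vfSeries(tm, v, grid, eyeId = d$eye_id[1])
    })
  }
  unname(out)
}

#' @rdname readVfSeries
#' @param series a \linkS4class{VFSeries}.
#' @export
writeVfSeries <- function(series, path) {
  q <- length(series@times); m <- nLocations(series@grid)
  df <- data.frame(
    eye_id = series@eyeId,
    time = rep(series@times, m),
    location_index = rep(0:(m - 1), each = q),
    dls = as.vector(series@values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Curation policy for raw series
#'
#' @param dropFirstTest discard the first test of each series (learning
#'   effects).
#' @param sameDayRule what to keep when several tests share a date ("last").
#' @param minTests minimum number of tests after curation (>= 3).
#' @param minSpanYears minimum follow-up span after curation.
#' @return a list of class `CurationPolicy`.
#' @export
curationPolicy <- function(dropFirstTest = TRUE, sameDayRule = "last",
                           minTests = 3, minSpanYears = 0) {
  stopifnot(minTests >= 3, sameDayRule == "last")
  structure(list(dropFirstTest = dropFirstTest, sameDayRule = sameDayRule,
                 minTests = minTests, minSpanYears = minSpanYears),
            class = "CurationPolicy")
}

#' Curate a raw series table into an analysable series
#'
#' Applies, in order: the same-day rule (keep the last test of a day), the
#' drop-first-test rule, and the minimum-count / minimum-span filters. Times
#' are re-expressed in years from the first retained test.
#'
#' @param raw data.frame in the wide layout (`eye_id`, `test_date_years` or
#'   ISO-8601 `test_date`, `loc_0 ...`).
#' @param grid the \linkS4class{VisualFieldGrid}.
#' @param policy a [curationPolicy()].
#' @return a \linkS4class{VFSeries}, or a list
#'   `list(rejected = TRUE, reason = <rule>)` when a filter rejects the
#'   series.
#' @export
curateSeries <- function(raw, grid, policy = curationPolicy()) {
  if (nrow(raw) == 0) return(list(rejected = TRUE, reason = "empty"))
  if ("test_date" %in% names(raw)) {
    d <- as.Date(raw$test_date, format = "%Y-%m-%d")
    if (anyNA(d))
      stop("unparseable test_date in row(s): ",
           paste(which(is.na(d)), collapse = ", "))
    raw$test_date_years <- as.numeric(d - min(d)) / 365.25
  }
  raw <- raw[order(raw$test_date_years), , drop = FALSE]
  # same-day rule: keep the last measurement of each day
  day <- floor(raw$test_date_years * 365.25 + 1e-9)
  keep <- !duplicated(day, fromLast = TRUE)
  raw <- raw[keep, , drop = FALSE]
  if (policy$dropFirstTest) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) < policy$minTests)
    return(list(rejected = TRUE, reason = "min_tests"))
  span <- diff(range(raw$test_date_years))
  if (span < policy$minSpanYears)
    return(list(rejected = TRUE, reason = "min_span_years"))
  cols <- grep("^loc_\\d+$", names(raw), value = TRUE)
  cols <- paste0("loc_", 0:(nLocations(grid) - 1))
  if (!all(cols %in% names(raw))) stop("missing location columns")
  v <- as.matrix(raw[, cols])
  if (anyNA(v)) stop("missing per-location values (complete fields required)")
  vfSeries(raw$test_date_years - raw$test_date_years[1], v, grid,
           eyeId = as.character(raw$eye_id[1]))
}

#' Write an analysis result as JSON
#'
#' @param estimate a \linkS4class{PosteriorEstimate}.
#' @param path output path.
#' @param seed RNG seed to record, if any.
#' @param config configuration list to hash into the output, if any.
#' @export
writeAnalysisResult <- function(estimate, path, seed = NULL, config = NULL) {
  obj <- list(
    eye_id = estimate@eyeId, mode = estimate@mode,
    slopes = estimate@slopes, intercepts = estimate@intercepts,
    slope_sds = slopeSD(estimate), pnd = estimate@pnd,
    s_d = estimate@sD, s_i = estimate@sI,
    converged = estimate@converged,
    package_version = as.character(utils::packageVersion("answers")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else .configHash(config))
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
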