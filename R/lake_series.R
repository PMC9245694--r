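#' Multivariate lake monitoring time series
#'
#' A `lake_series` is a data frame with a `time` column (Date or numeric) and
#' one column per monitored variable, on a (possibly irregular) increasing
#' time grid. The canonical variable set for deep-lake oxygen work is:
#' `DO_B` (deep-water dissolved oxygen, mg/L), `chl` (chlorophyll-a, ug/L),
#' `TP_surf` (epilimnion total phosphorus, ug/L), `TP_lake`
#' (hypsometry-integrated total phosphorus, ug/L), `h_mix` (thermocline /
#' mixed-layer depth, m), `T_surf` (epilimnion temperature, degC), `T_atm`
#' (air temperature, degC) and `Q` (river discharge, m3/s) — but any named
#' numeric columns are accepted.
#'
#' @param data data frame containing a `time` column plus numeric variable
#'   columns.
#' @param units optional named character vector of units, one per variable.
#' @return an object of class `lake_series` (a data frame).
#' @export
lake_series <- function(data, units = NULL) {
  stopifnot(is.data.frame(data))
  if (!"time" %in% names(data)) stop("`data` must contain a `time` column")
  tnum <- as.numeric(data$time)
  if (anyNA(tnum)) stop("`time` contains missing values")
  if (is.unsorted(tnum, strictly = TRUE)) {
    stop("`time` must be strictly increasing")
  }
  vars <- setdiff(names(data), "time")
  if (length(vars) == 0L) stop("no variable columns in `data`")
  for (v in vars) {
    if (!is.numeric(data[[v]])) stop("variable `", v, "` is not numeric")
  }
  conc <- intersect(vars, c("DO_B", "chl", "TP_surf", "TP_lake", "Q"))
  for (v in conc) {
    if (any(data[[v]] < 0, na.rm = TRUE)) {
      stop("variable `", v, "` has negative values")
    }
  }
  structure(as.data.frame(data), units = units, class = c("lake_series", "data.frame"))
}

#' @export
print.lake_series <- function(x, ...) {
  vars <- setdiff(names(x), "time")
  cat("<lake_series> ", nrow(x), " time points, ",
      length(vars), " variables: ", paste(vars, collapse = ", "), "\n", sep = "")
  invisible(x)
}

lake_vars <- function(ts) setdiff(names(ts), "time")

#' Regularize a lake series onto a uniform grid
#'
#' Interpolates each variable linearly onto a uniform time grid. Gaps wider
#' than `max_gap` grid steps between consecutive observations are left
#' missing rather than bridged, so long monitoring outages are never filled
#' by interpolation.
#'
#' @param ts a [lake_series()].
#' @param step grid step: `"month"` for Date-indexed series, or a numeric
#'   spacing for numeric time.
#' @param max_gap maximum gap (in grid steps) that linear interpolation may
#'   bridge; default 3.
#' @return a [lake_series()] on the uniform grid (a `step` attribute records
#'   the spacing).
#' @export
regularize <- function(ts, step = "month", max_gap = 3) {
  stopifnot(inherits(ts, "lake_series"))
  vars <- lake_vars(ts)
  for (v in vars) {
    if (all(is.na(ts[[v]]))) stop("variable `", v, "` has no observations")
    if (sum(!is.na(ts[[v]])) < 2L) stop("variable `", v, "` has < 2 observations")
  }
  if (identical(step, "month")) {
    if (!inherits(ts$time, "Date")) stop("step = \"month\" needs a Date time column")
    t0 <- as.Date(format(min(ts$time), "%Y-%m-01"))
    t1 <- as.Date(format(max(ts$time), "%Y-%m-01"))
    grid <- seq(t0, t1, by = "month")
    # fractional month index of each observation
    midx <- function(d) {
      as.numeric(format(d, "%Y")) * 12 + as.numeric(format(d, "%m")) +
        (as.numeric(format(d, "%d")) - 1) / 31
    }
    tx <- midx(ts$time); gx <- midx(grid)
  } else {
    stopifnot(is.numeric(step), step > 0)
    grid <- seq(min(as.numeric(ts$time)), max(as.numeric(ts$time)), by = step)
    tx <- as.numeric(ts$time); gx <- grid
  }
  out <- data.frame(time = grid)
  gap_steps <- if (identical(step, "month")) 1 else step
  for (v in vars) {
    ok <- !is.na(ts[[v]])
    y <- stats::approx(tx[ok], ts[[v]][ok], xout = gx, rule = 1)$y
    # mask grid points bridged by an observation gap wider than max_gap steps
    prev_obs <- stats::approx(tx[ok], tx[ok], xout = gx, method = "constant",
                              f = 0, rule = 2)$y
    next_obs <- stats::approx(tx[ok], tx[ok], xout = gx, method = "constant",
                              f = 1, rule = 2)$y
    y[(next_obs - prev_obs) > max_gap * gap_steps + 1e-9] <- NA_real_
    out[[v]] <- y
  }
  res <- lake_series(out, units = attr(ts, "units"))
  attr(res, "step") <- step
  res
}

#' Read a lake series from CSV
#'
#' Accepts either wide format (a `time`/`date` column plus one column per
#' variable) or tidy long format with columns `date`, `variable`, `value`
#' (and optionally `unit`).
#'
#' @param path CSV file path.
#' @return a [lake_series()].
#' @export
read_lake_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  if (all(c("variable", "value") %in% nm)) {
    names(df) <- nm
    tcol <- if ("date" %in% nm) "date" else "time"
    units <- NULL
    if ("unit" %in% nm) {
      u <- unique(df[, c("variable", "unit")])
      units <- stats::setNames(u$unit, u$variable)
    }
    wide <- stats::reshape(df[, c(tcol, "variable", "value")],
                           idvar = tcol, timevar = "variable",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    names(wide)[1] <- "time"
    wide$time <- parse_time(wide$time)
    wide <- wide[order(as.numeric(wide$time)), , drop = FALSE]
    rownames(wide) <- NULL
    return(lake_series(wide, units = units))
  }
  tcol <- intersect(c("time", "date"), nm)[1]
  if (is.na(tcol)) stop("no time/date column in ", path)
  names(df)[nm == tcol] <- "time"
  df$time <- parse_time(df$time)
  lake_series(df[order(as.numeric(df$time)), , drop = FALSE])
}

parse_time <- function(x) {
  if (is.numeric(x)) return(x)
  d <- as.Date(x)
  if (anyNA(d)) stop("unparseable dates in time column")
  d
}

#' Write a lake series to CSV
#'
#' @param ts a [lake_series()].
#' @param path output path.
#' @param format `"wide"` (default) or `"long"` tidy format.
#' @return `path`, invisibly.
#' @export
write_lake_csv <- function(ts, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  } else {
    vars <- lake_vars(ts)
    units <- attr(ts, "units")
    long <- do.call(rbind, lapply(vars, function(v) {
      data.frame(date = ts$time, variable = v, value = ts[[v]],
                 unit = if (!is.null(units) && v %in% names(units)) units[[v]] else "")
    }))
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
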