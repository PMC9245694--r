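#' Daily physical forcing series
#'
#' A data frame on a daily grid with columns `date`, `thermocline_depth_m`,
#' `T_surf_C`, `mixing_depth_m`, `Q_m3s`, `T_river_C`, `T_atm_C`. Produced
#' either by [surrogate_physics()] or by [read_forcing()] from the tabular
#' output of an external hydrodynamic model.
#'
#' @param df data frame with the columns above.
#' @return object of class `forcing_series`.
#' @export
forcing_series <- function(df) {
  req <- c("date", "thermocline_depth_m", "T_surf_C", "mixing_depth_m",
           "Q_m3s", "T_river_C", "T_atm_C")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing forcing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  if (!inherits(df$date, "Date")) df$date <- as.Date(df$date)
  dd <- diff(as.numeric(df$date))
  if (any(dd <= 0)) stop("forcing dates must be strictly increasing")
  if (any(df$thermocline_depth_m <= 0)) stop("thermocline depth must be > 0")
  structure(df, class = c("forcing_series", "data.frame"))
}

#' Surrogate lake physics generator
#'
#' A deterministic-given-seed stand-in for an external hydrodynamic model,
#' producing the daily drivers the two-box model consumes. The thermocline
#' follows a seasonal cycle (shallow in summer, deep in winter); each winter
#' a maximal mixing depth is drawn, with the probability of a deep-mixing
#' event (reaching `deep_threshold`) falling with the winter air-temperature
#' anomaly through a logistic link, so warmer winters ventilate the deep lake
#' less often. Discharge and river temperature follow alpine seasonal
#' cycles.
#'
#' @param years number of simulated years.
#' @param start_year first calendar year (default 1981).
#' @param params list of generator parameters, see [surrogate_params()].
#' @param seed RNG seed.
#' @param T_atm_daily optional externally supplied daily air-temperature
#'   vector (e.g. a detrended/offset scenario series); must match the grid
#'   length. When given, only its winter anomaly drives the mixing draw.
#' @param dT_atm uniform air-temperature offset (degC) applied after
#'   generation, so a warming scenario shares its weather realization with
#'   the unwarmed run under the same seed.
#' @return a [forcing_series()] with attribute `winters` (data.frame: year,
#'   T_winter, p_deep, max_mixing_depth, deep).
#' @export
surrogate_physics <- function(years, start_year = 1981,
                              params = surrogate_params(), seed = 1L,
                              T_atm_daily = NULL, dT_atm = 0) {
  p <- params
  dates <- seq(as.Date(sprintf("%04d-01-01", start_year)),
               by = "day", length.out = round(years * 365.25))
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  with_seed(seed, {
    season <- cos(2 * pi * (doy - 210) / 365.25) # +1 near late July
    if (is.null(T_atm_daily)) {
      T_atm <- p$T_mean + p$T_amp * season +
        as.numeric(stats::filter(stats::rnorm(n, 0, p$T_noise), 0.8,
                                 method = "recursive"))
    } else {
      stopifnot(length(T_atm_daily) == n)
      T_atm <- as.numeric(T_atm_daily)
    }
    T_atm <- T_atm + dT_atm
    T_surf <- pmax(p$Ts_floor, p$Ts_base + p$Ts_gain *
                     stats::filter(T_atm, rep(1 / 30, 30), sides = 1))
    T_surf[is.na(T_surf)] <- p$Ts_base + p$Ts_gain * T_atm[is.na(T_surf)]
    T_surf <- pmax(p$Ts_floor, T_surf)
    # seasonal thermocline: shallow (summer_depth) late July, deepening into winter
    th <- p$winter_depth - (p$winter_depth - p$summer_depth) *
      (1 + cos(2 * pi * (doy - 210) / 365.25)) / 2
    if (p$thermo_amp == 0) th <- rep(p$summer_depth, n)

    # winter mixing: one maximal depth per winter (Nov-Apr spanning year boundary)
    wyear <- as.integer(format(dates, "%Y")) + (as.integer(format(dates, "%m")) >= 11)
    mix <- rep(0, n)
    winters <- list()
    for (wy in unique(wyear)) {
      idx <- which(wyear == wy & (doy >= 305 | doy <= 120))
      if (length(idx) < 60) next
      Tw <- mean(T_atm[idx])
      anom <- Tw - p$T_winter_ref
      p_deep <- stats::plogis(p$mix_intercept - p$mix_slope * anom)
      deep <- stats::runif(1) < p_deep
      max_depth <- if (deep) {
        stats::runif(1, p$deep_threshold, p$z_max)
      } else {
        stats::runif(1, p$shallow_mix_min, p$shallow_mix_max)
      }
      # progressive deepening to the winter maximum, peaking ~ day 90 of winter
      u <- seq_along(idx)
      ramp <- pmin(1, u / max(1, round(length(idx) * 0.7)))
      mix[idx] <- pmax(mix[idx], p$shallow_mix_min / 2 +
                         (max_depth - p$shallow_mix_min / 2) * ramp)
      winters[[length(winters) + 1]] <-
        data.frame(year = wy, T_winter = Tw, p_deep = p_deep,
                   max_mixing_depth = max_depth, deep = deep)
    }
    Q <- pmax(p$Q_floor, p$Q_mean + p$Q_amp * cos(2 * pi * (doy - 190) / 365.25) +
                stats::rnorm(n, 0, p$Q_noise))
    T_river <- pmax(2, 8 + 6 * cos(2 * pi * (doy - 210) / 365.25))
    out <- forcing_series(data.frame(
      date = dates, thermocline_depth_m = pmin(th, p$z_max),
      T_surf_C = T_surf, mixing_depth_m = mix, Q_m3s = Q,
      T_river_C = T_river, T_atm_C = T_atm))
    attr(out, "winters") <- do.call(rbind, winters)
    out
  })
}

#' Parameters of the surrogate physics generator
#'
#' @param z_max maximum depth (m). @param summer_depth,winter_depth seasonal
#'   thermocline bounds (m). @param thermo_amp set 0 for a constant
#'   thermocline (testing). @param T_mean,T_amp,T_noise air-temperature
#'   climatology. @param Ts_base,Ts_gain,Ts_floor surface-temperature
#'   response. @param T_winter_ref reference winter air temperature (degC)
#'   for the mixing anomaly. @param mix_intercept,mix_slope logistic link of
#'   deep-mixing probability to the winter anomaly.
#'   @param deep_threshold mixing depth defining a deep (full-renewal)
#'   winter, m. @param shallow_mix_min,shallow_mix_max ordinary winter
#'   mixing range (m). @param Q_mean,Q_amp,Q_noise,Q_floor discharge
#'   climatology (m^3/s).
#' @return parameter list.
#' @export
surrogate_params <- function(z_max = 310, summer_depth = 15, winter_depth = 120,
                             thermo_amp = 1,
                             T_mean = 11, T_amp = 9, T_noise = 1.5,
                             Ts_base = 4, Ts_gain = 0.75, Ts_floor = 5,
                             T_winter_ref = 4.5,
                             mix_intercept = 0.4, mix_slope = 1.1,
                             deep_threshold = 250,
                             shallow_mix_min = 60, shallow_mix_max = 200,
                             Q_mean = 180, Q_amp = 90, Q_noise = 15,
                             Q_floor = 50) {
  as.list(environment())
}

#' Derive a daily forcing series from monthly lake observations
#'
#' Interpolates the physical drivers of a monthly [lake_series()] onto a
#' daily grid so the two-box model can be driven by the same conditions an
#' empirical analysis of that series saw (the hindcast configuration). The
#' mixed-layer depth column plays two roles: capped at `thermo_cap` it sets
#' the box boundary (thermocline), and during the mixing season its full
#' value is the daily homogenized depth.
#'
#' @param ts a monthly [lake_series()] with `h_mix`, `T_surf`, `T_atm`, `Q`.
#' @param max_depth cap on the box boundary (m); slightly above the deepest
#'   observed mixed layer by default.
#' @param winter_months months of the mixing season (default Nov-Apr).
#' @return a [forcing_series()].
#' @export
forcing_from_series <- function(ts, max_depth = NULL,
                                winter_months = c(11, 12, 1, 2, 3, 4)) {
  stopifnot(inherits(ts, "lake_series"),
            all(c("h_mix", "T_surf", "T_atm", "Q") %in% names(ts)))
  days <- seq(min(ts$time), max(ts$time), by = "day")
  interp <- function(v) {
    stats::approx(as.numeric(ts$time), ts[[v]], xout = as.numeric(days),
                  rule = 2)$y
  }
  h <- interp("h_mix")
  max_depth <- max_depth %||% (max(h) + 1)
  mon <- as.integer(format(days, "%m"))
  doy <- as.integer(format(days, "%j"))
  forcing_series(data.frame(
    date = days,
    thermocline_depth_m = pmin(pmax(h, 5), max_depth),
    T_surf_C = interp("T_surf"),
    mixing_depth_m = ifelse(mon %in% winter_months, pmin(h, max_depth), 0),
    Q_m3s = interp("Q"),
    T_river_C = pmax(2, 8 + 6 * cos(2 * pi * (doy - 210) / 365.25)),
    T_atm_C = interp("T_atm")))
}

#' Read a daily forcing file
#'
#' @param path CSV path.
#' @param dialect optional named character vector mapping required column
#'   names to the file's column names, e.g.
#'   `c(thermocline_depth_m = "thermo_z")`.
#' @param gap `"error"` (default) to fail on a missing day, or `"fill"` to
#'   forward-fill single-day gaps.
#' @return a [forcing_series()].
#' @export
read_forcing <- function(path, dialect = NULL, gap = c("error", "fill")) {
  gap <- match.arg(gap)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (!dialect[[std]] %in% names(df)) {
        stop("dialect column `", dialect[[std]], "` not found in ", path)
      }
      names(df)[names(df) == dialect[[std]]] <- std
    }
  }
  if (!"date" %in% names(df)) stop("missing required column: date")
  df$date <- as.Date(df$date)
  if (is.unsorted(as.numeric(df$date), strictly = TRUE)) {
    stop("forcing dates must be strictly increasing")
  }
  dd <- diff(as.numeric(df$date))
  if (any(dd > 1)) {
    if (gap == "error") stop("gap day(s) in forcing file (use gap = \"fill\")")
    full <- data.frame(date = seq(min(df$date), max(df$date), by = "day"))
    df <- merge(full, df, by = "date", all.x = TRUE)
    for (v in setdiff(names(df), "date")) {
      x <- df[[v]]
      for (i in seq_along(x)) if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
      df[[v]] <- x
    }
  }
  forcing_series(df)
}

#' Write a forcing series to CSV
#' @param fs a [forcing_series()]. @param path output path.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(fs, path) {
  utils::write.csv(as.data.frame(fs), path, row.names = FALSE)
  invisible(path)
}
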