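#' Fit the empirical (S-map) predictors the hybrid model iterates
#'
#' One S-map predictor per biogeochemical state variable (deep oxygen,
#' chlorophyll, surface phosphorus), each on a mechanistic multivariate
#' embedding and with its nonlinearity parameter tuned by leave-one-out
#' [theta_scan()]. The default embeddings pair each target with its direct
#' drivers at lag 0; alternative embeddings (e.g. from
#' [sequential_embedding_comparison()]) can be supplied.
#'
#' @param ts training [lake_series()] (monthly, regular). Only data up to
#'   `train_end` are used, so a simulation started afterwards never sees its
#'   own future.
#' @param specs named list of [embedding()]s for `DO_B`, `chl`, `TP_surf`
#'   (defaults as above).
#' @param theta_grid grid for the nonlinearity scan.
#' @param force_theta if non-NULL, skip the scan and use this theta for all
#'   predictors (0 gives the fixed-coefficient linear ablation).
#' @param train_end optional time cutoff; rows after it are dropped before
#'   fitting.
#' @return named list of `smap_fit` objects, class `hybrid_predictors`.
#' @export
fit_hybrid_predictors <- function(ts, specs = NULL,
                                  theta_grid = default_theta_grid(),
                                  force_theta = NULL, train_end = NULL) {
  if (!is.null(train_end)) {
    ts <- lake_series(as.data.frame(ts)[ts$time <= train_end, , drop = FALSE],
                      units = attr(ts, "units"))
  }
  specs <- specs %||% list(
    DO_B = embedding(c("DO_B", "chl", "TP_lake", "T_atm"), target = "DO_B"),
    chl = embedding(c("chl", "TP_surf", "T_atm"), target = "chl"),
    TP_surf = embedding(c("TP_surf", "TP_lake", "chl", "T_atm"),
                        target = "TP_surf"))
  fits <- lapply(names(specs), function(v) {
    sm <- state_matrix(ts, specs[[v]])
    th <- force_theta
    if (is.null(th)) {
      scan <- theta_scan(sm, theta_grid)
      th <- attr(scan, "best_theta")
    }
    smap_forecast(sm, theta = th)
  })
  names(fits) <- names(specs)
  structure(fits, class = "hybrid_predictors", train_end = train_end)
}

#' @export
print.hybrid_predictors <- function(x, ...) {
  cat("<hybrid_predictors>\n")
  for (v in names(x)) {
    cat("  ", v, ": theta =", x[[v]]$theta, " rho =", round(x[[v]]$skill, 3), "\n")
  }
  invisible(x)
}

# assemble the raw coordinate row a predictor needs from the current (and
# past) monthly state; `state` is a named vector, `history` a named list of
# previous values keyed "var|lag"
predictor_newdata <- function(fit, state, history = list()) {
  coords <- fit$spec$coordinates
  row <- lapply(seq_len(nrow(coords)), function(j) {
    v <- coords$var[j]; lag <- coords$lag[j]
    if (lag == 0L) {
      if (!v %in% names(state)) stop("state vector lacks variable `", v, "`")
      state[[v]]
    } else {
      key <- paste0(v, "|", lag)
      if (is.null(history[[key]])) stop("no history for `", v, "` at lag ", lag)
      history[[key]]
    }
  })
  stats::setNames(as.data.frame(row), colnames(fit$lib_x))
}

# nearest-neighbour distance (normalized space) from a state to the library
library_distance <- function(fit, newrow) {
  xn <- (as.numeric(newrow) - fit$center) / fit$scale
  min(sqrt(colSums((t(fit$lib_x) - xn)^2)))
}

#' Iterated empirical prediction of summer deep-oxygen depletion
#'
#' From a post-winter initial state, the three S-map predictors are iterated
#' monthly through the 6-month stratified season (about 180 days):
#' chlorophyll and surface phosphorus are predicted by their own predictors,
#' deep oxygen by its predictor, and the exogenous coordinates (physics
#' variables, lake phosphorus, air temperature) are refreshed from the
#' forcing at each step. Returns the monthly trajectory and the seasonally
#' averaged depletion rate.
#'
#' @param predictors a [fit_hybrid_predictors()] object.
#' @param state0 named numeric with at least `DO_B`, `chl`, `TP_surf` plus
#'   any exogenous variables the embeddings use, valid at the season start.
#' @param TP_lake lake-mean phosphorus: scalar or vector of length
#'   `n_steps`.
#' @param physics data.frame with `n_steps` rows of the monthly exogenous
#'   drivers (`h_mix`, `T_surf`, `T_atm`, `Q` as available).
#' @param n_steps iteration steps (default 6 months over 180 days).
#' @param extrapolation_radius states farther than this (normalized
#'   nearest-neighbour distance) from the deep-oxygen training library flag
#'   the output as an extrapolation; default 2.
#' @return data.frame (step, DO_B, chl, TP_surf) with attributes
#'   `depletion_rate` (mg/L/day, positive = loss), `DO_init` and
#'   `extrapolated`.
#' @export
summer_depletion <- function(predictors, state0, TP_lake, physics,
                             n_steps = 6L, extrapolation_radius = 2) {
  stopifnot(inherits(predictors, "hybrid_predictors"))
  TP_lake <- rep(as.numeric(TP_lake), length.out = n_steps)
  state <- state0
  out <- data.frame(step = 0:n_steps, DO_B = NA_real_, chl = NA_real_,
                    TP_surf = NA_real_)
  out[1, -1] <- state[c("DO_B", "chl", "TP_surf")]
  extrapolated <- FALSE
  for (s in seq_len(n_steps)) {
    state[["TP_lake"]] <- TP_lake[s]
    for (v in intersect(names(physics), c("h_mix", "T_surf", "T_atm", "Q"))) {
      state[[v]] <- physics[[v]][s]
    }
    nd <- predictor_newdata(predictors$DO_B, state)
    if (library_distance(predictors$DO_B, nd) > extrapolation_radius) {
      extrapolated <- TRUE
    }
    do_next <- predict(predictors$DO_B, nd)$pred
    chl_next <- predict(predictors$chl, predictor_newdata(predictors$chl, state))$pred
    tps_next <- predict(predictors$TP_surf,
                        predictor_newdata(predictors$TP_surf, state))$pred
    state[["DO_B"]] <- max(do_next, 0)
    state[["chl"]] <- max(chl_next, 0.05)
    state[["TP_surf"]] <- max(tps_next, 1)
    out[s + 1, -1] <- state[c("DO_B", "chl", "TP_surf")]
  }
  attr(out, "DO_init") <- out$DO_B[1]
  attr(out, "depletion_rate") <- (out$DO_B[1] - out$DO_B[n_steps + 1]) /
    (n_steps * 30)
  attr(out, "extrapolated") <- extrapolated
  if (extrapolated) {
    warning("summer state left the training library neighbourhood ",
            "(extrapolation flagged)")
  }
  out
}

#' Hybrid model configuration
#'
#' @param predictors a [fit_hybrid_predictors()] object.
#' @param hypso a [hypsometry()].
#' @param physics a [physics_params()].
#' @param init named list: `DO_up`, `DO_B` (mg/L) at simulation start, and
#'   optionally `chl`, `TP_surf` (defaults: training means).
#' @param summer_months months in which the empirical predictor owns deep
#'   oxygen (default May-October); the remaining months are the physics
#'   (mixing) season.
#' @param z_deep reference horizon (m) splitting the boxes: the deep box is
#'   the stratum below it, the water whose oxygen the DO_B predictors were
#'   trained on. Defaults to 250 m, the deep-mixing threshold, so the deep
#'   box is renewed by winter mixing only when mixing reaches it (plus the
#'   river underflow).
#' @param extrapolation_radius passed to [summer_depletion()].
#' @return list, class `hybrid_config`.
#' @export
hybrid_config <- function(predictors, hypso = synthetic_hypsometry(),
                          physics = physics_params(),
                          init = list(DO_up = 10, DO_B = 9),
                          summer_months = 5:10, z_deep = 250,
                          extrapolation_radius = 2) {
  stopifnot(inherits(predictors, "hybrid_predictors"),
            inherits(hypso, "hypsometry"))
  train_mean <- function(fit, var) {
    j <- grep(paste0("^", var, "_"), names(fit$center))[1]
    unname(fit$center[j])
  }
  chl0 <- init$chl %||% train_mean(predictors$chl, "chl")
  tps0 <- init$TP_surf %||% train_mean(predictors$TP_surf, "TP_surf")
  structure(list(predictors = predictors, hypso = hypso, physics = physics,
                 init = list(DO_up = init$DO_up, DO_B = init$DO_B,
                             chl = chl0, TP_surf = tps0),
                 summer_months = summer_months, z_deep = z_deep,
                 extrapolation_radius = extrapolation_radius),
            class = "hybrid_config")
}

#' Run the hybrid empirical-parametric simulation
#'
#' Alternates seasonally between the two oxygen controls. Through the mixing
#' season (November-April) the two-box physics evolves both boxes daily:
#' gas exchange ventilates the water column above `z_deep`, convective
#' homogenization renews the deep stratum in the winters whose mixing
#' reaches below `z_deep`, and the plunging river delivers oxygenated water
#' to the deep box every winter. Through the stratified season (May-October)
#' deep oxygen is handed to the iterated S-map predictors
#' ([summer_depletion()]) while the surface box continues under
#' [surface_do_update()] with the empirically predicted chlorophyll. At the
#' end of October the empirical deep oxygen is fed back as the physics
#' model's deep initial condition. A single initialization only: the run is
#' never re-anchored to observations.
#'
#' @param config a [hybrid_config()].
#' @param forcing a daily [forcing_series()] covering the span.
#' @param TP_lake lake-mean phosphorus: a scalar (scenario constant) or a
#'   monthly vector/series aligned with the forcing months.
#' @return data.frame (time, DO_B, DO_up, chl, TP_surf, phase) of monthly
#'   states with attribute `years` (per-year diagnostics: max mixing depth,
#'   summer depletion rate, extrapolation flag).
#' @export
run_hybrid <- function(config, forcing, TP_lake) {
  stopifnot(inherits(config, "hybrid_config"), inherits(forcing, "forcing_series"))
  fdate <- forcing$date
  months_all <- unique(format(fdate, "%Y-%m"))
  # start at the first May with a full preceding record
  start_m <- months_all[match(TRUE, substr(months_all, 6, 7) == "05")]
  if (is.na(start_m)) stop("forcing does not contain a May to start from")
  months_all <- months_all[seq(match(start_m, months_all), length(months_all))]
  mtab <- monthly_forcing(forcing)
  TPm <- rep(as.numeric(TP_lake), length.out = length(months_all))

  state <- c(DO_B = config$init$DO_B, chl = config$init$chl,
             TP_surf = config$init$TP_surf)
  z_deep <- min(config$z_deep, config$hypso$z_max - 1)
  d0 <- match(TRUE, format(fdate, "%Y-%m") == start_m)
  box <- box_state(config$init$DO_up, config$init$DO_B, config$hypso,
                   z_deep, date = fdate[d0])
  sim <- data.frame(time = as.Date(paste0(months_all, "-15")),
                    DO_B = NA_real_, DO_up = NA_real_, chl = NA_real_,
                    TP_surf = NA_real_, phase = NA_character_)
  yearly <- list()
  DO_up <- config$init$DO_up
  i <- 1L
  while (i <= length(months_all)) {
    ym <- months_all[i]
    mon <- as.integer(substr(ym, 6, 7))
    if (mon %in% config$summer_months) {
      # --- stratified season: iterated empirical prediction ---
      n_steps <- min(length(config$summer_months),
                     length(months_all) - i + 1L)
      idx <- i:(i + n_steps - 1L)
      if (i > 1L) state[["DO_B"]] <- box$DO_low # physics hands over deep DO
      phys <- mtab[match(months_all[idx], mtab$ym), , drop = FALSE]
      traj <- withCallingHandlers(
        summer_depletion(config$predictors, state, TPm[idx],
                         data.frame(h_mix = phys$h_mix, T_surf = phys$T_surf,
                                    T_atm = phys$T_atm, Q = phys$Q),
                         n_steps = n_steps,
                         extrapolation_radius = config$extrapolation_radius),
        warning = function(w) invokeRestart("muffleWarning"))
      # surface box runs daily on predicted chlorophyll; the deep box is
      # owned by the empirical predictor through the stratified season
      for (s in seq_len(n_steps)) {
        days <- which(format(fdate, "%Y-%m") == months_all[idx[s]])
        for (d in days) {
          box <- box_state(DO_up, traj$DO_B[s + 1], config$hypso,
                           z_deep, date = fdate[d])
          box <- surface_do_update(box, chl = max(traj$chl[s + 1], 0),
                                   T_surf = forcing$T_surf_C[d],
                                   params = config$physics)
          DO_up <- box$DO_up
        }
        sim[idx[s], c("DO_B", "DO_up", "chl", "TP_surf")] <-
          c(traj$DO_B[s + 1], DO_up, traj$chl[s + 1], traj$TP_surf[s + 1])
        sim$phase[idx[s]] <- "summer"
      }
      state[c("DO_B", "chl", "TP_surf")] <-
        as.numeric(traj[n_steps + 1, c("DO_B", "chl", "TP_surf")])
      yearly[[length(yearly) + 1]] <- data.frame(
        year = as.integer(substr(ym, 1, 4)),
        depletion_rate = attr(traj, "depletion_rate"),
        DO_init = attr(traj, "DO_init"),
        extrapolated = attr(traj, "extrapolated"),
        max_mixing_depth = NA_real_)
      i <- i + n_steps
    } else {
      # --- mixing season: daily two-box physics; DO_B fed back end-October ---
      days <- which(format(fdate, "%Y-%m") == ym)
      if (sim$phase[max(i - 1L, 1L)] %in% "summer" || i == 1L) {
        # season switch: the empirical deep oxygen re-enters the physics
        box <- box_state(DO_up, state[["DO_B"]], config$hypso,
                         z_deep, date = fdate[days[1]])
      }
      for (d in days) {
        box <- winter_mix_step(box, forcing$mixing_depth_m[d],
                               T_surf = forcing$T_surf_C[d],
                               Q = forcing$Q_m3s[d],
                               T_river = forcing$T_river_C[d],
                               params = config$physics)
        box$date <- fdate[d]
        DO_up <- box$DO_up
      }
      DO_low <- box$DO_low
      state[["DO_B"]] <- DO_low
      # chlorophyll / surface P keep evolving on their own predictors
      phys <- mtab[match(ym, mtab$ym), ]
      state[["TP_lake"]] <- TPm[i]
      for (v in c("h_mix", "T_surf", "T_atm", "Q")) state[[v]] <- phys[[v]]
      state[["chl"]] <- max(predict(config$predictors$chl,
        predictor_newdata(config$predictors$chl, state))$pred, 0.05)
      state[["TP_surf"]] <- max(predict(config$predictors$TP_surf,
        predictor_newdata(config$predictors$TP_surf, state))$pred, 1)
      sim[i, c("DO_B", "DO_up", "chl", "TP_surf")] <-
        c(DO_low, DO_up, state[["chl"]], state[["TP_surf"]])
      sim$phase[i] <- "winter"
      if (length(yearly)) {
        wy <- length(yearly)
        yearly[[wy]]$max_mixing_depth <-
          max(yearly[[wy]]$max_mixing_depth, max(forcing$mixing_depth_m[days]),
              na.rm = TRUE)
      }
      i <- i + 1L
    }
  }
  attr(sim, "years") <- do.call(rbind, yearly)
  sim
}

# monthly means of the forcing columns, renamed to EDM variable names
monthly_forcing <- function(forcing) {
  ym <- format(forcing$date, "%Y-%m")
  agg <- stats::aggregate(
    cbind(h_mix = pmax(forcing$thermocline_depth_m, forcing$mixing_depth_m),
          T_surf = forcing$T_surf_C, T_atm = forcing$T_atm_C,
          Q = forcing$Q_m3s),
    by = list(ym = ym), FUN = mean)
  agg[order(agg$ym), ]
}

#' Hindcast skill metrics
#'
#' @param simulated,observed aligned numeric vectors (or data.frames with
#'   `time` and a value column, merged on time).
#' @return list with `rho` (Pearson; `NA` with a note when either series has
#'   zero variance), `mae` and `bias` (mean simulated minus observed).
#' @export
evaluate_hindcast <- function(simulated, observed) {
  if (is.data.frame(simulated) && is.data.frame(observed)) {
    m <- merge(simulated[, 1:2], observed[, 1:2], by = 1)
    simulated <- m[[2]]; observed <- m[[3]]
  }
  ok <- is.finite(simulated) & is.finite(observed)
  if (sum(ok) < 3L) stop("need at least 3 overlapping points")
  s <- simulated[ok]; o <- observed[ok]
  rho <- if (stats::sd(s) == 0 || stats::sd(o) == 0) NA_real_ else stats::cor(s, o)
  list(rho = rho, mae = mean(abs(s - o)), bias = mean(s - o),
       n = sum(ok),
       note = if (is.na(rho)) "zero-variance input: rho undefined" else NULL)
}
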