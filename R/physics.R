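#' Lake hypsometry (depth-area curve)
#'
#' @param depth_m depth grid in metres, strictly increasing from 0 (surface)
#'   to the maximum depth.
#' @param area_m2 lake area at each depth, m^2; positive and nonincreasing
#'   with depth.
#' @return object of class `hypsometry`.
#' @export
hypsometry <- function(depth_m, area_m2) {
  stopifnot(is.numeric(depth_m), is.numeric(area_m2),
            length(depth_m) == length(area_m2), length(depth_m) >= 2)
  if (depth_m[1] != 0) stop("depth grid must start at the surface (0 m)")
  if (is.unsorted(depth_m, strictly = TRUE)) stop("depth grid must be strictly increasing")
  if (any(area_m2 <= 0)) stop("areas must be strictly positive")
  if (any(diff(area_m2) > 1e-9 * area_m2[1])) stop("area must be nonincreasing with depth")
  structure(list(depth = depth_m, area = area_m2, z_max = max(depth_m)),
            class = "hypsometry")
}

#' Default synthetic deep-lake hypsometry
#'
#' A smooth basin with 310 m maximum depth and 589 km^2 surface area
#' (deep perialpine-lake scale), generated on a 1 m grid. A stand-in for a
#' surveyed depth-area table; labelled synthetic accordingly.
#'
#' @param z_max maximum depth (m). @param A0 surface area (m^2).
#' @return a [hypsometry()].
#' @export
synthetic_hypsometry <- function(z_max = 310, A0 = 589e6) {
  z <- seq(0, z_max, by = 1)
  hypsometry(z, A0 * (0.02 + 0.98 * (1 - (z / z_max)^1.5)))
}

# area interpolated at arbitrary depth
area_at <- function(h, d) stats::approx(h$depth, h$area, xout = d, rule = 2)$y

#' Volume of the water column between two depths
#' @param h a [hypsometry()]. @param d0,d1 depth bounds (m), `d0 < d1`.
#' @return volume in m^3 by trapezoidal integration of area over depth.
#' @export
layer_volume <- function(h, d0, d1) {
  stopifnot(d0 >= 0, d1 <= h$z_max + 1e-9, d0 <= d1)
  if (d1 - d0 < 1e-12) return(0)
  grid <- sort(unique(c(d0, d1, h$depth[h$depth > d0 & h$depth < d1])))
  a <- area_at(h, grid)
  sum(diff(grid) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
}

#' Two-box volumes from the thermocline depth
#'
#' @param h a [hypsometry()].
#' @param thermocline_depth depth of the density interface (m), in
#'   `(0, z_max]`.
#' @return named numeric `c(V_up, V_low)` in m^3.
#' @export
box_volumes <- function(h, thermocline_depth) {
  if (!is.finite(thermocline_depth) || thermocline_depth <= 0 ||
      thermocline_depth > h$z_max + 1e-9) {
    stop("thermocline depth must lie in (0, z_max]")
  }
  c(V_up = layer_volume(h, 0, thermocline_depth),
    V_low = layer_volume(h, thermocline_depth, h$z_max))
}

#' Oxygen solubility at equilibrium with the atmosphere
#'
#' Benson-Krause freshwater solubility as a function of water temperature,
#' with an optional pressure correction for lake altitude.
#'
#' @param temp_c water temperature, degC.
#' @param pressure_atm ambient pressure in atmospheres (default 1; about
#'   0.95 at 400 m a.s.l.).
#' @return saturation concentration, mg/L.
#' @export
do_saturation <- function(temp_c, pressure_atm = 1) {
  TK <- temp_c + 273.15
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.2438e10 / TK^3 - 8.621949e11 / TK^4
  exp(lnC) * pressure_atm
}

#' Two-box oxygen state
#'
#' @param DO_up,DO_low dissolved oxygen, mg/L (>= 0).
#' @param h a [hypsometry()].
#' @param thermocline_depth interface depth (m).
#' @param date date of the state.
#' @return object of class `box_state` with volumes derived from the
#'   hypsometry (so `V_up + V_low` always equals the lake volume).
#' @export
box_state <- function(DO_up, DO_low, h, thermocline_depth, date = NULL) {
  stopifnot(DO_up >= 0, DO_low >= 0)
  v <- box_volumes(h, thermocline_depth)
  structure(list(DO_up = DO_up, DO_low = DO_low,
                 V_up = v[["V_up"]], V_low = v[["V_low"]],
                 thermocline_depth = thermocline_depth,
                 hypsometry = h, date = date),
            class = "box_state")
}

#' @export
print.box_state <- function(x, ...) {
  cat("<box_state> DO_up =", round(x$DO_up, 2), "mg/L  DO_low =",
      round(x$DO_low, 2), "mg/L  thermocline =", x$thermocline_depth, "m\n")
  invisible(x)
}

total_o2_mass <- function(state) state$DO_up * state$V_up + state$DO_low * state$V_low

#' Move the box boundary with conservative entrainment
#'
#' When the mixed layer deepens, the entrained slab of former deep water is
#' blended into the upper box; when it shoals, the detrained slab of former
#' surface water is blended into the deep box. Total oxygen mass is conserved
#' exactly, so seasonal thermocline migration performs the spring
#' redistribution of ventilated water without any ad hoc source term.
#'
#' @param state a [box_state()].
#' @param new_depth new thermocline depth (m).
#' @return a [box_state()] at the new geometry.
#' @export
rebox <- function(state, new_depth) {
  stopifnot(inherits(state, "box_state"))
  d0 <- state$thermocline_depth
  if (abs(new_depth - d0) < 1e-9) return(state)
  h <- state$hypsometry
  v_new <- box_volumes(h, new_depth)
  DO_up <- state$DO_up; DO_low <- state$DO_low
  if (new_depth > d0) {
    v_ent <- layer_volume(h, d0, new_depth)
    DO_up <- (DO_up * state$V_up + DO_low * v_ent) / v_new[["V_up"]]
  } else {
    v_det <- layer_volume(h, new_depth, d0)
    DO_low <- (DO_low * state$V_low + DO_up * v_det) / v_new[["V_low"]]
  }
  out <- state
  out$DO_up <- DO_up; out$DO_low <- DO_low
  out$V_up <- v_new[["V_up"]]; out$V_low <- v_new[["V_low"]]
  out$thermocline_depth <- new_depth
  out
}

#' Physics parameter defaults
#'
#' @param k_gas air-water gas-exchange velocity, m/day.
#' @param pressure_atm ambient pressure, atm.
#' @param river_underflow logical: does winter river inflow plunge into the
#'   deep box?
#' @param chl_production net photic-zone production coefficient,
#'   (mg/L/day) per (ug/L chlorophyll).
#' @param surface_respiration constant surface sink, mg/L/day.
#' @param photic_depth depth (m) over which the biological terms operate;
#'   when the upper box is deeper than this, the net rate is diluted by
#'   `photic_depth / h_up` so production is not spread over dark water.
#' @param production_fun optional plug-in `function(chl)` returning the net
#'   biological rate (mg/L/day, photic zone) for the surface box; overrides
#'   the default linear form `chl_production * chl - surface_respiration`.
#' @return list of parameters.
#' @export
physics_params <- function(k_gas = 1.0, pressure_atm = 1,
                           river_underflow = TRUE,
                           chl_production = 0.01,
                           surface_respiration = 0.02,
                           photic_depth = 20,
                           production_fun = NULL) {
  list(k_gas = k_gas, pressure_atm = pressure_atm,
       river_underflow = river_underflow,
       chl_production = chl_production,
       surface_respiration = surface_respiration,
       photic_depth = photic_depth,
       production_fun = production_fun)
}

#' One winter time step of the two-box model
#'
#' Three processes, in order: (1) homogenization of the water column above
#' `mixing_depth` — the upper box and the mixed fraction of the lower box are
#' set to their volume-weighted mean oxygen (deep renewal occurs only when
#' mixing reaches below the thermocline); (2) exponential relaxation of
#' surface oxygen toward temperature-dependent saturation (gas exchange);
#' (3) river underflow — in winter the cold river plunges, delivering water
#' saturated at river temperature to the deep box as a replacement flux
#' `Q x dt`.
#'
#' @param state a [box_state()].
#' @param mixing_depth today's homogenized depth (m).
#' @param T_surf surface water temperature (degC).
#' @param Q river discharge (m^3/s).
#' @param T_river river temperature (degC).
#' @param dt time step in days (default 1).
#' @param params a [physics_params()].
#' @return the updated `box_state`.
#' @export
winter_mix_step <- function(state, mixing_depth, T_surf, Q = 0, T_river = 5,
                            dt = 1, params = physics_params()) {
  stopifnot(inherits(state, "box_state"))
  h <- state$hypsometry
  d_th <- state$thermocline_depth
  DO_up <- state$DO_up; DO_low <- state$DO_low
  # 1. convective homogenization above mixing_depth
  if (mixing_depth > d_th) {
    v_mix_low <- layer_volume(h, d_th, min(mixing_depth, h$z_max))
    mixed <- (DO_up * state$V_up + DO_low * v_mix_low) / (state$V_up + v_mix_low)
    DO_up <- mixed
    if (state$V_low > 0) {
      DO_low <- (mixed * v_mix_low + DO_low * (state$V_low - v_mix_low)) / state$V_low
    } else {
      DO_low <- mixed
    }
  }
  # 2. gas exchange: exact exponential relaxation toward saturation
  if (params$k_gas > 0 && state$V_up > 0) {
    sat <- do_saturation(T_surf, params$pressure_atm)
    h_up <- state$V_up / area_at(h, 0)
    DO_up <- sat + (DO_up - sat) * exp(-params$k_gas * dt / h_up)
  }
  # 3. river underflow into the deep box (saturated at river temperature)
  if (params$river_underflow && Q > 0 && state$V_low > 0) {
    v_river <- min(Q * 86400 * dt, state$V_low)
    c_river <- do_saturation(T_river, params$pressure_atm)
    DO_low <- DO_low + (v_river / state$V_low) * (c_river - DO_low)
  }
  if (DO_up < 0 || DO_low < 0) {
    warning("negative oxygen after step; floored at 0")
    DO_up <- max(DO_up, 0); DO_low <- max(DO_low, 0)
  }
  state$DO_up <- DO_up; state$DO_low <- DO_low
  if (!is.null(state$date)) state$date <- state$date + dt
  state
}

#' Summer surface-box oxygen update
#'
#' The upper box evolves by gas exchange plus a net biological term driven by
#' chlorophyll. The default plug-in is linear,
#' `dDO/dt = (k/h)(sat - DO) + p * chl - r`, integrated exactly over the step
#' (so a constant-forcing trajectory equals the closed-form solution of the
#' linear ODE); any alternative rate law can be supplied via
#' `params$production_fun`. The deep box is untouched — in summer its oxygen
#' is governed by the empirical depletion predictor, not the physics.
#'
#' @param state a [box_state()].
#' @param chl surface chlorophyll (ug/L).
#' @param T_surf surface temperature (degC).
#' @param dt step in days.
#' @param params a [physics_params()].
#' @return updated `box_state`.
#' @export
surface_do_update <- function(state, chl, T_surf, dt = 1,
                              params = physics_params()) {
  stopifnot(inherits(state, "box_state"), chl >= 0)
  sat <- do_saturation(T_surf, params$pressure_atm)
  prod <- if (!is.null(params$production_fun)) {
    params$production_fun(chl)
  } else {
    params$chl_production * chl - params$surface_respiration
  }
  h_up <- state$V_up / area_at(state$hypsometry, 0)
  prod <- prod * min(1, params$photic_depth / h_up)
  alpha <- params$k_gas / h_up
  DO <- state$DO_up
  if (alpha > 0) {
    DO_inf <- sat + prod / alpha
    DO <- DO_inf + (DO - DO_inf) * exp(-alpha * dt)
  } else {
    DO <- DO + prod * dt
  }
  if (DO < 0) {
    warning("negative surface oxygen; floored at 0")
    DO <- 0
  }
  state$DO_up <- DO
  if (!is.null(state$date)) state$date <- state$date + dt
  state
}
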