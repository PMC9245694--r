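#' Parameters of the synthetic lake generator
#'
#' The generator is a discrete-time monthly process model chosen to exhibit
#' the phenomenology a reoligotrophicating deep lake presents to empirical
#' dynamic analysis: seasonal forcing, a multi-decadal declining phosphorus
#' trend, intermittent deep-mixing winters resupplying deep oxygen, and
#' state-dependent biogeochemical coupling. Chlorophyll responds to surface
#' phosphorus through a saturating (Michaelis-Menten) uptake `g_PC`, so the
#' phosphorus effect on chlorophyll is near zero when phosphorus is plentiful
#' and grows as it becomes limiting. The deep-oxygen sink combines a
#' phosphorus-scaled legacy demand with a chlorophyll-driven export term
#' gated by a phosphorus-dependent export fraction `e(P)` (logistic,
#' increasing as P falls), so the effect of chlorophyll on deep oxygen is
#' near zero in the eutrophic state and distinctly negative in the
#' oligotrophic state — and the total summer depletion is U-shaped in
#' phosphorus, with a minimum at intermediate concentrations.
#'
#' @param years simulated span (default 37).
#' @param TP_start,TP_end lake-mean phosphorus at the start/end of the span
#'   (ug/L); the trend follows a half-cosine remediation curve (slow onset,
#'   rapid mid-course decline, levelling off) between them.
#' @param c_PC,K_PC chlorophyll growth scale and half-saturation (ug/L P).
#' @param m_C monthly chlorophyll loss fraction.
#' @param r0,r1 surface-phosphorus replenishment rates (year-round and
#'   winter-added, per month).
#' @param u_P phosphorus uptake per unit chlorophyll (summer).
#' @param s0 baseline deep oxygen demand (mg/L/month).
#' @param s_hi eutrophic legacy demand (mg/L/month), switched on by a
#'   logistic threshold centred at `P_h` (ug/L) with width `s_h`: bulk
#'   settling organic matter loads the deep water only at high phosphorus.
#' @param P_h,s_h centre and width (ug/L) of the legacy-demand threshold.
#' @param c_CD chlorophyll-export oxygen demand coefficient
#'   (mg/L/month per ug/L chlorophyll).
#' @param P_e,s_e centre and width (ug/L) of the logistic export fraction.
#' @param mix_eff winter renewal efficiency scale.
#' @param DO_target post-mixing deep-oxygen target (mg/L).
#' @param mix_intercept,mix_slope logistic link from winter air-temperature
#'   anomaly to deep-mixing probability.
#' @param z_max maximum depth (m).
#' @param sd_chl,sd_tp,sd_do process noise standard deviations.
#' @param obs_noise_frac observation noise, as a fraction of each variable's
#'   process signal sd (default 0.02).
#' @param dT_atm uniform air-temperature offset (degC), for scenario rigs.
#' @return parameter list (class `lake_params`).
#' @export
lake_params <- function(years = 37, TP_start = 62, TP_end = 14,
                        c_PC = 6, K_PC = 15, m_C = 0.4,
                        r0 = 0.05, r1 = 0.45, u_P = 0.3,
                        s0 = 0.05, s_hi = 0.65, P_h = 50, s_h = 5, c_CD = 0.15,
                        P_e = 22, s_e = 3,
                        mix_eff = 1.0, DO_target = 11.5,
                        mix_intercept = 0.3, mix_slope = 1.2,
                        z_max = 310,
                        sd_chl = 0.6, sd_tp = 0.5, sd_do = 0.05,
                        obs_noise_frac = 0.02, dT_atm = 0) {
  p <- as.list(environment())
  stopifnot(all(unlist(p[c("sd_chl", "sd_tp", "sd_do", "obs_noise_frac")]) >= 0))
  class(p) <- "lake_params"
  p
}

# seasonal light/stratification weight: 1 in July, 0 in January
season_light <- function(mon) (1 + cos(2 * pi * (mon - 7) / 12)) / 2

# export fraction: ~0 in the eutrophic state, ~1 in the oligotrophic state
export_fraction <- function(P, params) 1 / (1 + exp((P - params$P_e) / params$s_e))

# eutrophic legacy demand switch: ~1 at high phosphorus, ~0 once remediated
legacy_demand <- function(P, params) 1 / (1 + exp(-(P - params$P_h) / params$s_h))

#' Deterministic one-month update of the synthetic lake
#'
#' The noise-free process map; the simulation adds process noise on top of
#' it. Exposed so its Jacobian can be checked independently (e.g. by finite
#' differences) against the analytic ground truth the generator records.
#'
#' @param state named numeric `c(chl, TP_surf, DO_B)`.
#' @param driver list/row with elements `light` (seasonal weight), `mr`
#'   (winter renewal fraction) and `TP_lake`.
#' @param params a [lake_params()].
#' @return named numeric next state.
#' @export
lake_step <- function(state, driver, params) {
  chl <- state[["chl"]]; P <- state[["TP_surf"]]; DO <- state[["DO_B"]]
  l <- driver$light; mr <- driver$mr; PL <- driver$TP_lake
  chl2 <- chl + l * params$c_PC * P / (params$K_PC + P) - params$m_C * chl
  P2 <- P + (params$r0 + params$r1 * (1 - l)) * (PL - P) - params$u_P * l * chl
  sink <- params$s0 + params$s_hi * legacy_demand(PL, params) +
    params$c_CD * export_fraction(PL, params) * chl
  DO2 <- DO + (1 - l) * mr * (params$DO_target - DO) - l * sink
  c(chl = chl2, TP_surf = P2, DO_B = DO2)
}

# analytic Jacobian elements of lake_step at a given state/driver
lake_step_jacobian <- function(state, driver, params) {
  P <- state[["TP_surf"]]; l <- driver$light
  c(dCHL_dTP = l * params$c_PC * params$K_PC / (params$K_PC + P)^2,
    dDO_dCHL = -l * params$c_CD * export_fraction(driver$TP_lake, params),
    dCHL_dCHL = 1 - params$m_C,
    dDO_dDO = 1 - (1 - l) * driver$mr)
}

#' Simulate a lake-like multivariate monthly series with known structure
#'
#' Runs the process model of [lake_step()] under seasonal and stochastic
#' drivers and returns both the observed series (all eight canonical
#' variables) and a ground-truth record: the drivers and the analytic
#' Jacobian elements d(chl(t+1))/d(TP_surf(t)) and d(DO_B(t+1))/d(chl(t))
#' along the realized trajectory. The true causal graph is
#' T_atm -> T_surf -> h_mix -> DO_B (via mixing) and TP -> chl -> DO_B.
#'
#' @param params a [lake_params()].
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with `series` (a [lake_series()], monthly), `truth`
#'   (data.frame: time, light, mr, TP_lake, deep_mix, and the Jacobian
#'   columns), `winters` (per-winter mixing diagnostics) and `params`.
#' @export
simulate_lake <- function(params = lake_params(), seed = 1L) {
  stopifnot(inherits(params, "lake_params"))
  n <- params$years * 12L
  dates <- seq(as.Date("1981-01-15"), by = "month", length.out = n)
  mon <- as.integer(format(dates, "%m"))
  with_seed(seed, {
    l <- season_light(mon)
    T_atm <- 11 + 9 * (2 * l - 1) + params$dT_atm +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.8), 0.5, method = "recursive"))
    T_sm <- stats::filter(T_atm, c(0.5, 0.5), sides = 1)
    T_sm[1] <- T_atm[1]
    T_surf <- pmax(5, 6 + 0.7 * (as.numeric(T_sm) - 4))
    Q <- pmax(50, 180 + 90 * (2 * l - 1) + stats::rnorm(n, 0, 12))
    # remediation curve: slow onset, rapid mid-course decline, levelling
    # off — giving the library comparable dwell time in both trophic extremes
    TP_lake <- params$TP_end + (params$TP_start - params$TP_end) *
      (1 + cos(pi * (seq_len(n) - 1) / (n - 1))) / 2 +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.2), 0.7, method = "recursive"))
    TP_lake <- pmax(2, TP_lake)

    # one winter-mixing draw per winter (Nov through Apr); h_mix follows it
    wid <- cumsum(mon == 11)
    deep <- rep(FALSE, n); wdepth <- rep(NA_real_, n)
    winters <- list()
    for (w in setdiff(unique(wid), 0)) {
      idx <- which(wid == w & (mon >= 11 | mon <= 4))
      if (!length(idx)) next
      Tw <- mean(T_atm[idx][mon[idx] %in% c(12, 1, 2)])
      if (!is.finite(Tw)) Tw <- mean(T_atm[idx])
      anom <- Tw - (2 + params$dT_atm * 0) # reference winter climatology
      p_deep <- stats::plogis(params$mix_intercept - params$mix_slope * anom)
      is_deep <- stats::runif(1) < p_deep
      dmax <- if (is_deep) stats::runif(1, 255, params$z_max) else
        stats::runif(1, 60, 150)
      deep[idx] <- is_deep
      wdepth[idx] <- dmax
      winters[[length(winters) + 1]] <-
        data.frame(winter = w, T_winter = Tw, p_deep = p_deep,
                   max_depth = dmax, deep = is_deep)
    }
    h_mix <- 15 + (ifelse(is.na(wdepth), 90, wdepth) - 15) * (1 - l)
    h_mix <- pmin(h_mix, params$z_max)
    # renewal fraction active only when mixing is at/near its winter deepest
    mr <- params$mix_eff * (h_mix / params$z_max)^2

    chl <- numeric(n); tps <- numeric(n); dob <- numeric(n)
    truth <- matrix(NA_real_, n, 4,
                    dimnames = list(NULL, c("dCHL_dTP", "dDO_dCHL",
                                            "dCHL_dCHL", "dDO_dDO")))
    state <- c(chl = 2.5, TP_surf = TP_lake[1], DO_B = 9)
    for (t in seq_len(n)) {
      chl[t] <- state[["chl"]]; tps[t] <- state[["TP_surf"]]
      dob[t] <- state[["DO_B"]]
      driver <- list(light = l[t], mr = mr[t], TP_lake = TP_lake[t])
      truth[t, ] <- lake_step_jacobian(state, driver, params)
      nxt <- lake_step(state, driver, params) +
        c(stats::rnorm(1, 0, params$sd_chl), stats::rnorm(1, 0, params$sd_tp),
          stats::rnorm(1, 0, params$sd_do))
      state <- pmax(nxt, c(chl = 0.05, TP_surf = 1, DO_B = 0.2))
    }

    obs <- function(x, f = params$obs_noise_frac) {
      if (f <= 0) return(x)
      pmax(x + stats::rnorm(n, 0, f * stats::sd(x)), 0)
    }
    series <- lake_series(data.frame(
      time = dates,
      DO_B = obs(dob), chl = obs(chl), TP_surf = obs(tps),
      TP_lake = obs(TP_lake), h_mix = pmin(obs(h_mix), params$z_max),
      T_surf = T_surf, T_atm = T_atm, Q = Q))
    truth_df <- data.frame(time = dates, month = mon, light = l, mr = mr,
                           TP_lake = TP_lake, deep_mix = deep,
                           chl = chl, TP_surf = tps, DO_B = dob, truth)
    list(series = series, truth = truth_df,
         winters = do.call(rbind, winters), params = params)
  })
}

#' Coupled logistic maps (cross-mapping benchmark)
#'
#' The canonical two-species benchmark for causal inference:
#' `x(t+1) = x (r1 (1 - x) - b12 y)`, `y(t+1) = y (r2 (1 - y) - b21 x)`.
#' `b21` is the influence of series 1 on series 2 (x drives y) and `b12` the
#' reverse. With one-way forcing, cross-mapping recovers the true direction
#' only.
#'
#' @param r1,r2 logistic growth rates (chaotic for values near 3.5-4).
#' @param b12 effect of y on x; `b21` effect of x on y.
#' @param n series length (>= 100). @param seed RNG seed (random initial
#'   conditions after a burn-in).
#' @param burn burn-in steps discarded (default 200).
#' @return data.frame (t, x, y) with attribute `coupling` = c(b12, b21).
#' @export
simulate_coupled_logistic <- function(r1 = 3.8, r2 = 3.5, b12 = 0, b21 = 0.1,
                                      n = 1000, seed = 1L, burn = 200) {
  stopifnot(r1 > 3, r1 < 4, r2 > 3, r2 < 4, n >= 100, b12 >= 0, b21 >= 0)
  with_seed(seed, {
    x <- stats::runif(1, 0.2, 0.8); y <- stats::runif(1, 0.2, 0.8)
    N <- n + burn
    xs <- numeric(N); ys <- numeric(N)
    for (t in seq_len(N)) {
      xs[t] <- x; ys[t] <- y
      x2 <- x * (r1 * (1 - x) - b12 * y)
      y2 <- y * (r2 * (1 - y) - b21 * x)
      x <- min(max(x2, 1e-6), 1); y <- min(max(y2, 1e-6), 1)
    }
    out <- data.frame(t = seq_len(n), x = xs[(burn + 1):N], y = ys[(burn + 1):N])
    attr(out, "coupling") <- c(b12 = b12, b21 = b21)
    out
  })
}

#' Stationary multivariate autoregressive (MAR(1)) realization
#'
#' The linear-stochastic null for the nonlinearity (theta) test: S-map skill
#' on MAR output should not improve at theta > 0.
#'
#' @param A coefficient matrix (spectral radius < 1).
#' @param sd innovation standard deviation (scalar or per-variable).
#' @param n length. @param seed RNG seed. @param burn burn-in (default 100).
#' @return matrix (n x k) with columns `V1..Vk`.
#' @export
simulate_mar <- function(A, sd = 1, n = 400, seed = 1L, burn = 100) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("coefficient matrix must have spectral radius < 1")
  }
  k <- nrow(A)
  sd <- rep(sd, length.out = k)
  with_seed(seed, {
    x <- rep(0, k)
    out <- matrix(NA_real_, n + burn, k)
    for (t in seq_len(n + burn)) {
      x <- drop(A %*% x) + stats::rnorm(k, 0, sd)
      out[t, ] <- x
    }
    out <- out[(burn + 1):(burn + n), , drop = FALSE]
    colnames(out) <- paste0("V", seq_len(k))
    out
  })
}
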