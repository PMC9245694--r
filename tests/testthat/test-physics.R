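cyl <- hypsometry(c(0, 100), c(1e6, 1e6))

test_that("box volumes follow the hypsometry", {
  v <- box_volumes(cyl, 50)
  expect_equal(v[["V_up"]], v[["V_low"]])
  expect_equal(sum(v), 1e8)
  expect_equal(box_volumes(cyl, 100)[["V_low"]], 0)
  expect_error(box_volumes(cyl, 0), "thermocline")
  expect_error(box_volumes(cyl, 101), "thermocline")

  # cone: A(z) = A0 (1 - z/zmax)^2; below half depth lies 1/8 of the volume
  z <- seq(0, 100, by = 0.1)
  cone <- hypsometry(z, 1e6 * (1 - z / 100)^2 + 1e-6)
  v <- box_volumes(cone, 50)
  expect_equal(v[["V_low"]] / sum(v), 1 / 8, tolerance = 1e-4)
})

test_that("volumes always partition the lake, whatever the thermocline", {
  h <- synthetic_hypsometry()
  total <- layer_volume(h, 0, h$z_max)
  for (d in c(1, 15, 60, 155, 250, 310)) {
    v <- box_volumes(h, d)
    expect_equal(sum(v), total, tolerance = 1e-6 * total)
  }
})

test_that("full winter mixing homogenizes both boxes and conserves oxygen", {
  st <- box_state(10, 4, cyl, 50)
  m0 <- st$DO_up * st$V_up + st$DO_low * st$V_low
  p <- physics_params(k_gas = 0, river_underflow = FALSE)
  st2 <- winter_mix_step(st, mixing_depth = 100, T_surf = 5, params = p)
  expect_equal(st2$DO_up, 7)
  expect_equal(st2$DO_low, 7)
  m1 <- st2$DO_up * st2$V_up + st2$DO_low * st2$V_low
  expect_lt(abs(m1 - m0) / m0, 1e-9)
})

test_that("mixing above the thermocline leaves deep oxygen untouched", {
  st <- box_state(10, 4, cyl, 50)
  p <- physics_params(k_gas = 0, river_underflow = FALSE)
  st2 <- winter_mix_step(st, mixing_depth = 30, T_surf = 5, params = p)
  expect_equal(st2$DO_low, 4)
})

test_that("gas exchange relaxes surface oxygen exponentially toward saturation", {
  p <- physics_params(k_gas = 1, river_underflow = FALSE)
  sat <- do_saturation(5)
  st <- box_state(6, 4, cyl, 50)
  traj <- numeric(40)
  for (i in 1:40) {
    st <- winter_mix_step(st, mixing_depth = 10, T_surf = 5, params = p)
    traj[i] <- st$DO_up
  }
  expect_true(all(diff(c(6, traj)) > 0)) # strictly increasing
  expect_true(all(traj < sat))
  h_up <- st$V_up / 1e6
  expect_equal(traj, sat + (6 - sat) * exp(-(1:40) / h_up), tolerance = 1e-9)
})

test_that("winter river underflow oxygenates the deep box", {
  p <- physics_params(k_gas = 0, river_underflow = TRUE)
  st <- box_state(8, 4, cyl, 50)
  st2 <- winter_mix_step(st, mixing_depth = 10, T_surf = 5, Q = 100,
                         T_river = 5, params = p)
  expect_gt(st2$DO_low, 4)
  expect_lt(st2$DO_low, do_saturation(5))
})

test_that("oxygen mass is conserved under pure mixing over many steps", {
  h <- synthetic_hypsometry()
  st <- box_state(11, 4, h, 60)
  m0 <- st$DO_up * st$V_up + st$DO_low * st$V_low
  p <- physics_params(k_gas = 0, river_underflow = FALSE)
  set.seed(10)
  depths <- runif(1e4, 61, 310)
  for (d in depths) st <- winter_mix_step(st, d, T_surf = 5, params = p)
  m1 <- st$DO_up * st$V_up + st$DO_low * st$V_low
  expect_lt(abs(m1 - m0) / m0, 1e-9)
})

test_that("moving the box boundary conserves mass in both directions", {
  h <- synthetic_hypsometry()
  st <- box_state(11, 5, h, 40)
  m0 <- st$DO_up * st$V_up + st$DO_low * st$V_low
  st2 <- rebox(st, 200)  # deepening entrains deep water upward
  m1 <- st2$DO_up * st2$V_up + st2$DO_low * st2$V_low
  expect_equal(m1, m0, tolerance = 1e-12 * m0)
  st3 <- rebox(st2, 15)  # shoaling detrains surface water downward
  m2 <- st3$DO_up * st3$V_up + st3$DO_low * st3$V_low
  expect_equal(m2, m0, tolerance = 1e-12 * m0)
})

test_that("the surface box sits at a fixed point when production balances nothing", {
  p <- physics_params(k_gas = 1, chl_production = 0.01,
                      surface_respiration = 0, river_underflow = FALSE)
  sat <- do_saturation(15)
  st <- box_state(sat, 6, cyl, 50)
  st2 <- surface_do_update(st, chl = 0, T_surf = 15, params = p)
  expect_equal(st2$DO_up, sat, tolerance = 1e-12)
})

test_that("the default production plug-in is linear in chlorophyll", {
  p <- physics_params(k_gas = 0, surface_respiration = 0, chl_production = 0.01,
                      river_underflow = FALSE)
  st <- box_state(8, 6, cyl, 50)
  d1 <- surface_do_update(st, chl = 5, T_surf = 15, params = p)$DO_up - 8
  d2 <- surface_do_update(st, chl = 10, T_surf = 15, params = p)$DO_up - 8
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("180 days of constant forcing match the linear ODE closed form", {
  p <- physics_params(k_gas = 0.8, chl_production = 0.012,
                      surface_respiration = 0.02, river_underflow = FALSE,
                      photic_depth = 50)
  st <- box_state(7, 6, cyl, 50)
  h_up <- st$V_up / 1e6
  alpha <- p$k_gas / h_up
  sat <- do_saturation(18)
  prod <- p$chl_production * 4 - p$surface_respiration
  DO_inf <- sat + prod / alpha
  for (d in 1:180) st <- surface_do_update(st, chl = 4, T_surf = 18, params = p)
  expect_equal(st$DO_up, DO_inf + (7 - DO_inf) * exp(-alpha * 180),
               tolerance = 1e-6)
})

test_that("oxygen solubility falls with temperature", {
  s <- do_saturation(0:30)
  expect_true(all(diff(s) < 0))
  expect_gt(s[1], 14); expect_lt(s[31], 8.5) # freshwater range, mg/L
  expect_lt(do_saturation(10, pressure_atm = 0.95), do_saturation(10))
})

test_that("hypsometry validation rejects unphysical tables", {
  expect_error(hypsometry(c(5, 10), c(1, 1)), "surface")
  expect_error(hypsometry(c(0, 10), c(1, 2)), "nonincreasing")
  expect_error(hypsometry(c(0, 10), c(1, 0)), "positive")
})
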