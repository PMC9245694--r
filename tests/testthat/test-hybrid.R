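test_that("hindcast metrics are exact on hand-computed fixtures", {
  x <- c(8.2, 7.1, 6.5, 9.0, 10.1)
  ev <- evaluate_hindcast(x, x)
  expect_equal(ev$rho, 1)
  expect_equal(ev$mae, 0)
  ev1 <- evaluate_hindcast(x + 1, x)
  expect_equal(ev1$rho, 1)
  expect_equal(ev1$mae, 1)
  expect_equal(ev1$bias, 1)
  # independent 5-point arithmetic
  a <- c(1, 3, 2, 5, 4); b <- c(2, 2, 3, 4, 6)
  ev2 <- evaluate_hindcast(a, b)
  expect_equal(ev2$mae, mean(abs(a - b)))
  expect_equal(ev2$bias, mean(a - b))
  expect_equal(ev2$rho, cor(a, b))
  expect_error(evaluate_hindcast(1:2, 2:3), "3 overlapping")
  ev3 <- evaluate_hindcast(rep(1, 5), c(1, 2, 1, 2, 1))
  expect_true(is.na(ev3$rho))
  expect_match(ev3$note, "zero-variance")
})

test_that("predictors trained with a cutoff never see later data", {
  lk <- default_lake()$series
  cutoff <- as.Date("1995-12-31")
  preds <- fit_hybrid_predictors(lk, force_theta = 1, train_end = cutoff)
  for (v in names(preds)) expect_true(all(preds[[v]]$lib_time <= cutoff))
})

test_that("summer depletion iterates monthly and reports a season-average rate", {
  preds <- lake_predictors()
  lk <- default_lake()$series
  may <- which(format(lk$time, "%m") == "05")[10]
  state0 <- c(DO_B = 9, chl = lk$chl[may], TP_surf = lk$TP_surf[may])
  phys <- as.data.frame(lk[may + 0:5, c("h_mix", "T_surf", "T_atm", "Q")])
  traj <- summer_depletion(preds, state0, TP_lake = 40, physics = phys)
  expect_equal(nrow(traj), 7) # initial state + 6 monthly steps
  expect_equal(attr(traj, "depletion_rate"),
               (traj$DO_B[1] - traj$DO_B[7]) / 180)
  expect_gte(attr(traj, "depletion_rate"), 0)
})

test_that("depletion responds to phosphorus as built into the generator", {
  preds <- lake_predictors()
  lk <- default_lake()$series
  may <- which(format(lk$time, "%m") == "05")[10]
  phys <- as.data.frame(lk[may + 0:5, c("h_mix", "T_surf", "T_atm", "Q")])
  rate <- function(tp, do0) {
    st <- c(DO_B = do0, chl = lk$chl[may], TP_surf = tp)
    attr(summer_depletion(preds, st, TP_lake = tp, physics = phys),
         "depletion_rate")
  }
  for (do0 in c(7.5, 6)) {
    expect_gt(rate(60, do0), rate(30, do0)) # eutrophic legacy demand dominates
  }
})

test_that("states far outside the training library are flagged as extrapolation", {
  preds <- lake_predictors()
  lk <- default_lake()$series
  may <- which(format(lk$time, "%m") == "05")[10]
  phys <- as.data.frame(lk[may + 0:5, c("h_mix", "T_surf", "T_atm", "Q")])
  st <- c(DO_B = 40, chl = 80, TP_surf = 200) # far off the attractor
  expect_warning(
    traj <- summer_depletion(preds, st, TP_lake = 500, physics = phys),
    "extrapolation")
  expect_true(attr(traj, "extrapolated"))
})

test_that("the hybrid simulation is deterministic and seasonally phased", {
  preds <- lake_predictors(force_theta = 1)
  lk <- default_lake()$series
  short <- lake_series(as.data.frame(lk)[1:96, ]) # 8 years
  forcing <- forcing_from_series(short)
  cfg <- hybrid_config(preds, init = list(DO_up = 10, DO_B = 9))
  h1 <- run_hybrid(cfg, forcing, TP_lake = short$TP_lake)
  h2 <- run_hybrid(cfg, forcing, TP_lake = short$TP_lake)
  expect_identical(h1, h2)
  expect_setequal(unique(h1$phase), c("summer", "winter"))
  mon <- as.integer(format(h1$time, "%m"))
  expect_true(all(h1$phase[mon %in% 5:10] == "summer"))
  expect_true(all(is.finite(h1$DO_B)))
  yr <- attr(h1, "years")
  expect_true(all(c("depletion_rate", "max_mixing_depth") %in% names(yr)))
})

test_that("swapping surrogate forcing for file-based forcing changes no code path", {
  preds <- lake_predictors(force_theta = 1)
  f <- surrogate_physics(6, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_forcing(f, path)
  cfg <- hybrid_config(preds, init = list(DO_up = 10, DO_B = 9))
  h_direct <- run_hybrid(cfg, f, TP_lake = 35)
  h_file <- run_hybrid(cfg, read_forcing(path), TP_lake = 35)
  expect_equal(h_direct, h_file, tolerance = 1e-12)
})
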