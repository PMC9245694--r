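test_that("detrending preserves structure and applies the offset exactly", {
  set.seed(8)
  flat <- rnorm(120)
  flat <- flat - unname(coef(lm(flat ~ seq_along(flat)))[2]) * seq_along(flat)
  expect_equal(detrend_offset(flat, 0), flat, tolerance = 1e-9)

  ramp <- 2 + 0.05 * (1:200)
  out <- detrend_offset(ramp, 1.5)
  expect_equal(out, rep(mean(ramp) + 1.5, 200), tolerance = 1e-9)

  # a phase-symmetric cosine over whole periods is exactly orthogonal to a
  # linear trend on this grid, so detrending must leave it untouched
  t <- 1:240
  seas <- 10 + 5 * cos(2 * pi * (t - mean(t)) / 12)
  x <- seas + 0.01 * t
  out3 <- detrend_offset(x, 3)
  expect_equal(mean(out3), mean(x) + 3, tolerance = 1e-9)
  expect_equal(out3 - mean(out3), seas - mean(seas), tolerance = 1e-8)
})

test_that("the scenario grid enumerates offsets by descending phosphorus", {
  g <- make_grid(dT_set = c(0, 1, 3), TP_min = 15, TP_max = 65, TP_step = 1)
  expect_equal(nrow(g), 153) # 3 offsets x 51 phosphorus levels
  expect_equal(g$dT_air[1:51], rep(0, 51))
  expect_equal(g$TP_const[1:3], c(65, 64, 63))
  expect_equal(nrow(make_grid(dT_set = 0, TP_min = 30, TP_max = 31, TP_step = 1)), 2)
  expect_error(make_grid(TP_min = 30, TP_max = 31, TP_step = 5), "larger")
  expect_error(make_grid(TP_min = 40, TP_max = 30), "TP_min")
})

test_that("the hypoxia benchmark counts time strictly below threshold", {
  expect_equal(hypoxia_fraction(c(1, 2, 3, 5, 6, 7), threshold = 4), 50)
  expect_equal(hypoxia_fraction(c(5, 6, 7)), 0)
  expect_equal(hypoxia_fraction(c(4, 4, 4)), 0) # strictly below
  expect_error(hypoxia_fraction(c(NA_real_, NA)), "all-missing")

  # uneven spacing: midpoint weights, checked by hand
  # times 0,1,2,10; values 5,3,3,5; weights 0.5, 1, 4.5, 4
  # below threshold at t=1,2 -> (1 + 4.5) / 10 = 55%
  expect_equal(hypoxia_fraction(c(5, 3, 3, 5), threshold = 4,
                                time = c(0, 1, 2, 10)), 55)
})

test_that("per-scenario seeds are pure functions of the master seed and label", {
  expect_identical(derive_seed(7, "dT0_TP30"), derive_seed(7, "dT0_TP30"))
  expect_false(derive_seed(7, "dT0_TP30") == derive_seed(7, "dT0_TP31"))
  expect_false(derive_seed(7, "a") == derive_seed(8, "a"))
})

test_that("a one-scenario grid equals a direct hybrid run", {
  preds <- lake_predictors(force_theta = 1)
  cfg <- hybrid_config(preds, init = list(DO_up = 10, DO_B = 9))
  g <- make_grid(dT_set = 0, TP_min = 34, TP_max = 35, TP_step = 1)[1, ]
  res <- run_grid(g, cfg, years = 6, master_seed = 5)
  expect_equal(nrow(res), 1)
  f <- surrogate_physics(6, seed = derive_seed(5, "TP35"), dT_atm = 0)
  direct <- run_hybrid(cfg, f, TP_lake = 35)
  expect_equal(res$hypoxia_pct, hypoxia_fraction(direct$DO_B), tolerance = 1e-12)
  expect_true(is.na(res$error))
})

test_that("scenario failures are recorded, not fatal", {
  preds <- lake_predictors(force_theta = 1)
  cfg <- hybrid_config(preds, init = list(DO_up = 10, DO_B = 9))
  g <- make_grid(dT_set = 0, TP_min = 34, TP_max = 35, TP_step = 1)
  g$TP_const[1] <- NA_real_ # unusable level -> per-scenario error
  res <- run_grid(g, cfg, years = 3, master_seed = 5)
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$hypoxia_pct[1]) != is.na(res$hypoxia_pct[2]))
})
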