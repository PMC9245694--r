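test_that("theta = 0 collapses to one global least-squares fit", {
  set.seed(7)
  n <- 100
  df <- data.frame(time = 1:n, x1 = rnorm(n), x2 = rnorm(n))
  df$y <- 0.5 * df$x1 - 1.2 * df$x2 + rnorm(n, 0, 0.1)
  sm <- state_matrix(lake_series(df), embedding(c("x1", "x2"), "y", tp = 0))
  fit <- smap_forecast(sm, theta = 0, exclusion_radius = -1L)
  lib <- which(sm$valid & !is.na(sm$y))
  ols <- unname(coef(lm(sm$y[lib] ~ sm$x[lib, ])))
  # identical coefficients at every target time, matching lm() to 1e-8
  expect_lt(max(abs(sweep(fit$coefficients, 2, ols))), 1e-8)
})

test_that("S-map predictions match an lm-based locally weighted oracle", {
  set.seed(9)
  x <- logistic_series(60) + rnorm(60, 0, 0.05)
  ts <- lake_series(data.frame(time = seq_along(x), x = x))
  sm <- state_matrix(ts, univariate_embedding("x", 2))
  fit <- smap_forecast(sm, theta = 1.5, exclusion_radius = -1L)
  lib <- which(sm$valid & !is.na(sm$y))
  for (p in fit$predictions$row[c(3, 17, 30)]) {
    ref <- oracle_smap_point(sm$x, sm$y, setdiff(lib, integer(0)), p, theta = 1.5)
    expect_equal(fit$predictions$pred[fit$predictions$row == p], ref,
                 tolerance = 1e-8)
  }
})

test_that("theta does not bias coefficient estimates on a linear system", {
  set.seed(13)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- c(NA, 0.7 * x1[-n] - 0.3 * x2[-n]) + rnorm(n, 0, 0.05)
  ts <- lake_series(data.frame(time = 1:n, x1 = x1, x2 = x2, y = y))
  sm <- state_matrix(ts, embedding(c("x1", "x2"), "y", tp = 1))
  for (th in c(0, 2)) {
    fit <- smap_forecast(sm, theta = th)
    a <- mean(interaction_coefficients(fit, "x1")$coef, na.rm = TRUE)
    b <- mean(interaction_coefficients(fit, "x2")$coef, na.rm = TRUE)
    expect_lt(abs(a - 0.7), 0.05)
    expect_lt(abs(b + 0.3), 0.05)
  }
})

test_that("theta_scan requires the linear reference and reports the scan", {
  ts <- lake_series(data.frame(time = 1:50, x = logistic_series(50)))
  sm <- state_matrix(ts, univariate_embedding("x", 2))
  expect_error(theta_scan(sm, c(1, 2)), "include 0")
  tab <- theta_scan(sm, 0)
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "delta_skill"), 0)
})

test_that("a linear stochastic system shows no nonlinearity gain", {
  A <- matrix(c(0.6, -0.3, 0.2, 0.5), 2, 2)
  m <- simulate_mar(A, sd = 1, n = 400, seed = 5)
  ts <- lake_series(data.frame(time = 1:400, m))
  sm <- state_matrix(ts, embedding(c("V1", "V2"), "V1", tp = 1))
  tab <- theta_scan(sm)
  expect_lt(attr(tab, "delta_skill"), 0.03)
})

test_that("theta = 0 interaction coefficients are constant through time", {
  set.seed(21)
  df <- data.frame(time = 1:80, a = rnorm(80), b = rnorm(80))
  df$y <- df$a - df$b + rnorm(80, 0.1)
  sm <- state_matrix(lake_series(df), embedding(c("a", "b"), "y", tp = 0))
  fit <- smap_forecast(sm, theta = 0, exclusion_radius = -1L)
  co <- interaction_coefficients(fit, "a")
  expect_lt(diff(range(co$coef, na.rm = TRUE)), 1e-10)
  expect_error(interaction_coefficients(fit, "zz"), "zz")
})

test_that("rank-deficient designs fall back to a minimum-norm solution with a warning", {
  set.seed(2)
  df <- data.frame(time = 1:40, a = rnorm(40))
  df$b <- 2 * df$a # collinear coordinate
  df$y <- df$a + rnorm(40, 0, 0.01)
  sm <- state_matrix(lake_series(df), embedding(c("a", "b"), "y", tp = 0))
  expect_warning(fit <- smap_forecast(sm, theta = 0), "rank-deficient")
  expect_true(all(is.finite(fit$predictions$pred)))
})

test_that("sequential embedding comparison rewards real drivers and ignores noise", {
  sim <- default_lake()
  df <- as.data.frame(sim$series)
  set.seed(17)
  df$junk <- rnorm(nrow(df))
  ts <- lake_series(df)
  grid <- c(0, 0.01, 0.1, 0.5, 1, 2, 5, 7.5, 10)
  expect_error(sequential_embedding_comparison(ts, c("T_surf", "chl"),
                                               c("chl"), "DO_B"),
               "disjoint")
  tab <- sequential_embedding_comparison(
    ts, base_vars = c("h_mix", "T_surf", "T_atm", "Q"),
    added_vars = c("chl", "TP_lake"), target = "DO_B", theta_grid = grid)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$embedding[1], "baseline")
  # biogeochemical drivers earn forecast skill, step by step
  expect_gt(tab$skill[2], tab$skill[1] + 0.02)
  expect_gt(tab$skill[3], tab$skill[2] + 0.02)
  best <- attr(tab, "best_spec")
  expect_s3_class(best, "embedding_spec")
  expect_equal(nrow(best$coordinates), tab$E[which.max(tab$skill)])

  # a pure-noise augmentation leaves the baseline's skill unchanged
  tabn <- sequential_embedding_comparison(
    ts, base_vars = c("h_mix", "T_surf", "T_atm", "Q"),
    added_vars = "junk", target = "DO_B", theta_grid = grid)
  expect_lt(abs(tabn$skill[2] - tabn$skill[1]), 0.02)

  # one-row table when nothing is added
  tab0 <- sequential_embedding_comparison(
    ts, base_vars = c("h_mix", "T_surf", "T_atm", "Q"),
    added_vars = character(), target = "DO_B", theta_grid = grid)
  expect_equal(nrow(tab0), 1)
})

test_that("binned interaction summaries use equal-count bins with bootstrap intervals", {
  set.seed(31)
  co <- data.frame(row = 1:200, time = 1:200, coef = rnorm(200, 1))
  cond <- runif(200)
  b <- bin_interactions(co, cond, bins = 4, n_boot = 50)
  expect_equal(nrow(b), 4)
  expect_true(all(abs(b$n - 50) <= 1))
  expect_true(all(b$lower <= b$mean & b$mean <= b$upper))
})
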