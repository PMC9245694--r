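test_that("the cross-map horizon follows the mid-vector protocol", {
  cl <- simulate_coupled_logistic(b21 = 0.3, n = 300, seed = 2)
  for (E in c(4, 5)) {
    r <- ccm(cl$y, cl$x, E_star = E, library_sizes = c(20, 100, 200),
             n_subsamples = 5, rho_crit = 0.5, seed = 1)
    expect_equal(r$tp_used, floor(-E / 2))
  }
})

test_that("E* selection scans the range and shrinks it for short series", {
  cl <- simulate_coupled_logistic(b21 = 0.32, n = 600, seed = 7)
  sel <- select_ccm_E(cl$y, cl$x, E_range = 1:8)
  expect_true(sel$E_star %in% 1:8)
  expect_equal(sel$E_star, sel$table$E[which.max(sel$table$skill)])
  expect_warning(select_ccm_E(cl$y[1:12], cl$x[1:12], E_range = 1:15),
                 "shrunk")
})

test_that("a shuffled cause has flat cross-map skill across E", {
  cl <- simulate_coupled_logistic(b21 = 0.32, n = 500, seed = 9)
  shuffled <- sample(cl$x)
  sel <- select_ccm_E(cl$y, shuffled, E_range = 1:8)
  expect_lt(max(abs(sel$table$skill)), 0.2)
})

test_that("one-way coupled maps cross-map strongly in the true direction only", {
  cl <- simulate_coupled_logistic(r1 = 3.7, r2 = 3.8, b12 = 0, b21 = 0.32,
                                  n = 600, seed = 4)
  r_true <- ccm(cl$y, cl$x, E_star = select_ccm_E(cl$y, cl$x)$E_star,
                n_subsamples = 20, n_surrogates = 40, seed = 8)
  r_false <- ccm(cl$x, cl$y, E_star = select_ccm_E(cl$x, cl$y)$E_star,
                 n_subsamples = 20, n_surrogates = 40, seed = 8)
  last <- function(r) rev(r$skill_curve$rho_mean)[1]
  expect_true(r_true$convergent)
  expect_gt(last(r_true), last(r_false) + 0.3) # markedly weaker reverse map
})

test_that("independent chaotic series are non-convergent in both directions", {
  a <- simulate_coupled_logistic(b21 = 0, n = 500, seed = 5)
  r1 <- ccm(a$y, a$x, E_star = 3, n_subsamples = 15, n_surrogates = 30, seed = 2)
  r2 <- ccm(a$x, a$y, E_star = 3, n_subsamples = 15, n_surrogates = 30, seed = 2)
  expect_false(r1$convergent)
  expect_false(r2$convergent)
  expect_lt(abs(rev(r1$skill_curve$rho_mean)[1]), 0.15)
})

test_that("a single library size yields an undefined verdict, flagged", {
  cl <- simulate_coupled_logistic(b21 = 0.3, n = 300, seed = 3)
  r <- ccm(cl$y, cl$x, E_star = 2, library_sizes = 150, n_subsamples = 5,
           seed = 1)
  expect_true(is.na(r$convergent))
  expect_match(r$note, "insufficient L range")
})

test_that("identical seeds reproduce the skill curve exactly", {
  cl <- simulate_coupled_logistic(b21 = 0.3, n = 400, seed = 6)
  r1 <- ccm(cl$y, cl$x, E_star = 2, n_subsamples = 10, rho_crit = 0.5, seed = 42)
  r2 <- ccm(cl$y, cl$x, E_star = 2, n_subsamples = 10, rho_crit = 0.5, seed = 42)
  expect_identical(r1$skill_curve, r2$skill_curve)
})

test_that("cross-map skill is nondecreasing in library size for coupled pairs", {
  cl <- simulate_coupled_logistic(b21 = 0.32, n = 600, seed = 12)
  r <- ccm(cl$y, cl$x, E_star = 2, n_subsamples = 25, rho_crit = 0.5, seed = 2)
  rho <- r$skill_curve$rho_mean
  expect_true(all(diff(rho) > -0.02)) # monotone within subsampling noise
})

test_that("phase surrogates preserve mean and amplitude spectrum", {
  set.seed(44)
  x <- sin(2 * pi * (1:256) / 12) + rnorm(256, 0, 0.3)
  y <- phase_surrogate(x)
  expect_equal(mean(y), mean(x), tolerance = 1e-9)
  expect_equal(Mod(fft(y))[2:128], Mod(fft(x))[2:128], tolerance = 1e-6)
  expect_gt(sd(y - x), 0) # actually randomized
  expect_error(phase_surrogate(c(1, NA, 3)), "gap-free")
})

test_that("pairwise cross-mapping emits one row per ordered pair, no self-pairs", {
  cl <- simulate_coupled_logistic(b21 = 0.3, n = 250, seed = 13)
  ts <- lake_series(data.frame(time = 1:250, x = cl$x, y = cl$y))
  tab <- ccm_matrix(ts, E_range = 1:4, n_subsamples = 5, n_surrogates = 10,
                    seed = 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$cause != tab$effect))
  expect_true(all(tab$tp_used == floor(-tab$E_star / 2)))
  single <- ccm_matrix(lake_series(data.frame(time = 1:50, x = rnorm(50))))
  expect_equal(nrow(single), 0)
})
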