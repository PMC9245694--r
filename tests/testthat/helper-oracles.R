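# Independent reference implementations used as oracles. These deliberately
# avoid the package's own kNN/WLS code paths: plain R loops and lm().

# brute-force simplex projection: exhaustive neighbour search, exponential
# weights exp(-d/dmin), ties broken by earlier library time
oracle_simplex <- function(X, y, lib, pred, k, r = 0L) {
  vapply(pred, function(p) {
    cand <- lib[abs(lib - p) > r]
    d <- vapply(cand, function(j) sqrt(sum((X[p, ] - X[j, ])^2)), 0)
    o <- order(d, cand)[seq_len(k)]
    dn <- d[o]
    w <- if (dn[1] > 0) exp(-dn / dn[1]) else ifelse(dn == 0, 1, 0)
    sum(w * y[cand[o]]) / sum(w)
  }, numeric(1))
}

# locally weighted regression oracle via lm(): weights exp(-theta d / dbar)
oracle_smap_point <- function(X, y, lib, p, theta) {
  d <- vapply(lib, function(j) sqrt(sum((X[p, ] - X[j, ])^2)), 0)
  w <- exp(-theta * d / mean(d))
  df <- data.frame(y = y[lib], X[lib, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = df, weights = w)
  unname(stats::predict(fit, newdata = as.data.frame(X)[p, , drop = FALSE]))
}

# deterministic logistic-map series
logistic_series <- function(n, r = 3.8, x0 = 0.4, burn = 100) {
  x <- x0
  out <- numeric(n + burn)
  for (t in seq_len(n + burn)) {
    out[t] <- x
    x <- r * x * (1 - x)
  }
  out[(burn + 1):(burn + n)]
}

# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_lake <- function(seed = 1L) {
  cached(paste0("lake", seed), simulate_lake(seed = seed))
}

lake_predictors <- function(seed = 1L, force_theta = NULL) {
  key <- paste0("preds", seed, "_", force_theta %||% "scan")
  cached(key, fit_hybrid_predictors(default_lake(seed)$series,
                                    force_theta = force_theta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
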