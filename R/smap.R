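#' S-map: sequentially locally weighted linear forecasting
#'
#' For each prediction row, library exemplars are weighted by
#' `w_i = exp(-theta * d_i / dbar)`, where `d_i` is the Euclidean distance
#' (on z-normalized coordinates) from the target state to exemplar `i` and
#' `dbar` is the mean library distance to the target. A weighted least-squares
#' regression of `target(t + tp)` on the embedding coordinates plus an
#' intercept (solved by SVD) yields both the forecast and a local coefficient
#' vector. At `theta = 0` all weights are equal and the fit collapses to a
#' single global linear (multivariate autoregressive) regression; as `theta`
#' grows, the regression becomes increasingly state-dependent, and the local
#' coefficients track the system's time-varying Jacobian elements.
#'
#' @param sm a [state_matrix()].
#' @param theta nonlinearity (locality) parameter, >= 0.
#' @param lib,pred library / prediction row indices (default: leave-one-out
#'   over all complete rows).
#' @param exclusion_radius rows within this many steps of the prediction row
#'   are dropped from its library (default: largest lag in the embedding).
#' @return an object of class `smap_fit` with `predictions` (data.frame: row,
#'   time, obs, pred), `coefficients` (one row per prediction; columns
#'   `"(Intercept)"` and one per coordinate, on the normalized-coordinate
#'   scale), `skill`, `mae`, `theta`, plus the frozen library and
#'   normalization needed by [predict.smap_fit()].
#' @export
smap_forecast <- function(sm, theta = 0, lib = NULL, pred = NULL,
                          exclusion_radius = NULL) {
  stopifnot(inherits(sm, "state_matrix"), is.numeric(theta), theta >= 0)
  E <- ncol(sm$x)
  r <- as.integer(exclusion_radius %||% max(sm$spec$coordinates$lag))
  lib <- library_rows(sm, lib)
  if (length(lib) < E + 2L) stop("need at least E + 2 library rows")
  pred <- if (is.null(pred)) lib else intersect(as.integer(pred), which(sm$valid))
  D <- cross_dist(sm$x, pred, lib)
  yhat <- rep(NA_real_, length(pred))
  coefs <- matrix(NA_real_, length(pred), E + 1L,
                  dimnames = list(NULL, c("(Intercept)", colnames(sm$x))))
  rank_warned <- FALSE
  for (i in seq_along(pred)) {
    usable <- abs(lib - pred[i]) > r
    if (sum(usable) < E + 2L) next
    d <- D[i, usable]
    dbar <- mean(d)
    if (dbar == 0) stop("all library points coincide with the target (dbar = 0)")
    w <- exp(-theta * d / dbar)
    if (sum(w > 0) < E + 2L) next
    rows <- lib[usable]
    A <- cbind(1, sm$x[rows, , drop = FALSE])
    fit <- wls_solve(A, sm$y[rows], w)
    if (fit$deficient && !rank_warned) {
      warning("rank-deficient S-map design; minimum-norm solution used")
      rank_warned <- TRUE
    }
    coefs[i, ] <- fit$beta
    yhat[i] <- sum(c(1, sm$x[pred[i], ]) * fit$beta)
  }
  obs <- sm$y[pred]
  structure(list(
    predictions = data.frame(row = pred, time = sm$time[pred], obs = obs, pred = yhat),
    coefficients = coefs,
    skill = safe_cor(obs, yhat),
    mae = mean(abs(obs - yhat), na.rm = TRUE),
    theta = theta, spec = sm$spec,
    center = sm$center, scale = sm$scale,
    lib_x = sm$x[lib, , drop = FALSE], lib_y = sm$y[lib],
    lib_time = sm$time[lib]),
    class = "smap_fit")
}

# weighted least squares via SVD; minimum-norm solution when rank deficient
wls_solve <- function(A, b, w, tol = 1e-10) {
  sw <- sqrt(w)
  sv <- svd(A * sw)
  pos <- sv$d > tol * max(sv$d[1], .Machine$double.xmin)
  beta <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], b * sw) / sv$d[pos])
  list(beta = drop(beta), deficient = !all(pos))
}

#' @export
print.smap_fit <- function(x, ...) {
  cat("<smap_fit> theta =", x$theta, " E =", ncol(x$coefficients) - 1L,
      " rho =", round(x$skill, 3), " mae =", signif(x$mae, 3), "\n")
  invisible(x)
}

#' Forecast new states with a fitted S-map
#'
#' Applies the fitted S-map (frozen library and normalization) to new raw
#' state vectors. This is the engine the hybrid simulator uses: predicted and
#' exogenous variables are assembled into a state vector, normalized with the
#' training statistics, and regressed against the training library.
#'
#' @param object an `smap_fit`.
#' @param newdata data frame or matrix of raw coordinate values; columns
#'   named as `<var>_<lag>` (see [state_matrix()] column names).
#' @param ... unused.
#' @return list with `pred` (numeric forecasts) and `coefficients` (matrix as
#'   in the fit).
#' @export
predict.smap_fit <- function(object, newdata, ...) {
  cn <- colnames(object$lib_x)
  newdata <- as.matrix(as.data.frame(newdata)[, cn, drop = FALSE])
  Xn <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  E <- length(cn)
  npred <- nrow(Xn)
  yhat <- rep(NA_real_, npred)
  coefs <- matrix(NA_real_, npred, E + 1L,
                  dimnames = list(NULL, c("(Intercept)", cn)))
  for (i in seq_len(npred)) {
    d <- sqrt(colSums((t(object$lib_x) - Xn[i, ])^2))
    dbar <- mean(d)
    if (dbar == 0) stop("degenerate library (dbar = 0)")
    w <- exp(-object$theta * d / dbar)
    fit <- wls_solve(cbind(1, object$lib_x), object$lib_y, w)
    coefs[i, ] <- fit$beta
    yhat[i] <- sum(c(1, Xn[i, ]) * fit$beta)
  }
  list(pred = yhat, coefficients = coefs)
}

#' Default theta grid for nonlinearity scans
#' @return numeric vector including 0 and a log-spread of positive values.
#' @export
default_theta_grid <- function() {
  c(0, 1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 0.5, 0.75,
    1, 1.5, 2, 3, 4, 5, 7.5, 10)
}

#' Scan S-map skill over a theta grid (the nonlinearity test)
#'
#' Leave-one-out forecast skill as a function of the nonlinearity parameter.
#' A clear gain of skill at some `theta > 0` over `theta = 0` indicates
#' state-dependent (nonlinear) dynamics; a linear stochastic system shows a
#' flat profile.
#'
#' @param sm a [state_matrix()].
#' @param theta_grid candidate thetas; must contain 0 (the linear reference).
#' @param ... passed to [smap_forecast()].
#' @return data.frame (theta, skill, mae) with attributes `best_theta`,
#'   `best_skill` and `delta_skill` (= best skill minus skill at theta 0).
#' @export
theta_scan <- function(sm, theta_grid = default_theta_grid(), ...) {
  stopifnot(length(theta_grid) > 0)
  if (!any(theta_grid == 0)) stop("theta_grid must include 0")
  rows <- lapply(theta_grid, function(th) {
    f <- tryCatch(smap_forecast(sm, theta = th, ...),
                  error = function(e) stop("theta = ", th, ": ",
                                           conditionMessage(e), call. = FALSE))
    data.frame(theta = th, skill = f$skill, mae = f$mae)
  })
  tab <- do.call(rbind, rows)
  i <- which.max(tab$skill)
  attr(tab, "best_theta") <- tab$theta[i]
  attr(tab, "best_skill") <- tab$skill[i]
  attr(tab, "delta_skill") <- tab$skill[i] - tab$skill[tab$theta == 0][1]
  tab
}

#' Sequential multivariate embedding comparison
#'
#' Evaluates a baseline embedding (typically the physical drivers) and then
#' the baseline augmented by each successive prefix of `added_vars`
#' (typically biogeochemical candidates), scoring each with [theta_scan()].
#' A variable that genuinely drives the target raises the best-theta skill
#' when added; a noise variable leaves it unchanged.
#'
#' @param ts a [lake_series()].
#' @param base_vars character vector of baseline coordinate variables.
#' @param added_vars variables added one at a time, in the given order.
#' @param target predicted variable.
#' @param theta_grid passed to [theta_scan()].
#' @param tp horizon (default 1).
#' @return data.frame (embedding label, E, best_theta, skill) with attribute
#'   `best_spec`, the [embedding()] of the top-scoring row.
#' @export
sequential_embedding_comparison <- function(ts, base_vars, added_vars = character(),
                                            target, theta_grid = default_theta_grid(),
                                            tp = 1L) {
  if (length(intersect(base_vars, added_vars))) {
    stop("base_vars and added_vars must be disjoint")
  }
  specs <- lapply(0:length(added_vars), function(i) {
    embedding(c(base_vars, added_vars[seq_len(i)]), target = target, tp = tp)
  })
  labels <- c("baseline",
              if (length(added_vars)) paste0("+", sapply(seq_along(added_vars),
                function(i) paste(added_vars[seq_len(i)], collapse = "+"))))
  rows <- lapply(seq_along(specs), function(i) {
    sm <- state_matrix(ts, specs[[i]])
    tab <- theta_scan(sm, theta_grid)
    data.frame(embedding = labels[i], E = nrow(specs[[i]]$coordinates),
               best_theta = attr(tab, "best_theta"),
               skill = attr(tab, "best_skill"))
  })
  out <- do.call(rbind, rows)
  attr(out, "best_spec") <- specs[[which.max(out$skill)]]
  attr(out, "specs") <- specs
  out
}

#' Extract a time series of local interaction coefficients
#'
#' Pulls the named coordinate's S-map coefficient at every prediction time.
#' With a mechanistic embedding (one containing the key causal variables)
#' these local regression coefficients approximate the Jacobian partial
#' derivatives of the dynamics, e.g. the effect of phosphorus on chlorophyll.
#' By default the coefficient is rescaled from the normalized-coordinate
#' scale back to raw units, so it is directly a partial derivative
#' d(target)/d(coordinate).
#'
#' @param fit an `smap_fit`.
#' @param coordinate coordinate name, either `"var"` (unique match) or
#'   `"var_lag"`.
#' @param rescale divide by the coordinate's library standard deviation to
#'   return raw-unit partial derivatives (default TRUE).
#' @return data.frame (row, time, coef).
#' @export
interaction_coefficients <- function(fit, coordinate, rescale = TRUE) {
  stopifnot(inherits(fit, "smap_fit"))
  cn <- colnames(fit$coefficients)[-1]
  j <- which(cn == coordinate)
  if (!length(j)) j <- which(sub("_[0-9]+$", "", cn) == coordinate)
  if (length(j) != 1L) {
    stop("coordinate `", coordinate, "` does not identify exactly one of: ",
         paste(cn, collapse = ", "))
  }
  co <- fit$coefficients[, j + 1L]
  if (rescale) co <- co / fit$scale[[j]]
  data.frame(row = fit$predictions$row, time = fit$predictions$time, coef = co)
}

#' Bin an interaction-coefficient series against a conditioning variable
#'
#' Summarizes how an interaction strength depends on system state: the
#' coefficient series is split into equal-count bins of the conditioning
#' variable (e.g. lake-mean phosphorus) and each bin's mean is reported with
#' a bootstrap interval.
#'
#' @param coefs data.frame from [interaction_coefficients()].
#' @param conditioning numeric vector aligned with `coefs` rows.
#' @param bins number of equal-count bins (default 10).
#' @param n_boot bootstrap replicates for the interval (default 200).
#' @param level interval coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame (bin, mid, mean, lower, upper, n).
#' @export
bin_interactions <- function(coefs, conditioning, bins = 10, n_boot = 200,
                             level = 0.95, seed = 1L) {
  ok <- is.finite(coefs$coef) & is.finite(conditioning)
  x <- conditioning[ok]; y <- coefs$coef[ok]
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  g <- cut(x, breaks = br, include.lowest = TRUE)
  alpha <- (1 - level) / 2
  with_seed(seed, {
    out <- lapply(levels(g), function(lv) {
      yy <- y[g == lv]
      bm <- replicate(n_boot, mean(sample(yy, replace = TRUE)))
      data.frame(bin = lv, mid = mean(x[g == lv]), mean = mean(yy),
                 lower = stats::quantile(bm, alpha),
                 upper = stats::quantile(bm, 1 - alpha), n = length(yy))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}
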