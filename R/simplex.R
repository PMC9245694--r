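#' Simplex projection forecasting
#'
#' Nearest-neighbour forecasting in embedding space: each prediction is the
#' weighted mean of the targets of the `E + 1` nearest library neighbours,
#' with weights `exp(-d_i / d_min)` where `d_min` is the distance to the
#' nearest neighbour. If `d_min = 0`, all zero-distance neighbours receive
#' weight 1 and the remainder a machine-epsilon-guarded weight (effectively
#' 0), so an exact state match reproduces its own future. Neighbour ties are
#' broken by earlier time index, making forecasts deterministic.
#'
#' @param sm a [state_matrix()].
#' @param lib integer row indices forming the library (default: all rows with
#'   complete embedding and observed target).
#' @param pred integer row indices to predict (default `lib`).
#' @param num_neighbors number of neighbours; default `E + 1`.
#' @param exclusion_radius rows within this many time steps of a prediction
#'   row are excluded from its library (leave-one-out leakage guard). Default
#'   is the largest lag in the embedding, and the prediction row itself is
#'   always excluded.
#' @return an object of class `simplex_fit`: a list with `predictions`
#'   (data.frame: row, time, obs, pred), `skill` (Pearson rho), `mae`, `E`.
#' @export
simplex_project <- function(sm, lib = NULL, pred = NULL,
                            num_neighbors = NULL,
                            exclusion_radius = NULL) {
  stopifnot(inherits(sm, "state_matrix"))
  E <- ncol(sm$x)
  k <- as.integer(num_neighbors %||% (E + 1L))
  r <- as.integer(exclusion_radius %||% max(sm$spec$coordinates$lag))
  lib <- library_rows(sm, lib)
  pred <- if (is.null(pred)) lib else intersect(as.integer(pred), which(sm$valid))
  if (length(lib) < k + 1L) stop("library too small for ", k, " neighbours")
  D <- cross_dist(sm$x, pred, lib)
  yhat <- simplex_knn(D, lib, pred, sm$y, k, r)
  obs <- sm$y[pred]
  res <- data.frame(row = pred, time = sm$time[pred], obs = obs, pred = yhat)
  structure(list(predictions = res, skill = safe_cor(obs, yhat),
                 mae = mean(abs(obs - yhat), na.rm = TRUE), E = E,
                 num_neighbors = k, exclusion_radius = r),
            class = "simplex_fit")
}

# core nearest-neighbour projection given a precomputed distance matrix
# D[i, j] = distance from pred[i] to lib[j]; returns forecasts for pred
simplex_knn <- function(D, lib, pred, y, k, r) {
  .simplex_knn_cpp(D, as.integer(lib), as.integer(pred), as.numeric(y),
                   as.integer(k), as.integer(r))
}

#' @export
print.simplex_fit <- function(x, ...) {
  cat("<simplex_fit> E =", x$E, " rho =", round(x$skill, 3),
      " mae =", signif(x$mae, 3), "\n")
  invisible(x)
}

#' Univariate simplex forecast over a series
#'
#' Convenience wrapper: builds the lag-0..(E-1) delay embedding of a single
#' variable and runs leave-one-out [simplex_project()].
#'
#' @param ts a [lake_series()] (or numeric vector, wrapped internally).
#' @param var variable name (ignored for a numeric vector).
#' @param E embedding dimension.
#' @param tp prediction horizon (default 1).
#' @param ... passed to [simplex_project()].
#' @return a `simplex_fit`.
#' @export
simplex <- function(ts, var = NULL, E = 2L, tp = 1L, ...) {
  ts <- as_series(ts, var)
  var <- lake_vars(ts)[1]
  sm <- state_matrix(ts, univariate_embedding(var, E, tp = tp))
  simplex_project(sm, ...)
}

#' Select the univariate embedding dimension by forecast skill
#'
#' Leave-one-out simplex skill is evaluated for each dimension in `E_range`;
#' the argmax is returned (ties broken toward the smaller dimension).
#'
#' @param ts a [lake_series()] or numeric vector.
#' @param var variable name.
#' @param E_range candidate dimensions (default 1:10).
#' @param tp horizon.
#' @return list with `E` (selected), `table` (data.frame E, skill, mae).
#' @export
select_E <- function(ts, var = NULL, E_range = 1:10, tp = 1L) {
  ts <- as_series(ts, var)
  var <- lake_vars(ts)[1]
  n_ok <- sum(!is.na(ts[[var]]))
  E_range <- E_range[E_range + 2L < n_ok]
  if (!length(E_range)) stop("series too short for requested E range")
  tab <- do.call(rbind, lapply(E_range, function(E) {
    f <- simplex(ts, var, E = E, tp = tp)
    data.frame(E = E, skill = f$skill, mae = f$mae)
  }))
  best <- tab$E[which.max(tab$skill)]
  list(E = best, table = tab)
}

as_series <- function(ts, var = NULL) {
  if (inherits(ts, "lake_series")) return(ts)
  if (is.numeric(ts)) {
    nm <- var %||% "x"
    df <- data.frame(time = seq_along(ts))
    df[[nm]] <- as.numeric(ts)
    return(lake_series(df))
  }
  stop("expected a lake_series or numeric vector")
}
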