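#' Specify a (multivariate) delay embedding
#'
#' An embedding is a list of `(variable, lag)` coordinates plus a prediction
#' target and horizon. `E`, the embedding dimension, is the number of
#' coordinates. `tp` may be negative (used by cross-mapping, where the
#' estimate is anchored mid-vector).
#'
#' @param coordinates either a character vector of variable names (all lag 0),
#'   or a data frame with columns `var` and `lag`, or a list of
#'   `c(name, lag)` pairs.
#' @param target name of the predicted variable.
#' @param tp prediction horizon in grid steps (default 1).
#' @return an object of class `embedding_spec`.
#' @export
embedding <- function(coordinates, target, tp = 1L) {
  coords <- normalize_coords(coordinates)
  if (nrow(coords) == 0L) stop("empty coordinate list")
  key <- paste(coords$var, coords$lag)
  if (anyDuplicated(key)) stop("duplicate (variable, lag) coordinates")
  stopifnot(is.character(target), length(target) == 1L)
  structure(list(coordinates = coords, target = target, tp = as.integer(tp)),
            class = "embedding_spec")
}

normalize_coords <- function(coordinates) {
  if (is.data.frame(coordinates)) {
    stopifnot(all(c("var", "lag") %in% names(coordinates)))
    coords <- data.frame(var = as.character(coordinates$var),
                         lag = as.integer(coordinates$lag))
  } else if (is.character(coordinates)) {
    coords <- data.frame(var = coordinates, lag = 0L)
  } else if (is.list(coordinates)) {
    coords <- data.frame(var = vapply(coordinates, function(p) as.character(p[[1]]), ""),
                         lag = vapply(coordinates, function(p) as.integer(p[[2]]), 0L))
  } else stop("unrecognized coordinate specification")
  if (any(coords$lag < 0L)) stop("lags must be >= 0")
  coords
}

#' Lags 0..(E-1) of a single variable
#' @param var variable name.
#' @param E embedding dimension.
#' @param target target variable (default `var`).
#' @param tp prediction horizon.
#' @return an `embedding_spec`.
#' @export
univariate_embedding <- function(var, E, target = var, tp = 1L) {
  embedding(data.frame(var = var, lag = 0:(E - 1L)), target = target, tp = tp)
}

#' @export
print.embedding_spec <- function(x, ...) {
  cat("<embedding> E =", nrow(x$coordinates), " target =", x$target,
      " tp =", x$tp, "\n coords:",
      paste0(x$coordinates$var, "(-", x$coordinates$lag, ")", collapse = ", "),
      "\n")
  invisible(x)
}

coord_names <- function(spec) {
  paste0(spec$coordinates$var, "_", spec$coordinates$lag)
}

#' Build the state matrix induced by an embedding
#'
#' Row `t` of the state matrix holds the lagged coordinates
#' `x_j(t - lag_j)`; the target column holds `target(t + tp)`. Coordinates
#' are z-normalized using the library rows only, so distances are computed on
#' a scale-free space. Rows with any missing lag are masked out, never
#' imputed.
#'
#' @param ts a [lake_series()] on a uniform grid.
#' @param spec an [embedding()].
#' @param lib optional integer vector of library row indices used for the
#'   normalization statistics (default: all rows valid in both embedding and
#'   target).
#' @return an object of class `state_matrix` with elements `x` (normalized
#'   matrix), `raw`, `y` (target at horizon, raw units), `time`, `valid`
#'   (rows with complete embedding), `center`, `scale`, `spec`.
#' @export
state_matrix <- function(ts, spec, lib = NULL) {
  stopifnot(inherits(spec, "embedding_spec"))
  vars <- unique(c(spec$coordinates$var, spec$target))
  missing_vars <- setdiff(vars, names(ts))
  if (length(missing_vars)) {
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  }
  n <- nrow(ts)
  if (max(spec$coordinates$lag) >= n) stop("lag exceeds series length")
  raw <- vapply(seq_len(nrow(spec$coordinates)), function(j) {
    shift_lag(ts[[spec$coordinates$var[j]]], spec$coordinates$lag[j])
  }, numeric(n))
  colnames(raw) <- coord_names(spec)
  y <- shift_lead(ts[[spec$target]], spec$tp)
  valid <- rowSums(is.na(raw)) == 0L
  if (!any(valid)) stop("all embedding rows are masked (no complete rows)")
  if (is.null(lib)) lib <- which(valid & !is.na(y))
  ctr <- colMeans(raw[lib, , drop = FALSE])
  scl <- apply(raw[lib, , drop = FALSE], 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance coordinate(s): ",
         paste(colnames(raw)[scl == 0], collapse = ", "))
  }
  x <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  structure(list(x = x, raw = raw, y = y, time = ts$time,
                 valid = valid, center = ctr, scale = scl, spec = spec),
            class = "state_matrix")
}

#' @export
print.state_matrix <- function(x, ...) {
  cat("<state_matrix> E =", ncol(x$x), ", ", sum(x$valid), "valid rows of",
      nrow(x$x), "\n")
  invisible(x)
}

# rows usable as library exemplars: complete embedding + observed target
library_rows <- function(sm, lib = NULL) {
  ok <- which(sm$valid & !is.na(sm$y))
  if (is.null(lib)) ok else intersect(as.integer(lib), ok)
}

# pairwise Euclidean distances between pred rows and lib rows of a matrix
cross_dist <- function(X, pred, lib) {
  P <- X[pred, , drop = FALSE]
  L <- X[lib, , drop = FALSE]
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * tcrossprod(P, L)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
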