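# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Used so that per-scenario random streams are a pure function of the master
#' seed and the scenario label: permuting or extending a scenario grid never
#' shifts the seeds of existing scenarios.
#'
#' @param master integer master seed.
#' @param label character label.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.numeric(master) %% 2147483647
  for (k in utf8ToInt(paste(label, collapse = "|"))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# lag a vector by k steps (k >= 0): result[t] = x[t - k]
shift_lag <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  c(rep(NA_real_, k), x[seq_len(n - k)])
}

# lead a vector by k steps (k may be negative): result[t] = x[t + k]
shift_lead <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k > 0L) c(x[-seq_len(k)], rep(NA_real_, k)) else shift_lag(x, -k)
}

# Pearson correlation that tolerates missing values and degenerate input
safe_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])
}
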