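# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

stop_semdec <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_semdec(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_finite_matrix <- function(x, name) {
  if (!is.matrix(x)) stop_semdec(sprintf("`%s` must be a matrix", name))
  if (anyNA(x) || any(!is.finite(x))) {
    stop_semdec(sprintf("`%s` contains non-finite values", name))
  }
  x
}

# Pearson correlation that returns NA (instead of erroring/warning) when
# either input is constant; used where the caller defines the NA policy.
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}
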