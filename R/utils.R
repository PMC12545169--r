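#' @keywords internal
"_PACKAGE"

# Monitor geometry: the display subtends +/-54 deg azimuth and +/-38 deg
# elevation of visual field; screen centre is (0, 0), azimuth positive
# rightward, elevation positive upward.
MONITOR_AZ <- c(-54, 54)
MONITOR_EL <- c(-38, 38)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Nearest-rank (type 1) quantile used for the tuning-curve rescaling.
quantile1 <- function(x, p) {
  stats::quantile(x, probs = p, type = 1, names = FALSE, na.rm = TRUE)
}

# Count spikes of one sorted spike-time vector in windows [lo_i, hi_i).
count_in_windows <- function(times, lo, hi) {
  findInterval(hi, times, left.open = FALSE) - findInterval(lo, times)
}

# Population variance (divide by n): the convention used throughout the
# variance-decomposition analyses so ratios are scale-consistent.
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
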