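# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

#' Convert t-statistics to standard-normal deviates
#'
#' Maps a Student-t statistic with `df` degrees of freedom to the z-value with
#' the same cumulative tail probability. Computed in log-probability space so
#' that far-tail statistics do not underflow to +/-Inf prematurely.
#'
#' @param t numeric vector of t-statistics.
#' @param df degrees of freedom (scalar).
#' @return numeric vector of z-values.
#' @export
t_to_z <- function(t, df) {
  if (!is.numeric(df) || length(df) != 1L || df <= 0)
    stopf("'df' must be a positive scalar")
  z <- t
  ok <- is.finite(t)
  neg <- ok & t <= 0
  pos <- ok & t > 0
  # work in the lower tail for each sign to preserve precision
  z[neg] <- qnorm(pt(t[neg], df, lower.tail = TRUE, log.p = TRUE), log.p = TRUE)
  z[pos] <- -qnorm(pt(-t[pos], df, lower.tail = TRUE, log.p = TRUE), log.p = TRUE)
  z
}

# z-score a vector with the n-1 denominator; errors on constants when `name` given
zscore_vec <- function(x, name = NULL) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    if (!is.null(name)) stopf("variable '%s' is constant (or non-finite); cannot standardize", name)
    return(x - mean(x))
  }
  (x - mean(x)) / s
}

# evaluate expr under a private RNG stream; caller's stream is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic child seeds derived from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
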