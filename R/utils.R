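#' @useDynLib syllakin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx lm median na.omit p.adjust pchisq pnorm prcomp
#'   rnorm runif sd setNames var wilcox.test
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# standard error of the mean, NA-safe
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# Fold a coordinate into [0, size] as if reflected at both walls.
reflect_into <- function(x, size) {
  y <- x %% (2 * size)
  size - abs(y - size)
}
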