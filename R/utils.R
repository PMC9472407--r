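#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom rexp median sd var
#'   quantile binom.test wilcox.test ks.test glm binomial coef vcov cmdscale
#'   dist rank complete.cases plogis qlogis uniroot setNames
#' @importFrom utils head tail
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic per-stage seed fan-out
#'
#' One user-facing seed drives every stochastic stage of a run. Each stage
#' gets its own child seed via a Lehmer-style counter scheme:
#' `child = (seed * 48271 + stage_counter) mod (2^31 - 1)`, mapped away from
#' zero. Stage counters are fixed small integers, so adding stages never
#' perturbs the seeds of existing ones.
#'
#' @param seed integer master seed.
#' @param stage integer stage counter (>= 0), or a known stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
fanout_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(freqs = 1L, genotypes = 2L, phenotypes = 3L, aggressiveness = 4L,
                missingness = 5L, haplotypes = 6L, proxies = 7L, ages = 8L,
                downsample = 9L, weights = 10L, world = 11L, evaluation = 12L)
    if (!stage %in% names(stages)) stopf("unknown stage name '%s'", stage)
    stage <- stages[[stage]]
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number")
  m <- 2147483647
  child <- (abs(as.double(seed)) %% m * 48271 + as.double(stage)) %% m
  as.integer(child %% (m - 2) + 1)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stopf("%s must be finite numeric", name)
  bad_lo <- if (open_lower) x <= lower else x < lower
  bad_hi <- if (open_upper) x >= upper else x > upper
  if (any(bad_lo | bad_hi))
    stopf("%s must be in %s%g, %g%s", name,
          if (open_lower) "(" else "[", lower, upper,
          if (open_upper) ")" else "]")
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("%s must be TRUE or FALSE", name)
  invisible(x)
}

#' Sample standard deviation scaling used throughout the package (n - 1).
#' @noRd
sample_scale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("zero variance: cannot standardize")
  (x - mean(x)) / s
}
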