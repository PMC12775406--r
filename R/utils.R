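#' Natural-abundance isotope ratios
#'
#' Standard reference ratios used as the non-enriched baseline:
#' 13C/12C = 0.0112372 (VPDB) and 15N/14N = 0.0036765 (atmospheric N2).
#'
#' @return Named numeric vector with elements \code{r13C} and \code{r15N}.
#' @export
naturalRatios <- function() c(r13C = 0.0112372, r15N = 0.0036765)

# Deterministic sub-seed per simulation entity, so population, stack and
# count simulations are independently reproducible from one master seed.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483629)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# mean/sd -> lognormal parameters (meanlog, sdlog)
lognormalParams <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
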