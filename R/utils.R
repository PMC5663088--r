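#' @importFrom stats rpois rbinom runif rnorm cor median qlogis plogis
#' @importFrom stats pchisq p.adjust dpois chisq.test fisher.test
#' @importFrom stats wilcox.test smooth.spline predict approxfun glm anova
#' @importFrom stats as.formula model.matrix coef quantile sd setNames
#' @importFrom methods is new
#' @importClassesFrom vcfR vcfR
#' @importFrom utils head tail write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is restored afterwards so that seeded helpers do not
## perturb enclosing simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

xo_log <- function(...) message("[xomap] ", ...)

## Add-one empirical p-value: never 0, floored at 1/(n_perm + 1).
empirical_p <- function(observed, null, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  r <- if (alternative == "greater") sum(null >= observed) else sum(null <= observed)
  (1 + r) / (1 + length(null))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
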