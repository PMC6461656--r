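#' @importFrom stats rnorm runif rpois rbinom rlnorm rgamma quantile median mad
#'   sd var coef vcov pnorm anova as.formula complete.cases aggregate qnorm
#'   fisher.test wilcox.test setNames p.adjust dhyper
#' @importFrom utils write.csv read.csv head tail
NULL

## Deterministic 31-bit stream seed for (master seed, string id).  Adding
## animals to a cohort must never perturb the streams of existing ones.
deriveSeed <- function(masterSeed, id) {
  stopifnot(is.numeric(masterSeed), length(masterSeed) == 1L)
  h <- masterSeed %% 2147483647
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Truncated normal by rejection; bounds are hard constraints of the stated
## world (e.g. fast anastomotic delays stay strictly inside the 1.3 s rule).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
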