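# internal helpers shared across modules

#' @importFrom stats rnorm runif rbinom setNames complete.cases sd cor.test rbeta
#' @importFrom utils read.delim write.table modifyList
NULL

# canonical locus key used for all merges and joins
locus_key <- function(chrom, pos, unit) paste(chrom, pos, unit, sep = ":")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run code under a temporary RNG state so library functions that need a seed
# do not perturb the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# population order is fixed package-wide; argmax ties resolve in this order
AIM_POPS <- c("AFR", "EUR", "EAS", "AMR")

ANCESTRY_GROUPS <- c("AFR", "EUR", "EAS", "AdmixedAMR", "NonadmixedAMR", "PAC")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
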