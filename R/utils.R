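#' @keywords internal
"_PACKAGE"

#' @importFrom stats pbinom ppois rpois rbinom rnorm runif rbeta median
#'   quantile fisher.test wilcox.test p.adjust hclust dist cor setNames
#'   rlnorm as.dist
#' @importFrom utils read.table write.table packageVersion
NULL

# Canonical time-point grid.  "6h" is optional (Tet-on scenario) and never
# participates in persistent/transient labelling.
TIMEPOINTS <- c("0h", "6h", "24h", "72h", "proB")
CORE_TIMEPOINTS <- c("0h", "24h", "72h", "proB")
INDUCED_TIMEPOINTS <- c("24h", "72h", "proB")
SITE_CLASSES <- c("preexisting", "gain24", "gain72", "gainproB", "transient")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so stochastic internals (shuffles,
#' permutation tests, generators) never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed from a master seed by a fixed offset, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order a timepoint label vector along the canonical grid.
order_timepoints <- function(tps) {
  unknown <- setdiff(tps, TIMEPOINTS)
  if (length(unknown)) {
    stopf("unknown time point label(s): %s", paste(unknown, collapse = ", "))
  }
  TIMEPOINTS[TIMEPOINTS %in% tps]
}
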