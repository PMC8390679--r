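#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is new
#' @importFrom stats approx bw.nrd0 cutree density dist dnbinom hclust
#'   optimize p.adjust pnorm prcomp pt quantile rlnorm rmultinom rnbinom
#'   rnorm runif sd setNames var cor
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

#' Derive a named per-stage seed substream from one root seed
#'
#' Every source of randomness in the pipeline draws its seed from the global
#' seed through this map, keeping stages independently reproducible. All
#' derived seeds are valid 32-bit integers.
#'
#' @param seed Root integer seed.
#' @param stage Substream name (e.g. `"simulate"`, `"cluster"`, `"de"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(
    simulate = 1L, qc = 2L, ambient = 3L, normalize = 4L, cluster = 5L,
    signatures = 6L, pseudotime = 7L, regulons = 8L, de = 9L, tiebreak = 10L,
    fit = 11L, band = 12L, dip = 13L
  )
  if (!stage %in% names(offs)) stop("unknown seed substream: ", stage)
  as.integer((as.numeric(seed) * 97L + offs[[stage]] * 1000003) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf(
      "%s must be in %s%g, %g%s, got %s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]",
      format(x)
    ), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == floor(x) && x >= min
  if (!ok) stop(sprintf("%s must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
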