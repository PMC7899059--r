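#' @importFrom rlang abort warn %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Deterministic substream scheme: one global seed is expanded into independent
# per-stage, per-unit streams so that adding observers or stages never perturbs
# existing draws. stream = (seed * 1009 + stage * 101 + unit) mod (2^31 - 2) + 1.
stage_codes <- c(simulate = 1L, group = 2L, fit = 3L, evidence = 4L, recover = 5L)

substream_seed <- function(seed, stage, unit = 0L) {
  stage_id <- stage_codes[[stage]]
  as.integer((as.numeric(seed) * 1009 + stage_id * 101 + unit) %% 2147483645 + 1)
}

with_substream <- function(seed, stage, unit = 0L, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stage, unit))
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Four-parameter logistic in the decreasing-denominator form used throughout:
# l1 + (l0 - l1) / (1 + (x / x0)^k); tends to l0 as x -> 0+ and l1 as x -> Inf.
logistic_curve <- function(x, l0, l1, x0, k) {
  l1 + (l0 - l1) / (1 + (x / x0)^k)
}

is_binary <- function(x) all(x %in% c(0, 1))

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
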