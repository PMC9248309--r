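`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.finite_check <- function(x, what = "data") {
  rng <- suppressWarnings(range(x))
  if (anyNA(x) || any(is.infinite(rng)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(TRUE)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    .assert(is.finite(seed), "seed must be a finite number")
    set.seed(as.integer(seed))
  }
  expr
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
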