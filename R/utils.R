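# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from a single top-level seed, so every
# source of randomness in a run flows from one integer. Keyed by stage name
# so that adding a stage never shifts the streams of the others. Kept within
# the 32-bit integer range R requires of set.seed().
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + key * 10007) %% 2147483647)
}

assert_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0(what, " must be a finite numeric vector"))
  }
  invisible(x)
}

# Closed-interval run extraction over a contiguous grid: maximal runs of TRUE.
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}
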