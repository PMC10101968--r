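# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded generators are pure
#' functions of their seed without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number, got: ", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic child seed from a master seed and a stream index,
# kept below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147480017)
}

stopif_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

# round half away from zero (printed tables use half-up on positives)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# column-wise min/max of an index matrix (faster than apply for the
# large arr.ind matrices used throughout)
col_range <- function(m) {
  lo <- vapply(seq_len(ncol(m)), function(c) min(m[, c]), 0)
  hi <- vapply(seq_len(ncol(m)), function(c) max(m[, c]), 0)
  rbind(lo = lo, hi = hi)
}
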