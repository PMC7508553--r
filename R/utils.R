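# Internal helpers: clamping, seeding, logging.

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Derive a child seed from a root seed
#'
#' Hierarchical seeding: every lineage/line/replicate gets its own stream
#' derived deterministically from `(root, index)`, so adding more units to a
#' run never perturbs units that already exist.
#'
#' @param root Integer root seed.
#' @param index Non-negative integer index of the child stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root),
            is.numeric(index), all(index >= 0))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  r <- as.double(root) %% m
  # two rounds of a multiplicative mix, all intermediates < 2^53
  s <- (r * 48271) %% m
  s <- (s + as.double(index) * 69621 + 1) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

ml_log <- function(..., verbose = getOption("mitolevel.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[mitolevel] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
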