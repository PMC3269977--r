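# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Per-operation random streams: every stochastic operation mixes the user seed
# with a fixed operation offset so stages can be re-run independently while a
# full pipeline stays reproducible end to end.  Keep results < 2^31.
.OP_OFFSETS <- c(
  ancestral   = 1L,
  equilibrate = 2L,
  diverge     = 3L,
  trios       = 4L
)

#' @keywords internal
.op_seed <- function(seed, op, index = 0L) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single finite number")
  off <- .OP_OFFSETS[[op]]
  as.integer((abs(as.numeric(seed)) + 1299709 * off + 7368787 * index) %% 2147483629)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
#' @keywords internal
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
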