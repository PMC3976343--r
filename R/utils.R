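# Internal helpers: deterministic RNG substreams and seed scoping.

# Mix a master seed with integer ids into a substream seed in [1, 2^31-2].
# Each (lot, passage, well, field) gets its own stream so regenerating a
# subset of the design reproduces exactly the same pixels.
substream_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  s <- 0
  for (x in ids) {
    s <- (s * 69069 + (as.numeric(x) + 1) * 2654435761) %% 2147483629
  }
  as.integer(s %% 2147483629 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sample_id <- function(lot, passage) sprintf("lot%s_p%d", lot, as.integer(passage))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run bulk summarisation quietly: degenerate-distribution warnings (zero
# interquartile range, zero-denominator ratios) are expected for sparse
# features like hole area; collapse them into one summary message.
quiet_degenerate <- function(expr) {
  n <- 0L
  out <- withCallingHandlers(expr, warning = function(w) {
    if (grepl("zero interquartile range|zero denominator",
              conditionMessage(w))) {
      n <<- n + 1L
      invokeRestart("muffleWarning")
    }
  })
  if (n > 0)
    message(n, " degenerate distribution statistic(s) set to 0/sentinel")
  out
}
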