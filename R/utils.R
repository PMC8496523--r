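# Internal helpers shared across modules.

# Classed error conditions so callers can catch specific failures
# (e.g. "unreachable_facility") without string matching.
mc_condition <- function(class, message, data = list()) {
  structure(
    class = c(class, "microcatch_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
}

mc_stop <- function(class, message, data = list()) {
  stop(mc_condition(class, message, data))
}

# Round half away from zero (Table-2 display convention); base round()
# uses banker's rounding and would disagree on *.5 values.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Derive a deterministic sub-stream seed from the master seed so the
# network / grid / facility / case generators draw from independent
# sequences. Always < 2^31 and exactly representable.
substream_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2146483) * 1000 + k * 7 + 11) %% 2147483647
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
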