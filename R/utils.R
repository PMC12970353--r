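# internal helpers

# classed conditions so callers can distinguish failure modes programmatically
cb_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "cb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# run code with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

# vectorized population count (number of set bits per element)
popcount <- function(x) {
  x <- as.integer(x)
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + x %% 2L
    x <- x %/% 2L
  }
  out
}

# baby-step/giant-step base used by the rotation key set: the smallest power
# of two whose square covers the row size N/2
bsgs_base <- function(slot_count) {
  half <- slot_count / 2
  base <- 1L
  while (base * base < half) base <- base * 2L
  base
}

# number of key-switched rotations needed for a row rotation by `steps`
# (vectorized): one giant step plus one baby step, either possibly absent
rotation_ops <- function(steps, slot_count) {
  base <- bsgs_base(slot_count)
  steps <- as.integer(steps) %% as.integer(slot_count / 2)
  (steps %/% base > 0L) + (steps %% base > 0L)
}
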