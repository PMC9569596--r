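# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  genv <- globalenv()
  if (!exists(".Random.seed", envir = genv, inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = genv)
  on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  set.seed(seed)
  code
}

# scalar integer-ish check
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

stop_lp <- function(...) stop(sprintf(...), call. = FALSE)
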