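# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# monotonic clock in seconds; proc.time elapsed is monotonic within a session
mono_time <- function() {
  unname(proc.time()["elapsed"])
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# deterministic child seed derived from a base seed; kept below 2^31
derive_seed <- function(seed, salt) {
  as.integer(((as.numeric(seed) * 1103 + as.numeric(salt) * 12289) %% 2147483629) + 1)
}
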