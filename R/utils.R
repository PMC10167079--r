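# Internal helpers shared across modules.

# Deterministic derivation of sub-stream seeds from a master seed.
# Keeps results < 2^31 so they remain valid R integer seeds.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483629
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 7919 + k * 104729) %% 2147483629
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Largest-remainder integer allocation of `total` across quotas `w`
# (non-negative, sums need not be integer). Returns integer vector summing
# to `total`, each entry >= floor(w) and differing from w by < 1.
largest_remainder <- function(w, total) {
  base <- floor(w)
  rem <- w - base
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(rem, decreasing = FALSE)
    take <- ord[seq_len(-short)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
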