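# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's RNG stream afterwards; NULL seed leaves RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder apportionment of n into length(fracs) integer parts.
alloc_counts <- function(n, fracs) {
  stopifnot(abs(sum(fracs) - 1) < 1e-9)
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
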