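# Run code with a local, restored RNG state so package functions are
# reproducible without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically expand a global seed into per-stage child seeds,
# kept below 2^31 so they remain valid R integers.
derive_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash over the tag string, mod a prime < 2^31
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
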