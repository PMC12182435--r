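# Internal deterministic RNG (Park-Miller minimal standard LCG).
#
# All stochastic components of the package (mock predictor background,
# presenter weight matrices, synthetic worlds, cohort sampling) draw from
# private LCG streams rather than R's global RNG, so results are
# byte-identical across platforms and never perturb, nor are perturbed by,
# the caller's RNG state. Substreams are keyed by mixing arbitrary tokens
# into a seed, so adding donors does not shift patient genotypes.

.LCG_M <- 2147483647  # 2^31 - 1, Mersenne prime modulus
.LCG_A <- 48271       # multiplier; products stay < 2^53, exact in doubles

.lcgNew <- function(seed) {
  s <- as.double(seed) %% .LCG_M
  if (s <= 0) s <- s + .LCG_M - 1
  env <- new.env(parent = emptyenv())
  env$state <- s
  env
}

.lcgNext <- function(rng) {
  rng$state <- (.LCG_A * rng$state) %% .LCG_M
  rng$state
}

# n uniforms in (0, 1)
.lcgUnif <- function(rng, n = 1L) {
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- .lcgNext(rng) / .LCG_M
  out
}

# n integers uniform on 1..max
.lcgInt <- function(rng, n, max) {
  pmin(floor(.lcgUnif(rng, n) * max) + 1L, max)
}

# sample of size n from 1..length(prob) with given weights (with replacement)
.lcgSampleProb <- function(rng, n, prob) {
  cw <- cumsum(prob) / sum(prob)
  findInterval(.lcgUnif(rng, n), cw, left.open = TRUE) + 1L
}

# sample n distinct values from 1..max (partial Fisher-Yates)
.lcgSampleNoReplace <- function(rng, n, max) {
  stopifnot(n <= max)
  pool <- seq_len(max)
  out <- integer(n)
  for (i in seq_len(n)) {
    j <- .lcgInt(rng, 1L, max - i + 1L)
    out[i] <- pool[j]
    pool[j] <- pool[max - i + 1L]
  }
  out
}

# Mix arbitrary tokens (numbers/strings) into a seed in 1..(2^31-2).
.lcgMix <- function(...) {
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- 104729
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 131 + code + 7) %% (.LCG_M - 1)
    }
    h <- (h * 131 + 257) %% (.LCG_M - 1)
  }
  as.double(h) + 1
}
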