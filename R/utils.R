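## Internal helpers shared across modules.

## Boltzmann constant, J/K
.kB <- 1.380649e-23

## Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so generator calls do not perturb user code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic sub-seed derivation (all arithmetic kept < 2^31).
deriveSeed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts)
    h <- (h * 7919 + (as.numeric(p) %% 104729) + 1) %% 2147483629
  as.integer(h) + 1L
}

## Root-mean-square about the mean (the Sq convention).
rmsAboutMean <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

## Quadrant swap so that the DC bin of an M x M DFT sits at (M/2+1, M/2+1).
fftShift2 <- function(x) {
  m <- nrow(x)
  idx <- c((m %/% 2 + 1L):m, 1L:(m %/% 2))
  x[idx, idx, drop = FALSE]
}

## Signed centred frequency index for 1-based position i in an M-point DFT.
.centredIndex <- function(m) {
  i <- seq_len(m) - 1L
  ifelse(i <= m %/% 2, i, i - m)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
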