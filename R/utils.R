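# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Cumulative trapezoidal integral on the frame mid-time grid, anchored at
# (0, 0): activity is taken to be zero at injection. This single operator is
# shared by the tissue-curve generator and the Patlak transform, which makes
# the noiseless Patlak relation exactly linear on the frame grid.
cumTrapz0 <- function(t, a) {
  stopifnot(length(t) == length(a), all(t > 0), !is.unsorted(t))
  n <- length(t)
  seg <- c(0.5 * t[1] * a[1],
           if (n > 1) 0.5 * (a[-1] + a[-n]) * diff(t) else numeric())
  cumsum(seg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
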