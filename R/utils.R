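## Internal helpers shared across modules.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Centered moving average; the window shrinks symmetrically at the edges so
# no samples are lost. width is forced odd.
movingAverage <- function(x, width = 5L) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

# First time at which a series crosses `level`, linearly interpolated.
# Returns NA_real_ when there is no crossing.
firstCrossing <- function(times, values, level) {
  d <- values - level
  hit <- which(d == 0)
  cross <- which(d[-length(d)] * d[-1] < 0)
  cand <- c(times[hit],
            if (length(cross)) {
              i <- cross
              times[i] + (times[i + 1] - times[i]) * (-d[i]) / (d[i + 1] - d[i])
            })
  if (!length(cand)) return(NA_real_)
  min(cand)
}

# Min-max rescale to [0, 1]; errors on a constant vector.
rescale01 <- function(v, what = "series") {
  rng <- range(v)
  if (rng[2] <= rng[1])
    stop("degenerate ", what, ": max equals min, cannot normalize")
  (v - rng[1]) / (rng[2] - rng[1])
}
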