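# shared internal helpers

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Wrap angles to (-pi, pi].
wrap_angle <- function(x) {
  y <- atan2(sin(x), cos(x))
  y[y <= -pi] <- pi
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Population (divide-by-n) standard deviation along rows of a matrix.
row_pop_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

default_channel_labels <- function(n) {
  # emitter-detector channel names of a standard 14-channel frontal montage;
  # generic labels otherwise
  frontal <- c(
    "Fpz-Fp1", "Fpz-Fp2", "Fpz-AFz", "AF3-Fp1", "AF3-AFz", "AF3-F1",
    "AF4-Fp2", "AF4-AFz", "AF4-F2", "Fz-AFz", "Fz-F1", "Fz-F2",
    "F3-F1", "F4-F2"
  )
  if (n == length(frontal)) frontal else sprintf("ch%02d", seq_len(n))
}
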