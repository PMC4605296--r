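# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; on-disk BED/BED-PE follow the BED convention
# (identical), and printed reports are 1-based inclusive.

stop_usage <- function(msg) rlang::abort(msg, class = "nucmap_usage_error")
stop_input <- function(msg) rlang::abort(msg, class = "nucmap_input_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log(exp(a) + exp(b)), elementwise, safe for -Inf.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Sliding-window sum of x over windows of length k; result length n - k + 1.
moving_sum <- function(x, k) {
  n <- length(x)
  if (k > n) return(numeric(0))
  cs <- cumsum(x)
  cs[k:n] - c(0, cs)[1:(n - k + 1)]
}

# 1-based R indexing of a 0-based genomic position.
idx <- function(pos0) pos0 + 1L

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
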