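# Internal helpers shared across modules.

# round() uses banker's rounding at .5; thresholds here are defined round-half-up.
round_half_up <- function(x) floor(x + 0.5)

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic helpers do not disturb an enclosing
#' simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Centered moving average with edge truncation: near the ends the window is
# clipped to the available samples and the mean taken over what remains.
moving_average <- function(x, width) {
  n <- length(x)
  if (width > n) width <- n
  lo_half <- (width - 1L) %/% 2L
  hi_half <- width - 1L - lo_half
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - lo_half, 1L)
  hi <- pmin(i + hi_half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of local maxima: strictly greater than both neighbours; an interior
# plateau flanked by lower values on both sides counts once, at its leftmost
# sample. Boundary samples are never maxima. Falls back to which.max() when
# no interior maximum exists.
local_maxima <- function(w) {
  n <- length(w)
  if (n < 3L) return(which.max(w))
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        out <- c(out, starts[j])
    }
  }
  if (length(out) == 0L) out <- which.max(w)
  out
}

scatter_channels <- function() c("scatter405", "scatter488", "scatter633")

all_channels <- function() c(scatter_channels(), "gfp525", "red670")
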