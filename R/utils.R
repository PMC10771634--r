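#' @keywords internal
"_PACKAGE"

## condition helpers ---------------------------------------------------------

tug_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "tug_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format       <- function(fmt, ...) tug_stop("tug_format_error", fmt, ...)
stop_parameter    <- function(fmt, ...) tug_stop("tug_parameter_error", fmt, ...)
stop_segmentation <- function(fmt, ...) tug_stop("tug_segmentation_error", fmt, ...)
stop_gait         <- function(fmt, ...) tug_stop("tug_gait_error", fmt, ...)

## RNG scoping ---------------------------------------------------------------

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## small numeric helpers -----------------------------------------------------

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smoothstep ramp: 0 at u <= 0, 1 at u >= 1, C1-continuous in between.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Contiguous runs of TRUE in a logical vector; returns start/end (inclusive).
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
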