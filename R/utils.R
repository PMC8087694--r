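# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom stats median mad sd cor lm anova coef pchisq pf pt qt t.test
#'   rnorm rpois runif complete.cases lowess approx fivenum quantile setNames
#' @importFrom utils head tail
NULL

# Centered moving average; ends are padded by shrinking the window so the
# output has the same length as the input.
moving_average <- function(x, width = 3L) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local extrema of a numeric vector: indices where the first difference
# changes sign. `kind` selects minima ("min"), maxima ("max") or both.
local_extrema <- function(x, kind = c("both", "min", "max")) {
  kind <- match.arg(kind)
  d <- sign(diff(x))
  # collapse zero-slope plateaus onto the preceding slope
  for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
  flips <- which(d[-1] != d[-length(d)]) + 1L
  if (kind == "min") flips <- flips[d[flips] > 0]
  if (kind == "max") flips <- flips[d[flips] < 0]
  flips
}

# First local extremum of `x` at or beyond `from`, scanning in `direction`
# (+1 right, -1 left). Returns NA_integer_ if none found.
next_extremum <- function(x, from, direction, kind = c("min", "max"),
                          limit = NULL) {
  kind <- match.arg(kind)
  n <- length(x)
  if (is.null(limit)) limit <- if (direction > 0) n else 1L
  idx <- from
  repeat {
    nxt <- idx + direction
    if (nxt <= 1L || nxt >= n) return(NA_integer_)
    if (direction > 0 && nxt > limit) return(NA_integer_)
    if (direction < 0 && nxt < limit) return(NA_integer_)
    if (x[nxt] <= x[nxt - 1L] && x[nxt] <= x[nxt + 1L]) {
      if (kind == "min" && nxt != from) return(nxt)
    }
    if (x[nxt] >= x[nxt - 1L] && x[nxt] >= x[nxt + 1L]) {
      if (kind == "max" && nxt != from) return(nxt)
    }
    idx <- nxt
  }
}

# First crossing of `level`, scanning from `from` in `direction`; the trace is
# expected to start on one side of the level. Returns a fractional sample
# index (linear interpolation between the bracketing samples), or NA_real_.
next_crossing <- function(x, from, level, direction, limit = NULL) {
  n <- length(x)
  if (is.null(limit)) limit <- if (direction > 0) n else 1L
  s0 <- sign(x[from] - level)
  if (s0 == 0) return(as.numeric(from))
  idx <- from
  repeat {
    nxt <- idx + direction
    if (nxt < 1L || nxt > n) return(NA_real_)
    if (direction > 0 && nxt > limit) return(NA_real_)
    if (direction < 0 && nxt < limit) return(NA_real_)
    v <- x[nxt] - level
    if (sign(v) != s0) {
      prev <- x[idx] - level
      frac <- prev / (prev - v)
      return(idx + direction * frac)
    }
    idx <- nxt
  }
}

# Evaluate a sum of Gaussian bumps at sample positions `t` (same units as
# centers/sd). Vectorized over bumps; assumes `t` is an increasing uniform
# grid so each bump's support maps to an index range arithmetically.
gaussian_bumps <- function(t, centers, sds, amps) {
  out <- numeric(length(t))
  n <- length(t)
  if (n < 2) return(out)
  dt <- t[2] - t[1]
  for (i in seq_along(centers)) {
    lo <- max(1L, ceiling((centers[i] - 5 * sds[i] - t[1]) / dt) + 1L)
    hi <- min(n, floor((centers[i] + 5 * sds[i] - t[1]) / dt) + 1L)
    if (lo <= hi) {
      sel <- lo:hi
      out[sel] <- out[sel] +
        amps[i] * exp(-((t[sel] - centers[i])^2) / (2 * sds[i]^2))
    }
  }
  out
}

cosine24 <- function(t_h, mesor, amplitude, acrophase_h, period = 24) {
  mesor + amplitude * cos(2 * pi * (t_h - acrophase_h) / period)
}

circular_mean_h <- function(hours, period = 24) {
  ang <- hours * 2 * pi / period
  m <- atan2(mean(sin(ang)), mean(cos(ang)))
  out <- (m * period / (2 * pi)) %% period
  if (period - out < 1e-9) out <- 0
  out
}

resultant_length <- function(hours, period = 24) {
  ang <- hours * 2 * pi / period
  sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
}

# Maximum-likelihood inverse of A1(kappa) for the von Mises concentration,
# piecewise approximation (Fisher 1993).
a1inv <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
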