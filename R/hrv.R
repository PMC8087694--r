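# Robust geometric heart-rate variability on relative RR intervals.

#' Relative RR intervals
#'
#' \eqn{r_i = 2 (RR_i - RR_{i-1}) / (RR_i + RR_{i-1})}: dimensionless,
#' exactly invariant under uniform rescaling of all RR intervals, hence
#' insensitive to the absolute heart rate.
#'
#' @param rr numeric vector of RR intervals (ms), length >= 2, positive.
#' @return Numeric vector of length `length(rr) - 1`.
#' @export
relative_rr <- function(rr) {
  rr <- rr[!is.na(rr)]
  if (length(rr) < 2) abort("need at least 2 RR intervals")
  if (any(rr <= 0)) abort("RR intervals must be positive")
  2 * diff(rr) / (rr[-length(rr)] + rr[-1])
}

#' Geometric HRV measure on the relative-RR Poincare cloud
#'
#' Consecutive relative-RR pairs \eqn{(r_i, r_{i+1})} form a Poincare point
#' set; the measure is 100 times the median Euclidean distance of the points
#' from the set's component-wise median. Both the relative-RR core and the
#' median aggregation make it insensitive to isolated outliers and to
#' changes in absolute heart rate.
#'
#' @param rr numeric vector of RR intervals (ms), length >= 3.
#' @return An object of class `hrv_result`: list with `measure` (%),
#'   `n_pairs`, `rel_rr`, and the Poincare `points` tibble. With fewer than
#'   two pairs the measure is `NA`.
#' @export
geometric_hrv <- function(rr) {
  rr <- rr[!is.na(rr)]
  if (length(rr) < 3) {
    return(structure(list(measure = NA_real_, n_pairs = 0L,
                          rel_rr = numeric(0),
                          points = tibble::tibble(x = numeric(0),
                                                  y = numeric(0))),
                     class = "hrv_result"))
  }
  r <- relative_rr(rr)
  pts <- tibble::tibble(x = r[-length(r)], y = r[-1])
  cx <- median(pts$x); cy <- median(pts$y)
  d <- sqrt((pts$x - cx)^2 + (pts$y - cy)^2)
  structure(
    list(measure = 100 * median(d), n_pairs = nrow(pts), rel_rr = r,
         points = pts),
    class = "hrv_result"
  )
}

#' @export
print.hrv_result <- function(x, ...) {
  cat("<hrv_result> measure:", format(x$measure, digits = 4), "% over",
      x$n_pairs, "pairs\n")
  invisible(x)
}

#' @exportS3Method
tidy.hrv_result <- function(x, ...) {
  tibble::tibble(measure = x$measure, n_pairs = x$n_pairs)
}
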