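# Quantile discretization of the continuous composites.
#
# The network is discrete, so the OQ and RFL mean composites are binned into
# k training-quantile levels. Intervals are left-closed/right-open except
# the last; values outside the training range clamp to the extreme levels.
# Composite means of a few Likert items are heavily tied (a 4-item mean
# takes at most 17 values), so a naive interpolated quantile can fall on a
# tied block and move the whole block across an edge; edges are therefore
# snapped to boundaries between distinct observed values.

#' Fit a quantile discretizer
#'
#' Each interior edge is an empirical quantile made tie-aware: among the
#' boundaries between consecutive distinct observed values, the edge for
#' level j is placed (at the midpoint of the bracketing values) where the
#' cumulative sample share is closest to j/k. A tied block is never split,
#' and on tie-free data the edges coincide with ordinary sample quantiles
#' up to one observation.
#'
#' @param values Numeric training values.
#' @param k Number of levels (default 3).
#' @return An object of class `pvq_discretizer` with the k-1 interior
#'   edges.
#' @export
fit_discretizer <- function(values, k = 3) {
  k <- as.integer(k)
  if (k < 2) rlang::abort("k must be >= 2", class = "pvq_degenerate_error")
  values <- values[is.finite(values)]
  u <- sort(unique(values))
  m <- length(u)
  if (m < k) {
    rlang::abort(sprintf("need at least %d distinct values to fit %d bins", k, k),
                 class = "pvq_degenerate_error")
  }
  cum <- cumsum(tabulate(match(values, u), nbins = m)) / length(values)
  idx <- integer(k - 1)
  last <- 0L
  for (j in seq_len(k - 1)) {
    avail <- seq.int(last + 1L, m - 1L - (k - 1L - j))
    idx[j] <- avail[which.min(abs(cum[avail] - j / k))]
    last <- idx[j]
  }
  edges <- (u[idx] + u[idx + 1L]) / 2
  structure(list(edges = edges, k = k), class = "pvq_discretizer")
}

#' Apply a fitted discretizer
#'
#' @param disc A `pvq_discretizer` from [fit_discretizer()].
#' @param value Numeric vector.
#' @return Integer levels 1..k. Values below the first edge map to 1, at or
#'   above the last edge to k; level boundaries are left-closed
#'   (value == edge goes to the upper level).
#' @export
apply_discretizer <- function(disc, value) {
  stopifnot(inherits(disc, "pvq_discretizer"))
  as.integer(findInterval(value, disc$edges)) + 1L
}
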