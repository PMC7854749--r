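#' Start days of the 10-day compositing grid
#'
#' The growing season (day-of-year 90-300) is discretized into 22 ten-day
#' intervals with start days 90, 100, ..., 300; interval i covers
#' `[start, start + 10)`. 22 intervals (not 21) are used so that the per-proxy
#' time-series block contributes 10 x 22 = 220 crop features.
#'
#' @return Integer vector of length 22.
#' @export
interval_starts <- function() seq.int(90L, 300L, by = 10L)

#' 10-day median composite of an irregular series
#'
#' Aggregates valid observations into the fixed 22-interval grid using the
#' median; intervals with no valid observation are marked as gaps (`NA`).
#' Non-finite values (e.g. an index with zero denominator) are treated as
#' invalid.
#'
#' @param doys Integer vector of observation days-of-year.
#' @param values Numeric vector of the proxy at each observation.
#' @param valid Logical vector; `FALSE` marks cloud-contaminated observations.
#' @return A `regular_series`: list with `grid` (the 22 start days), `values`
#'   (median or `NA`), `filled` (logical, `TRUE` where a later stage
#'   interpolated the value; all `FALSE` here).
#' @export
composite_10day <- function(doys, values, valid = rep(TRUE, length(doys))) {
  stopifnot(length(doys) == length(values), length(valid) == length(values))
  grid <- interval_starts()
  keep <- valid & is.finite(values)
  idx <- findInterval(doys[keep], c(grid, 310L))
  v <- values[keep]
  inside <- idx >= 1L & idx <= length(grid) & doys[keep] < 310
  out <- rep(NA_real_, length(grid))
  if (any(inside)) {
    med <- tapply(v[inside], idx[inside], stats::median)
    out[as.integer(names(med))] <- med
  }
  structure(list(grid = grid, values = out, filled = rep(FALSE, length(grid))),
            class = "regular_series")
}

#' Fill gaps of a regular series by linear interpolation
#'
#' Interior gaps are linearly interpolated between the nearest non-gap
#' neighbours (on the interval start-day axis); leading/trailing gaps take the
#' nearest observed value, so filling never extrapolates outside the observed
#' range. The `filled` mask records which intervals were interpolated.
#'
#' @param rs A `regular_series` from [composite_10day()].
#' @return A gap-free `regular_series`.
#' @export
fill_gaps <- function(rs) {
  stopifnot(inherits(rs, "regular_series"))
  obs <- !is.na(rs$values)
  if (!any(obs)) stop("all intervals are gaps: series unclassifiable")
  if (all(obs)) return(rs)
  filled <- if (sum(obs) == 1L) rep(rs$values[obs], length(rs$grid))
  else stats::approx(rs$grid[obs], rs$values[obs], xout = rs$grid,
                     method = "linear", rule = 2)$y
  rs$filled <- rs$filled | !obs
  rs$values <- filled
  rs
}

#' Savitzky-Golay filter coefficients
#'
#' Least-squares derivation: fit a polynomial of degree `order` to `window`
#' equally spaced points and evaluate it at offset `at` from the window centre.
#' `at = 0` gives the classical smoothing weights.
#'
#' @param window Odd window length in points.
#' @param order Polynomial order, `< window`.
#' @param at Evaluation offset from the centre (integer in
#'   `-(window-1)/2 ... (window-1)/2`).
#' @return Numeric weight vector of length `window`.
#' @export
sg_coefficients <- function(window = 7L, order = 3L, at = 0L) {
  if (window %% 2L != 1L) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  h <- (window - 1L) / 2L
  z <- seq.int(-h, h)
  A <- outer(z, 0:order, `^`)
  # row of A (A'A)^-1 A' for evaluation point `at`
  e <- (at)^(0:order)
  as.numeric(A %*% solve(crossprod(A), e))
}

#' Savitzky-Golay smoothing of a gap-free regular series
#'
#' Applies the (window, order) Savitzky-Golay filter. The defaults are a
#' 70-day window (7 ten-day points) and a 3rd-order polynomial. Edges are
#' handled by evaluating the least-squares polynomial of the first/last full
#' window at the edge positions (asymmetric weights), so any polynomial of
#' degree `<= order` passes the filter unchanged everywhere, including the
#' endpoints.
#'
#' @param rs A gap-free `regular_series`, or a plain numeric vector.
#' @param window,order Filter configuration; `window` odd, `order < window`.
#' @return Object of the same kind as the input, smoothed.
#' @export
sg_smooth <- function(rs, window = 7L, order = 3L) {
  vec_in <- !inherits(rs, "regular_series")
  x <- if (vec_in) as.numeric(rs) else rs$values
  if (anyNA(x)) stop("sg_smooth requires a gap-free series; run fill_gaps first")
  n <- length(x)
  if (n < window) stop("series shorter than the smoothing window")
  h <- (window - 1L) / 2L
  out <- numeric(n)
  centre <- sg_coefficients(window, order, 0L)
  for (i in seq_len(n)) {
    if (i <= h) {
      w <- sg_coefficients(window, order, i - 1L - h)
      out[i] <- sum(w * x[1:window])
    } else if (i > n - h) {
      w <- sg_coefficients(window, order, i - (n - h))
      out[i] <- sum(w * x[(n - window + 1L):n])
    } else {
      out[i] <- sum(centre * x[(i - h):(i + h)])
    }
  }
  if (vec_in) return(out)
  rs$values <- out
  rs
}

#' Regularize one observation series into smoothed 10-day proxy series
#'
#' Full per-pixel temporal pipeline, in the fixed order: (1) per-observation
#' proxy computation, (2) 10-day median compositing of valid observations,
#' (3) linear gap filling, (4) Savitzky-Golay smoothing.
#'
#' @param series An `obs_series` (see [simulate_series()]).
#' @param window,order Savitzky-Golay configuration.
#' @param rep_literal Passed to [proxy_matrix()].
#' @return Numeric matrix, 10 proxies x 22 intervals, with dimnames.
#' @export
regularize_series <- function(series, window = 7L, order = 3L,
                              rep_literal = FALSE) {
  stopifnot(inherits(series, "obs_series"))
  pm <- proxy_matrix(series$reflectance, rep_literal = rep_literal)
  out <- matrix(NA_real_, nrow = 10L, ncol = 22L,
                dimnames = list(proxy_names(), interval_starts()))
  for (p in proxy_names()) {
    rs <- composite_10day(series$doys, pm[, p], series$valid)
    rs <- fill_gaps(rs)
    out[p, ] <- sg_smooth(rs, window, order)$values
  }
  out
}
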