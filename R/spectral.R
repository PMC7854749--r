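#' Band names of an 8-band reflectance observation
#'
#' Order of the reflectance columns used throughout the package:
#' blue (B2), red (B4), red-edge 1-3 (B5-B7), NIR (B8A), SWIR1 (B11),
#' SWIR2 (B12). All values are top-of-atmosphere reflectance in \[0, 1\].
#'
#' @return Character vector of length 8.
#' @export
band_names <- function() {
  c("blue", "red", "re1", "re2", "re3", "nir", "swir1", "swir2")
}

#' Names of the 10 per-observation proxies
#'
#' The three reflectance bands (RE2, SWIR1, SWIR2) and seven spectral indices
#' (NDVI, EVI, LSWI, NDSVI, NDTI, RENDVI, REP) from which every feature in the
#' cropland and crop banks derives.
#'
#' @return Character vector of length 10.
#' @export
proxy_names <- function() {
  c("re2", "swir1", "swir2",
    "ndvi", "evi", "lswi", "ndsvi", "ndti", "rendvi", "rep")
}

.as_band_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  missing <- setdiff(band_names(), colnames(x))
  if (length(missing) > 0L)
    stop("missing reflectance bands: ", paste(missing, collapse = ", "))
  x
}

.nd <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[den == 0] <- NaN
  out
}

#' Compute a spectral index or band passthrough
#'
#' Evaluates one of the seven vegetation/water/tillage indices, or returns the
#' RE2/SWIR1/SWIR2 band unchanged. Index names are accepted case-insensitively.
#' Zero denominators yield `NaN` (treated downstream as gaps), never an error.
#'
#' The red-edge position supports two forms. The default
#' `REP = 705 + 35 * ((0.5 * (re3 + red) - re1) / (re2 - re1))`
#' is the standard linear-interpolation red-edge position. `rep_literal = TRUE`
#' instead divides the entire `705 + 35 * (...)` numerator by `(re2 - re1)`,
#' reproducing a dimensionally inconsistent variant that occasionally appears
#' in print.
#'
#' @param x Named numeric vector (one observation) or matrix/data frame with
#'   the 8 band columns of [band_names()].
#' @param name Index name: one of `ndvi`, `evi`, `lswi`, `ndsvi`, `ndti`,
#'   `rendvi`, `rep`, `re2`, `swir1`, `swir2`.
#' @param rep_literal Use the literal typeset REP variant (default `FALSE`).
#' @return Numeric vector, one value per observation.
#' @examples
#' spectral_index(c(blue = .05, red = .1, re1 = .1, re2 = .2, re3 = .3,
#'                  nir = .4, swir1 = .1, swir2 = .05), "ndvi")
#' @export
spectral_index <- function(x, name, rep_literal = FALSE) {
  x <- .as_band_matrix(x)
  name <- tolower(name)
  if (length(name) != 1L) stop("'name' must be a single index name")
  b <- function(nm) unname(x[, nm])
  switch(name,
    re2    = b("re2"),
    swir1  = b("swir1"),
    swir2  = b("swir2"),
    ndvi   = .nd(b("nir"), b("red")),
    lswi   = .nd(b("nir"), b("swir1")),
    ndsvi  = .nd(b("swir1"), b("red")),
    ndti   = .nd(b("swir1"), b("swir2")),
    rendvi = .nd(b("nir"), b("re2")),
    evi    = {
      den <- b("nir") + 6 * b("red") - 7.5 * b("blue") + 1
      out <- 2.5 * (b("nir") - b("red")) / den
      out[den == 0] <- NaN
      out
    },
    rep = {
      den <- b("re2") - b("re1")
      num <- 0.5 * (b("re3") + b("red")) - b("re1")
      out <- if (rep_literal) (705 + 35 * num) / den else 705 + 35 * num / den
      out[den == 0] <- NaN
      out
    },
    stop("unknown index name: ", name)
  )
}

#' All 10 proxies for a set of observations
#'
#' @param x Matrix/data frame of 8-band reflectances (see [band_names()]).
#' @param rep_literal Passed to [spectral_index()].
#' @return Numeric matrix, observations x 10 proxies (see [proxy_names()]).
#' @export
proxy_matrix <- function(x, rep_literal = FALSE) {
  x <- .as_band_matrix(x)
  out <- vapply(proxy_names(), function(nm)
    spectral_index(x, nm, rep_literal = rep_literal),
    numeric(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, proxy_names()))
  out
}

.rescale01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))

#' Surrogate cloud score
#'
#' A documented stand-in for adjusted cloud-score screening of top-of-atmosphere
#' imagery. Clouds are bright in the aerosol and visible bands and moist (low
#' SWIR relative to NIR); snow is excluded through the snow index. The score is
#' the minimum of four rescaled criteria, each clipped to \[0, 1\]:
#'
#' * brightness in blue, rescaled over \[0.1, 0.3\];
#' * brightness in aerosols + visible mean, rescaled over \[0.2, 0.8\]
#'   (monotonically non-decreasing in visible brightness);
#' * moisture: NDMI = (nir - swir1) / (nir + swir1), rescaled over \[-0.1, 0.3\];
#' * not-snow: NDSI = (green - swir1) / (green + swir1), rescaled downward over
#'   \[0.8, 0.6\] so that strong snow signatures suppress the score.
#'
#' @param x Named vector or matrix with columns `aerosols`, `blue`, `green`,
#'   `red`, `nir`, `swir1`.
#' @param threshold Observations with score above this are flagged cloudy
#'   (default 0.2).
#' @return A data.frame with columns `score` and `cloudy`.
#' @export
cloud_score <- function(x, threshold = 0.2) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  need <- c("aerosols", "blue", "green", "red", "nir", "swir1")
  missing <- setdiff(need, colnames(x))
  if (length(missing) > 0L)
    stop("cloud_score needs bands: ", paste(missing, collapse = ", "))
  ndmi <- .nd(x[, "nir"], x[, "swir1"])
  ndsi <- .nd(x[, "green"], x[, "swir1"])
  vis <- (x[, "blue"] + x[, "green"] + x[, "red"]) / 3
  s <- pmin(
    .rescale01(x[, "blue"], 0.1, 0.3),
    .rescale01(x[, "aerosols"] + vis, 0.2, 0.8),
    .rescale01(ndmi, -0.1, 0.3),
    .rescale01(ndsi, 0.8, 0.6)
  )
  s[is.na(s)] <- 1 # undefined ratios are treated as contaminated
  data.frame(score = as.numeric(s), cloudy = as.numeric(s) >= threshold)
}
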