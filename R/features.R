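#' Crop-calendar stage windows
#'
#' Fixed day-of-year windows of the Northeast-China crop calendar used for
#' seasonal metrics and texture images: seeding 109-169, growth 170-230,
#' harvest 231-291, and the full growing season 90-300.
#'
#' @return Named list of length-2 integer vectors.
#' @export
stage_windows <- function() {
  list(seeding = c(109L, 169L), growth = c(170L, 230L),
       harvest = c(231L, 291L), season = c(90L, 300L))
}

.stage_cols <- function(stage) {
  w <- stage_windows()[[stage]]
  which(interval_starts() >= w[1] & interval_starts() <= w[2])
}

#' Seasonal (per-stage median) metrics
#'
#' For each of the 10 proxies and each of the three crop stages, the median of
#' the regular-series values whose interval start day lies inside the stage
#' window: 30 features.
#'
#' @param reg 10 x 22 proxy matrix from [regularize_series()].
#' @return Named numeric vector of length 30 (`<proxy>_med_<stage>`).
#' @export
seasonal_metrics <- function(reg) {
  stages <- c("seeding", "growth", "harvest")
  out <- unlist(lapply(stages, function(s) {
    cols <- .stage_cols(s)
    v <- apply(reg[, cols, drop = FALSE], 1, stats::median)
    names(v) <- paste0(rownames(reg), "_med_", s)
    v
  }))
  out
}

#' Annual (growing-season) metrics
#'
#' Ten statistics per proxy over the 22 regular-series values: min, max, mean,
#' standard deviation, amplitude (max - min) and the 5/25/50/75/95th
#' percentiles (linear interpolation between order statistics): 100 features.
#'
#' @param reg 10 x 22 proxy matrix from [regularize_series()].
#' @return Named numeric vector of length 100 (`<proxy>_<stat>`).
#' @export
annual_metrics <- function(reg) {
  stats_one <- function(v) {
    q <- stats::quantile(v, c(.05, .25, .50, .75, .95), names = FALSE, type = 7)
    c(min = min(v), max = max(v), mean = mean(v), std = stats::sd(v),
      amp = max(v) - min(v),
      p05 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5])
  }
  out <- unlist(lapply(rownames(reg), function(p) {
    v <- stats_one(reg[p, ])
    names(v) <- paste0(p, "_", names(v))
    v
  }))
  out
}

#' Names of the 18 co-occurrence texture statistics
#' @return Character vector of length 18.
#' @export
glcm_stat_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "diff_variance", "diff_entropy",
    "imc1", "imc2", "mcc", "dissimilarity", "inertia", "cluster_shade",
    "cluster_prominence")
}

#' Quantize an image to gray levels
#'
#' Equal-width bins over the finite min-max range; a constant image maps to a
#' single level. `NA` pixels stay `NA`.
#'
#' @param img Numeric matrix.
#' @param levels Number of gray levels (default 32).
#' @return Integer matrix of levels in `1..levels`.
#' @export
quantize_image <- function(img, levels = 32L) {
  rng <- range(img, na.rm = TRUE, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2])
    return(matrix(ifelse(is.na(img), NA_integer_, 1L), nrow(img), ncol(img)))
  q <- pmin(levels, floor((img - rng[1]) / (rng[2] - rng[1]) * levels) + 1L)
  matrix(as.integer(q), nrow(img), ncol(img))
}

#' Gray-level co-occurrence texture statistics of an image
#'
#' Computes the 18 second-order texture statistics (angular second moment,
#' contrast, correlation, variance, inverse difference moment, sum average,
#' sum variance, sum entropy, entropy, difference variance, difference
#' entropy, the two information measures of correlation, maximal correlation
#' coefficient, dissimilarity, inertia, cluster shade, cluster prominence)
#' from symmetric, normalized co-occurrence matrices, averaged over the four
#' standard one-pixel offsets (0,1), (1,0), (1,1), (1,-1). The image is
#' quantized to `levels` gray levels unless `quantized = TRUE`.
#'
#' Degenerate conventions: correlation of a zero-variance matrix is 1; the
#' information measures with zero marginal entropy are 0; the maximal
#' correlation coefficient of a single-level matrix is 1. Natural logarithms
#' throughout; inertia duplicates contrast by definition.
#'
#' @param img Numeric matrix (or pre-quantized integer matrix).
#' @param levels Number of gray levels (default 32).
#' @param quantized Set `TRUE` when `img` already holds levels in `1..levels`.
#' @return Named numeric vector of length 18 (see [glcm_stat_names()]).
#' @export
glcm_features <- function(img, levels = 32L, quantized = FALSE) {
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop("image smaller than the minimum 2x2 texture window")
  q <- if (quantized) img else quantize_image(img, levels)
  storage.mode(q) <- "integer"
  stats::setNames(glcm_features_cpp(q, as.integer(levels)), glcm_stat_names())
}

#' Greenest/wettest-pixel temporal composites
#'
#' On the original valid observations, finds the observation with the highest
#' NDVI (greenest) and the one with the highest LSWI (wettest) inside the
#' growing season, and returns the 10 proxies evaluated at each: 20 features.
#' Ties are broken by the earliest day-of-year.
#'
#' @param series An `obs_series`.
#' @param rep_literal Passed to [proxy_matrix()].
#' @return Named numeric vector of length 20 (`greenest_*`, `wettest_*`).
#' @export
temporal_composites <- function(series, rep_literal = FALSE) {
  stopifnot(inherits(series, "obs_series"))
  w <- stage_windows()$season
  pm <- proxy_matrix(series$reflectance, rep_literal = rep_literal)
  ok <- series$valid & series$doys >= w[1] & series$doys <= w[2]
  .composites_from_pm(pm, ok)
}

# Shared core of temporal_composites for precomputed proxy matrices.
.composites_from_pm <- function(pm, ok) {
  pick <- function(v) {
    cand <- which(ok & is.finite(v))
    if (length(cand) == 0) stop("no valid observation in the growing season")
    cand[which.max(v[cand])] # which.max takes the first (earliest) maximum
  }
  gi <- pick(pm[, "ndvi"])
  wi <- pick(pm[, "lswi"])
  out <- c(pm[gi, ], pm[wi, ])
  names(out) <- c(paste0("greenest_", proxy_names()), paste0("wettest_", proxy_names()))
  out
}

#' Harmonic regression on valid observations
#'
#' Ordinary least squares of the 5-term harmonic design
#' `VI_t = c + a1 cos(3 pi t) + b1 sin(3 pi t) + a2 cos(6 pi t) + b2 sin(6 pi t)`
#' with `t = (doy - 1)/365` (0 on January 1, 1 on December 31), fit to the
#' original valid observations.
#'
#' @param doys Integer days-of-year.
#' @param values Proxy values at those days.
#' @param valid Logical validity flags.
#' @return Named numeric vector `c, a1, b1, a2, b2` (class `harmonic_fit`).
#' @export
fit_harmonics <- function(doys, values, valid = rep(TRUE, length(doys))) {
  ok <- valid & is.finite(values)
  if (sum(ok) < 5L) stop("harmonic regression needs >= 5 valid observations")
  t <- (doys[ok] - 1) / 365
  X <- cbind(1, cos(3 * pi * t), sin(3 * pi * t), cos(6 * pi * t), sin(6 * pi * t))
  qr_ <- qr(X)
  if (qr_$rank < 5L) stop("singular harmonic design")
  cf <- qr.coef(qr_, values[ok])
  structure(stats::setNames(as.numeric(cf), c("c", "a1", "b1", "a2", "b2")),
            class = "harmonic_fit")
}

# Shared evaluation of the harmonic basis (used by tests and the generator).
harmonic_eval <- function(coef, doys) {
  t <- (doys - 1) / 365
  coef[["c"]] + coef[["a1"]] * cos(3 * pi * t) + coef[["b1"]] * sin(3 * pi * t) +
    coef[["a2"]] * cos(6 * pi * t) + coef[["b2"]] * sin(6 * pi * t)
}

# Precomputed Savitzky-Golay smoothing matrix with asymmetric edge rows.
.sg_matrix <- function(n, window = 7L, order = 3L) {
  h <- (window - 1L) / 2L
  S <- matrix(0, n, n)
  centre <- sg_coefficients(window, order, 0L)
  for (i in seq_len(n)) {
    if (i <= h) S[i, 1:window] <- sg_coefficients(window, order, i - 1L - h)
    else if (i > n - h) S[i, (n - window + 1L):n] <- sg_coefficients(window, order, i - (n - h))
    else S[i, (i - h):(i + h)] <- centre
  }
  S
}

# Fast path of regularize_series for bank building: returns 10 x 22 matrix,
# NULL if the pixel is unclassifiable (some proxy entirely gap). `pm` is the
# precomputed proxy matrix of the series.
.regularize_fast <- function(series, S, pm) {
  grid <- interval_starts()
  idx <- findInterval(series$doys, c(grid, 310L))
  keep <- series$valid & idx >= 1L & idx <= 22L
  if (!any(keep)) return(NULL)
  groups <- split.default(which(keep), idx[keep])
  gids <- as.integer(names(groups))
  fmed <- function(v) { # median without dispatch overhead
    n <- length(v)
    if (n == 0L) return(NA_real_)
    half <- (n + 1L) %/% 2L
    s <- sort.int(v, partial = c(half, half + 1L - n %% 2L))
    if (n %% 2L == 1L) s[half] else (s[half] + s[half + 1L]) / 2
  }
  med <- matrix(NA_real_, 22L, 10L)
  for (gi in seq_along(groups)) {
    sub <- pm[groups[[gi]], , drop = FALSE]
    for (p in seq_len(10L)) {
      v <- sub[, p]
      med[gids[gi], p] <- fmed(v[is.finite(v)])
    }
  }
  filled <- med
  for (p in seq_len(10L)) {
    obs <- which(!is.na(med[, p]))
    if (length(obs) == 0L) return(NULL)
    if (length(obs) < 22L)
      filled[, p] <- stats::approx(grid[obs], med[obs, p], xout = grid,
                                   method = "linear", rule = 2)$y
  }
  t(S %*% filled) # 10 x 22
}

#' Build the crop feature bank (255 candidates)
#'
#' For each series: the 220 ten-day time-series features (10 proxies x 22
#' intervals, from the composited/gap-filled/smoothed regular series), the 20
#' greenest/wettest-composite features and the 15 harmonic coefficients
#' (NDVI, EVI, LSWI x 5), both computed on the original valid observations.
#' Series with an unclassifiable proxy (no valid observations) or fewer than
#' 5 valid observations are dropped with a logged count.
#'
#' @param series_list List of `obs_series`.
#' @param window,order Savitzky-Golay configuration.
#' @param rep_literal Passed to the index computations.
#' @return A `feature_bank`: list with `features` (n x 255 matrix), `label`,
#'   `class_label`, `subtype`, `zone` (vectors over kept series), `kept`
#'   (indices into `series_list`), `dropped` (count).
#' @export
build_crop_bank <- function(series_list, window = 7L, order = 3L,
                            rep_literal = FALSE) {
  S <- .sg_matrix(22L, window, order)
  ts_names <- as.vector(outer(proxy_names(), interval_starts(),
                              function(p, d) paste0("ts_", p, "_", d)))
  rows <- vector("list", length(series_list))
  kept <- logical(length(series_list))
  for (k in seq_along(series_list)) {
    s <- series_list[[k]]
    row <- tryCatch({
      pm <- proxy_matrix(s$reflectance, rep_literal = rep_literal)
      reg <- .regularize_fast(s, S, pm)
      if (is.null(reg)) stop("unclassifiable")
      ts <- as.vector(reg) # proxy-major within interval: matches ts_names
      w <- stage_windows()$season
      ok <- s$valid & s$doys >= w[1] & s$doys <= w[2]
      comp <- .composites_from_pm(pm, ok)
      harm <- unlist(lapply(c("ndvi", "evi", "lswi"), function(p) {
        cf <- fit_harmonics(s$doys, pm[, p], s$valid)
        stats::setNames(as.numeric(cf), paste0("harm_", p, "_", names(cf)))
      }))
      c(stats::setNames(ts, ts_names), comp, harm)
    }, error = function(e) NULL)
    if (!is.null(row) && all(is.finite(row))) {
      rows[[k]] <- row
      kept[k] <- TRUE
    }
  }
  dropped <- sum(!kept)
  if (dropped > 0)
    message("build_crop_bank: dropped ", dropped, " unclassifiable series")
  if (!any(kept)) stop("no classifiable series")
  X <- do.call(rbind, rows[kept])
  structure(list(
    features = X,
    label = vapply(series_list[kept], `[[`, integer(1), "label"),
    class_label = vapply(series_list[kept], `[[`, character(1), "class_label"),
    subtype = vapply(series_list[kept], `[[`, character(1), "subtype"),
    zone = vapply(series_list[kept], `[[`, character(1), "zone"),
    kept = which(kept), dropped = dropped, mode = "crop"),
    class = "feature_bank")
}

#' Per-stage median NDVI images of a scene
#'
#' Median of the valid per-observation NDVI values inside each crop stage
#' window, per pixel; the input images of the texture features.
#'
#' @param scene A `scene_raster`.
#' @return Named list of three matrices (seeding, growth, harvest).
#' @export
stage_ndvi_images <- function(scene) {
  stopifnot(inherits(scene, "scene_raster"))
  stages <- c("seeding", "growth", "harvest")
  dims <- dim(scene$truth)
  out <- lapply(stats::setNames(nm = stages), function(st) {
    w <- stage_windows()[[st]]
    vals <- vapply(scene$series, function(s) {
      ndvi <- spectral_index(s$reflectance, "ndvi")
      ok <- s$valid & s$doys >= w[1] & s$doys <= w[2] & is.finite(ndvi)
      if (!any(ok)) NA_real_ else stats::median(ndvi[ok])
    }, numeric(1))
    matrix(vals, dims[1], dims[2])
  })
  out
}

#' Build the cropland feature bank (184 candidates) for scene pixels
#'
#' Per pixel: 30 seasonal stage-median features, 100 annual growing-season
#' features (both on the smoothed regular series) and 54 texture features
#' (18 co-occurrence statistics on a `win x win` window of each stage-median
#' NDVI image, quantized once per image). Pixels whose series are
#' unclassifiable are dropped with a logged count.
#'
#' @param scene A `scene_raster`.
#' @param pixels Indices (column-major) of the pixels to featurize; default
#'   all.
#' @param win Texture window side in pixels (odd; default 9).
#' @param levels Gray levels for quantization (default 32).
#' @param window,order Savitzky-Golay configuration.
#' @param rep_literal Passed to the index computations.
#' @return A `feature_bank` with an n x 184 `features` matrix; `label` holds
#'   the truth codes, `cropland` a logical truth for the binary stage
#'   (grass-like "other" pixels are the non-cropland).
#' @export
build_cropland_bank <- function(scene, pixels = NULL, win = 9L, levels = 32L,
                                window = 7L, order = 3L, rep_literal = FALSE) {
  stopifnot(inherits(scene, "scene_raster"))
  if (is.null(pixels)) pixels <- seq_along(scene$series)
  S <- .sg_matrix(22L, window, order)
  imgs <- stage_ndvi_images(scene)
  qimgs <- lapply(imgs, quantize_image, levels = levels)
  nr <- nrow(scene$truth); nc <- ncol(scene$truth)
  hw <- (win - 1L) %/% 2L
  rows <- vector("list", length(pixels))
  kept <- logical(length(pixels))
  for (k in seq_along(pixels)) {
    s <- scene$series[[pixels[k]]]
    row <- tryCatch({
      pm <- proxy_matrix(s$reflectance, rep_literal = rep_literal)
      reg <- .regularize_fast(s, S, pm)
      if (is.null(reg)) stop("unclassifiable")
      rownames(reg) <- proxy_names()
      pr <- (pixels[k] - 1L) %% nr + 1L
      pc <- (pixels[k] - 1L) %/% nr + 1L
      rr <- max(1L, pr - hw):min(nr, pr + hw)
      cc <- max(1L, pc - hw):min(nc, pc + hw)
      tex <- unlist(lapply(names(qimgs), function(st) {
        v <- glcm_features(qimgs[[st]][rr, cc, drop = FALSE], levels, quantized = TRUE)
        stats::setNames(v, paste0("tex_", st, "_", names(v)))
      }))
      c(seasonal_metrics(reg), annual_metrics(reg), tex)
    }, error = function(e) NULL)
    if (!is.null(row) && all(is.finite(row))) {
      rows[[k]] <- row
      kept[k] <- TRUE
    }
  }
  dropped <- sum(!kept)
  if (dropped > 0)
    message("build_cropland_bank: dropped ", dropped, " unclassifiable pixels")
  if (!any(kept)) stop("no classifiable pixels")
  X <- do.call(rbind, rows[kept])
  px <- pixels[kept]
  subtype <- vapply(scene$series[px], `[[`, character(1), "subtype")
  structure(list(
    features = X,
    label = scene$truth[px],
    cropland = !(scene$truth[px] == 3L & subtype == "grass"),
    subtype = subtype,
    zone = scene$zone,
    kept = px, dropped = dropped, mode = "cropland"),
    class = "feature_bank")
}

#' Manifest of a feature bank
#'
#' One row per feature with its group and the (proxy, period, metric)
#' decomposition encoded in the name.
#'
#' @param mode `"cropland"` or `"crop"`.
#' @return data.frame with columns `name`, `group`.
#' @export
bank_manifest <- function(mode = c("crop", "cropland")) {
  mode <- match.arg(mode)
  if (mode == "crop") {
    data.frame(
      name = c(as.vector(outer(proxy_names(), interval_starts(),
                               function(p, d) paste0("ts_", p, "_", d))),
               paste0("greenest_", proxy_names()), paste0("wettest_", proxy_names()),
               unlist(lapply(c("ndvi", "evi", "lswi"), function(p)
                 paste0("harm_", p, "_", c("c", "a1", "b1", "a2", "b2"))))),
      group = rep(c("timeseries", "composite", "harmonic"), c(220L, 20L, 15L)))
  } else {
    stages <- c("seeding", "growth", "harvest")
    seas <- unlist(lapply(stages, function(s) paste0(proxy_names(), "_med_", s)))
    ann <- as.vector(t(outer(proxy_names(), c("min", "max", "mean", "std", "amp",
                                              "p05", "p25", "p50", "p75", "p95"),
                             paste, sep = "_")))
    tex <- unlist(lapply(stages, function(s) paste0("tex_", s, "_", glcm_stat_names())))
    data.frame(name = c(seas, ann, tex),
               group = rep(c("seasonal", "annual", "texture"), c(30L, 100L, 54L)))
  }
}
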