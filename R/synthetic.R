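#' Crop class codes
#'
#' Fixed coding of the map product: 0 rice, 1 maize, 2 soybean, 3 other
#' (other crops and non-cropland merged).
#'
#' @return Named integer vector.
#' @export
crop_codes <- function() c(rice = 0L, maize = 1L, soybean = 2L, other = 3L)

#' Label for a class code
#' @param code Integer vector of codes in 0..3.
#' @return Character vector of labels.
#' @export
crop_label <- function(code) {
  codes <- crop_codes()
  if (!all(code %in% codes)) stop("class codes must be in {0,1,2,3}")
  names(codes)[match(code, codes)]
}

# Seasonal curve: product of a green-up and a senescence logistic, in [0, 1].
.double_logistic <- function(doy, sos, eos, rate_up = 8, rate_down = 10) {
  stats::plogis((doy - sos) / rate_up) * stats::plogis((eos - doy) / rate_down)
}

# Bare-soil baseline and water end-member (TOA-like reflectance magnitudes;
# the source product never publishes per-crop band magnitudes, so these are
# free parameters chosen to look like Northeast-China croplands).
.soil_spectrum <- function() {
  c(blue = 0.10, red = 0.15, re1 = 0.17, re2 = 0.19, re3 = 0.21,
    nir = 0.23, swir1 = 0.28, swir2 = 0.25)
}
.water_spectrum <- function() {
  c(blue = 0.08, red = 0.07, re1 = 0.08, re2 = 0.10, re3 = 0.12,
    nir = 0.14, swir1 = 0.05, swir2 = 0.04)
}
.cloud_spectrum <- function() {
  c(blue = 0.65, red = 0.62, re1 = 0.62, re2 = 0.63, re3 = 0.64,
    nir = 0.65, swir1 = 0.45, swir2 = 0.35)
}

#' Phenology parameters for one synthetic class
#'
#' Parameter object consumed by [simulate_series()]. Band trajectories are
#' double-logistic blends from a bare-soil baseline towards a class-specific
#' peak-canopy spectrum; rice additionally blends towards a water end-member
#' during its flooding/transplanting window (default day-of-year 120-150),
#' which depresses SWIR1/SWIR2 and elevates LSWI. The maize canopy spectrum
#' has a lower RE2 relative to NIR and steeper red edge than soybean, so
#' RENDVI and REP of maize exceed soybean at peak season (day-of-year
#' 200-240).
#'
#' @param class_label One of `"rice"`, `"maize"`, `"soybean"`, `"other"`.
#' @param noise_sd Gaussian reflectance noise s.d. (default 0.02).
#' @param cloud_prob Per-observation contamination probability (default 0.3).
#' @param revisit_days Acquisition interval in days (default 5, the two-
#'   satellite constellation revisit).
#' @param flooding_window Length-2 day-of-year window or `NULL`; only rice has
#'   one by default.
#' @param sos,eos Start/end of season (green-up and senescence midpoints).
#' @param peak Named length-8 peak-canopy spectrum; defaults per class.
#' @return A `phenology_params` list.
#' @export
phenology_params <- function(class_label,
                             noise_sd = 0.02,
                             cloud_prob = 0.3,
                             revisit_days = 5L,
                             flooding_window = if (class_label == "rice") c(120, 150) else NULL,
                             sos = NULL, eos = NULL, peak = NULL) {
  class_label <- match.arg(class_label, names(crop_codes()))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cloud_prob < 0 || cloud_prob > 1) stop("cloud_prob must be in [0,1]")
  if (revisit_days < 1) stop("revisit_days must be >= 1")
  if (!is.null(flooding_window)) {
    if (length(flooding_window) != 2L || flooding_window[1] >= flooding_window[2] ||
        flooding_window[1] < 90 || flooding_window[2] > 300)
      stop("flooding_window must be an increasing pair within [90, 300]")
  }
  defaults <- list(
    rice = list(sos = 160, eos = 275,
                peak = c(blue = 0.040, red = 0.045, re1 = 0.080, re2 = 0.310,
                         re3 = 0.410, nir = 0.440, swir1 = 0.160, swir2 = 0.080)),
    maize = list(sos = 145, eos = 270,
                 peak = c(blue = 0.040, red = 0.040, re1 = 0.070, re2 = 0.300,
                          re3 = 0.430, nir = 0.460, swir1 = 0.180, swir2 = 0.090)),
    soybean = list(sos = 155, eos = 265,
                   peak = c(blue = 0.045, red = 0.050, re1 = 0.095, re2 = 0.330,
                            re3 = 0.400, nir = 0.420, swir1 = 0.200, swir2 = 0.110)),
    other = list(sos = 110, eos = 290,
                 peak = c(blue = 0.060, red = 0.080, re1 = 0.110, re2 = 0.250,
                          re3 = 0.300, nir = 0.330, swir1 = 0.230, swir2 = 0.160))
  )
  d <- defaults[[class_label]]
  if (is.null(sos)) sos <- d$sos
  if (is.null(eos)) eos <- d$eos
  if (is.null(peak)) peak <- d$peak
  if (!all(band_names() %in% names(peak)))
    stop("peak spectrum must name all 8 bands")
  if (any(peak < 0 | peak > 1)) stop("peak reflectances must lie in [0,1]")
  structure(list(class_label = class_label, code = crop_codes()[[class_label]],
                 sos = sos, eos = eos, peak = peak[band_names()],
                 flooding_window = flooding_window, noise_sd = noise_sd,
                 cloud_prob = cloud_prob, revisit_days = as.integer(revisit_days)),
            class = "phenology_params")
}

#' Default parameter set for the four classes
#'
#' The "other" class is a mixture: half grass-like (early, flat, persistent
#' greenness; stands in for non-cropland vegetation) and half vegetable-like
#' (short late cycle; stands in for minor crops such as vegetables, peanuts
#' and sunflowers that are realistically confused with soybean).
#'
#' @param noise_sd,cloud_prob,revisit_days Shared overrides.
#' @return Named list of `phenology_params`, one per class label.
#' @export
default_params <- function(noise_sd = 0.02, cloud_prob = 0.3, revisit_days = 5L) {
  lapply(stats::setNames(nm = names(crop_codes())), function(cl)
    phenology_params(cl, noise_sd = noise_sd, cloud_prob = cloud_prob,
                     revisit_days = revisit_days))
}

# Deterministic expected spectrum (no noise/cloud) of a class at given DOYs.
.expected_reflectance <- function(params, doys, subtype = "grass") {
  soil <- .soil_spectrum()
  sos <- params$sos; eos <- params$eos
  amp_scale <- 1
  if (params$class_label == "other") {
    if (subtype == "grass") { amp_scale <- 0.65 }
    else { sos <- 170; eos <- 235; amp_scale <- 0.9 }
  }
  g <- .double_logistic(doys, sos, eos) * amp_scale
  refl <- outer(g, params$peak) + outer(1 - g, soil)
  colnames(refl) <- band_names()
  if (!is.null(params$flooding_window)) {
    fl <- doys >= params$flooding_window[1] & doys <= params$flooding_window[2]
    if (any(fl)) {
      w <- 0.7 # water fraction of the flooded-pixel mixture
      refl[fl, ] <- (1 - w) * refl[fl, , drop = FALSE] +
        w * matrix(.water_spectrum(), nrow = sum(fl), ncol = 8L, byrow = TRUE)
    }
  }
  refl
}

#' Simulate labeled observation series
#'
#' Draws `n` per-pixel irregular time series of 8-band top-of-atmosphere
#' reflectance over day-of-year 90-300 at the configured revisit, with
#' additive Gaussian noise, and i.i.d. Bernoulli cloud contamination.
#' Contaminated observations are flagged invalid and their reflectance is
#' blended towards a bright cloud spectrum (upward perturbation in the
#' visible bands). Aerosol and green bands needed by the cloud screen are
#' attached as the `screen` matrix.
#'
#' @param params A `phenology_params` object.
#' @param n Number of series (>= 1).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param zone Zone identifier attached to each series.
#' @return List of `obs_series`: each has `doys`, `reflectance` (n_obs x 8),
#'   `screen` (n_obs x 2: aerosols, green), `valid`, `label` (code),
#'   `class_label`, `subtype`, `zone`.
#' @export
simulate_series <- function(params, n, seed = 1L, zone = "SJ") {
  stopifnot(inherits(params, "phenology_params"))
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  .simulate_series_impl(params, n, zone)
}

# RNG-stream version shared by simulate_series and simulate_scene.
.simulate_series_impl <- function(params, n, zone = "SJ") {
  doys <- seq.int(90L, 300L, by = params$revisit_days)
  lapply(seq_len(n), function(i) {
    subtype <- if (params$class_label == "other") {
      if (stats::runif(1) < 0.5) "grass" else "vegetable"
    } else "crop"
    refl <- .expected_reflectance(params, doys, subtype)
    if (params$noise_sd > 0)
      refl <- refl + matrix(stats::rnorm(length(refl), 0, params$noise_sd),
                            nrow = nrow(refl))
    cloudy <- stats::runif(length(doys)) < params$cloud_prob
    if (any(cloudy)) {
      cf <- stats::runif(sum(cloudy), 0.5, 0.95) # cloud cover fraction
      cl <- matrix(.cloud_spectrum(), nrow = sum(cloudy), ncol = 8L, byrow = TRUE)
      refl[cloudy, ] <- (1 - cf) * refl[cloudy, , drop = FALSE] + cf * cl
    }
    refl[] <- pmin(1, pmax(0, refl))
    # aerosol ~ slightly above blue; green between blue and red
    screen <- cbind(
      aerosols = pmin(1, pmax(0, refl[, "blue"] + 0.02)),
      green = pmin(1, pmax(0, 0.5 * (refl[, "blue"] + refl[, "red"]) + 0.01))
    )
    structure(list(doys = doys, reflectance = refl, screen = screen,
                   valid = !cloudy, label = params$code,
                   class_label = params$class_label, subtype = subtype,
                   zone = zone),
              class = "obs_series")
  })
}

#' Simulate a rasterized field scene
#'
#' Partitions an `nrow x ncol` grid (10 m pixels) into rectangular field
#' patches, assigns each patch a class drawn from `class_mix`, and simulates
#' one observation series per pixel (pixels of a patch share the class but
#' draw independent noise/clouds). Optionally carves a small patch (< 0.1 ha)
#' into the scene centre for despeckler tests.
#'
#' @param nrow,ncol Grid size (positive).
#' @param class_mix Length-4 proportions for (rice, maize, soybean, other);
#'   must sum to 1 within 1e-6.
#' @param params Named list of `phenology_params` as from [default_params()].
#' @param patch_side Length-2 range of patch side lengths in pixels.
#' @param small_patch If not `NULL`, a list `list(class =, side =)` carving a
#'   `side x side` patch of that class label at the scene centre.
#' @param seed Integer seed.
#' @param zone Zone identifier.
#' @return A `scene_raster`: list with `truth` (nrow x ncol integer codes),
#'   `series` (list of length nrow*ncol, column-major), `patch_id`
#'   (nrow x ncol), `pixel_size` (10), `zone`.
#' @export
simulate_scene <- function(nrow, ncol, class_mix = c(0.25, 0.3, 0.25, 0.2),
                           params = default_params(), patch_side = c(6L, 14L),
                           small_patch = NULL, seed = 1L, zone = "SJ") {
  if (nrow < 1 || ncol < 1) stop("scene grid must be non-empty")
  if (length(class_mix) != 4L || abs(sum(class_mix) - 1) > 1e-6)
    stop("class_mix must be 4 proportions summing to 1")
  set.seed(seed)
  cut_points <- function(total) {
    cuts <- integer(0); pos <- 0L
    while (pos < total) {
      side <- sample(seq.int(patch_side[1], patch_side[2]), 1L)
      pos <- min(pos + side, total)
      cuts <- c(cuts, pos)
    }
    cuts
  }
  row_cuts <- cut_points(nrow); col_cuts <- cut_points(ncol)
  row_start <- c(1L, utils::head(row_cuts, -1L) + 1L)
  col_start <- c(1L, utils::head(col_cuts, -1L) + 1L)
  truth <- matrix(NA_integer_, nrow, ncol)
  patch_id <- matrix(NA_integer_, nrow, ncol)
  n_patches <- length(row_cuts) * length(col_cuts)
  # patch extents (column-major over the patch grid)
  heights <- row_cuts - row_start + 1L
  widths <- col_cuts - col_start + 1L
  patch_px <- as.vector(outer(heights, widths))
  # quota allocation: visit patches in random order and assign the
  # positive-mix class with the largest remaining pixel deficit, so class
  # frequencies track `class_mix` to within about one patch
  quota <- class_mix * nrow * ncol
  assigned <- numeric(4L)
  candidates <- which(class_mix > 0)
  patch_class <- integer(n_patches)
  for (pid in sample.int(n_patches)) {
    deficit <- quota[candidates] - assigned[candidates]
    k <- candidates[which.max(deficit)]
    patch_class[pid] <- k - 1L
    assigned[k] <- assigned[k] + patch_px[pid]
  }
  pid <- 0L
  for (ci in seq_along(col_cuts)) for (ri in seq_along(row_cuts)) {
    pid <- pid + 1L
    rows <- row_start[ri]:row_cuts[ri]; cols <- col_start[ci]:col_cuts[ci]
    truth[rows, cols] <- patch_class[pid]
    patch_id[rows, cols] <- pid
  }
  if (!is.null(small_patch)) {
    side <- small_patch$side
    if (side * side >= 10L) stop("small_patch must be under 10 pixels (0.1 ha)")
    cls <- crop_codes()[[small_patch$class]]
    r0 <- max(1L, (nrow - side) %/% 2L); c0 <- max(1L, (ncol - side) %/% 2L)
    rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
    truth[rows, cols] <- cls
    patch_id[rows, cols] <- pid + 1L
  }
  labels <- names(crop_codes())[truth + 1L]
  series <- vector("list", nrow * ncol)
  for (k in seq_along(series))
    series[[k]] <- .simulate_series_impl(params[[labels[k]]], 1L, zone)[[1]]
  structure(list(truth = truth, series = series, patch_id = patch_id,
                 pixel_size = 10, zone = zone),
            class = "scene_raster")
}
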