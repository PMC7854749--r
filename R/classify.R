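#' Known agro-climate zone identifiers
#' @return Character vector of the six zone codes.
#' @export
zone_ids <- function() c("GK", "SJ", "LK", "SL", "LD", "IM")

#' Train the two-stage classifier for one zone
#'
#' Stage 1 is a binary cropland-vs-non-cropland forest on the (selected)
#' cropland features; stage 2 a 4-class crop forest (rice, maize, soybean,
#' other crops) on the (selected) crop features. Feature selection is run
#' per stage when `select = TRUE`.
#'
#' @param cropland_bank `feature_bank` (mode "cropland") with its `cropland`
#'   truth vector.
#' @param crop_bank `feature_bank` (mode "crop") of cropland training pixels.
#' @param zone Zone identifier (one of [zone_ids()]).
#' @param cfg An [rf_config()].
#' @param select Run the two-step feature selection per stage (default TRUE).
#' @param top_k,cut_height Selection configuration.
#' @return A `zone_model`.
#' @export
train_zone <- function(cropland_bank, crop_bank, zone, cfg = rf_config(),
                       select = TRUE, top_k = 50L, cut_height = 1) {
  if (!zone %in% zone_ids()) stop("unknown zone id: ", zone)
  ycl <- as.integer(cropland_bank$cropland)
  ycr <- crop_bank$label
  if (length(unique(ycl)) < 2L)
    stop("zone ", zone, ": cropland stage needs both classes")
  missing_crop <- setdiff(0:3, unique(ycr))
  if (length(missing_crop) > 0L)
    stop("zone ", zone, ": missing crop class(es) ",
         paste(crop_label(missing_crop), collapse = ", "))
  sel_cl <- sel_cr <- NULL
  Xcl <- cropland_bank$features
  Xcr <- crop_bank$features
  if (select) {
    sel_cl <- select_features(Xcl, ycl, top_k, cut_height, cfg)
    sel_cr <- select_features(Xcr, ycr, top_k, cut_height, cfg)
    Xcl <- Xcl[, sel_cl$selected, drop = FALSE]
    Xcr <- Xcr[, sel_cr$selected, drop = FALSE]
  }
  structure(list(zone = zone,
                 cropland_features = colnames(Xcl),
                 crop_features = colnames(Xcr),
                 selection = list(cropland = sel_cl, crop = sel_cr),
                 rf_cropland = rf_fit(Xcl, ycl, cfg),
                 rf_crop = rf_fit(Xcr, ycr, cfg),
                 cfg = cfg),
            class = "zone_model")
}

#' Hierarchical prediction for one zone
#'
#' Pixels predicted non-cropland by stage 1 receive code 3 (other); pixels
#' inside the cropland mask receive the stage-2 code in {0,1,2,3}. Crop codes
#' 0-2 are therefore never emitted outside the cropland mask.
#'
#' @param model A `zone_model`.
#' @param cropland_features Matrix with (at least) the model's cropland
#'   feature columns.
#' @param crop_features Matrix with the model's crop feature columns, same
#'   rows.
#' @return Integer codes in {0,1,2,3}.
#' @export
predict_zone <- function(model, cropland_features, crop_features) {
  stopifnot(inherits(model, "zone_model"))
  if (nrow(cropland_features) != nrow(crop_features))
    stop("feature matrices disagree in length")
  is_crop <- predict(model$rf_cropland, cropland_features) == 1L
  out <- rep(3L, nrow(cropland_features))
  if (any(is_crop))
    out[is_crop] <- predict(model$rf_crop,
                            crop_features[is_crop, , drop = FALSE])
  out
}

#' Hierarchical prediction with per-zone models
#'
#' @param models Named list of `zone_model`s keyed by zone id.
#' @param cropland_features,crop_features Feature matrices, same rows.
#' @param zones Zone id per row.
#' @return Integer codes in {0,1,2,3}.
#' @export
predict_hierarchical <- function(models, cropland_features, crop_features,
                                 zones) {
  zones <- as.character(zones)
  unknown <- setdiff(unique(zones), names(models))
  if (length(unknown) > 0L)
    stop("no model for zone(s): ", paste(unknown, collapse = ", "))
  out <- integer(length(zones))
  for (z in unique(zones)) {
    i <- which(zones == z)
    out[i] <- predict_zone(models[[z]],
                           cropland_features[i, , drop = FALSE],
                           crop_features[i, , drop = FALSE])
  }
  out
}

#' Class reference spectra for SAM/SCM
#'
#' Per-class mean feature vector over the training samples.
#'
#' @param X Feature matrix.
#' @param y Class labels.
#' @return Matrix, classes x features, rownames = class.
#' @export
reference_spectra <- function(X, y) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  refs <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                   numeric(ncol(X))))
  rownames(refs) <- as.character(classes)
  if (any(!is.finite(refs))) stop("non-finite reference spectrum")
  refs
}

#' Spectral Angle Mapper classification
#'
#' Assigns each sample the class whose reference spectrum subtends the
#' smallest angle `arccos(<x, r> / (|x| |r|))`; invariant to positive scaling
#' of the sample vector.
#'
#' @param X Feature matrix (columns must match the references).
#' @param refs Reference matrix from [reference_spectra()].
#' @return Labels of the same type as the reference rownames (integer codes
#'   if they parse as integers).
#' @export
sam_classify <- function(X, refs) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(colnames(refs))) {
    if (!all(colnames(refs) %in% colnames(X)))
      stop("feature names do not match the reference spectra")
    X <- X[, colnames(refs), drop = FALSE]
  }
  nx <- sqrt(rowSums(X^2))
  nr <- sqrt(rowSums(refs^2))
  if (any(nx == 0) || any(nr == 0)) stop("zero-norm vector in SAM")
  cosang <- (X %*% t(refs)) / (nx %o% nr)
  cosang[] <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang)
  cls <- rownames(refs)[apply(ang, 1, which.min)]
  if (!anyNA(suppressWarnings(as.integer(cls)))) as.integer(cls) else cls
}

#' Spectral Correlation Mapper classification
#'
#' Assigns each sample the class maximizing the centered Pearson correlation
#' with the class reference; invariant to additive offsets and positive
#' scaling of the sample vector.
#'
#' @param X Feature matrix (>= 2 columns, nonzero variance per row).
#' @param refs Reference matrix from [reference_spectra()].
#' @return Labels as in [sam_classify()].
#' @export
scm_classify <- function(X, refs) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("SCM needs feature vectors with >= 2 components")
  if (!is.null(colnames(X)) && !is.null(colnames(refs))) {
    if (!all(colnames(refs) %in% colnames(X)))
      stop("feature names do not match the reference spectra")
    X <- X[, colnames(refs), drop = FALSE]
  }
  Xc <- X - rowMeans(X)
  Rc <- refs - rowMeans(refs)
  sx <- sqrt(rowSums(Xc^2))
  sr <- sqrt(rowSums(Rc^2))
  if (any(sx == 0)) stop("zero-variance sample vector in SCM")
  if (any(sr == 0)) stop("zero-variance reference spectrum in SCM")
  r <- (Xc %*% t(Rc)) / (sx %o% sr)
  cls <- rownames(refs)[apply(r, 1, which.max)]
  if (!anyNA(suppressWarnings(as.integer(cls)))) as.integer(cls) else cls
}
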