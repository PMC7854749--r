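#' Confusion matrix (map rows, reference columns)
#'
#' @param pred Predicted (map) labels, codes in 0..3.
#' @param ref Reference labels, same length.
#' @param classes Class codes fixing row/column order (default 0:3).
#' @param labels Class names for dimnames (default rice, maize, soybean,
#'   other).
#' @return Integer K x K matrix of counts, class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred, ref, classes = 0:3,
                             labels = names(crop_codes())) {
  if (length(pred) != length(ref)) stop("pred and ref differ in length")
  if (length(pred) == 0) stop("empty label vectors")
  if (!all(c(pred, ref) %in% classes)) stop("labels outside the class set")
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(map = labels, reference = labels))
  for (i in seq_len(K)) for (j in seq_len(K))
    cm[i, j] <- sum(pred == classes[i] & ref == classes[j])
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Round half away from zero
#'
#' Presentation rounding matching the published tables (R's `round()` rounds
#' half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Accuracy metrics of a confusion matrix
#'
#' Overall accuracy (trace/total), user's accuracy (row-wise,
#' 1 - commission), producer's accuracy (column-wise, 1 - omission) and the
#' per-class F1 (harmonic mean of UA and PA). Undefined ratios (empty row or
#' column) are `NaN` with a warning.
#'
#' @param cm A square count matrix (rows = map, columns = reference).
#' @return List with `oa` (scalar), `ua`, `pa`, `f1` (named per class).
#' @export
accuracy_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix")
  d <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  ua <- d / rs; pa <- d / cs
  if (any(rs == 0) || any(cs == 0))
    warning("empty row/column: undefined UA/PA reported as NaN")
  f1 <- 2 * ua * pa / (ua + pa)
  nm <- rownames(cm)
  list(oa = sum(d) / total,
       ua = stats::setNames(as.numeric(ua), nm),
       pa = stats::setNames(as.numeric(pa), nm),
       f1 = stats::setNames(as.numeric(f1), nm))
}

#' Published accuracy-assessment confusion matrices (2017-2019)
#'
#' The validation confusion matrices of the released 10-m Northeast-China
#' crop maps, reconstructed from the published accuracy-assessment table
#' (rows = map classes, columns = reference classes; one matrix per year).
#'
#' @return Named list of three 4x4 integer matrices (`"2017"`, `"2018"`,
#'   `"2019"`).
#' @export
published_confusion_matrices <- function() {
  path <- system.file("extdata", "published_confusion_2017_2019.csv",
                      package = "hiercrop", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- names(crop_codes())
  out <- lapply(split(df, df$year), function(d) {
    m <- as.matrix(d[match(labels, d$map_class), labels])
    dimnames(m) <- list(map = labels, reference = labels)
    storage.mode(m) <- "integer"
    class(m) <- c("confusion_matrix", class(m))
    m
  })
  out
}

#' Map-vs-statistics area comparison
#'
#' Ordinary least squares of mapped area on reference (yearbook) area per
#' crop, with the coefficient of determination.
#'
#' @param at data.frame with columns `region`, `crop`, `mapped_ha`,
#'   `reference_ha`.
#' @return data.frame per crop: `crop`, `n`, `r2`, `slope`, `intercept`.
#' @export
area_compare <- function(at) {
  need <- c("region", "crop", "mapped_ha", "reference_ha")
  if (!all(need %in% names(at))) stop("area table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(at$mapped_ha < 0 | at$reference_ha < 0)) stop("areas must be >= 0")
  res <- lapply(split(at, at$crop), function(d) {
    if (nrow(d) < 3L) stop("need >= 3 regions per crop: ", d$crop[1])
    if (stats::sd(d$reference_ha) == 0) stop("zero variance in reference areas")
    fit <- stats::lm(mapped_ha ~ reference_ha, data = d)
    tss <- sum((d$mapped_ha - mean(d$mapped_ha))^2)
    r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
    data.frame(crop = d$crop[1], n = nrow(d),
               r2 = r2,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mapped area per class of a class raster
#'
#' @param cr Integer class matrix.
#' @param pixel_size Pixel side in metres (default 10; 1 pixel = 0.01 ha).
#' @return Named numeric vector of hectares per class label.
#' @export
mapped_area_ha <- function(cr, pixel_size = 10) {
  counts <- vapply(crop_codes(), function(k) sum(cr == k, na.rm = TRUE),
                   numeric(1))
  counts * pixel_size^2 / 1e4
}
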