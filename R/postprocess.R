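#' Connected components of equal class code
#'
#' Labels maximal connected patches of identical code (8-connectivity by
#' default); `NA` (nodata) pixels get label `NA`.
#'
#' @param cr Integer class matrix (`NA` = nodata).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of patch labels starting at 1.
#' @export
label_patches <- function(cr, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(cr); nc <- ncol(cr)
  lab <- matrix(NA_integer_, nr, nc)
  nbr <- if (connectivity == 8L)
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  cur <- 0L
  for (start in seq_along(cr)) {
    if (is.na(cr[start]) || !is.na(lab[start])) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    code <- cr[start]
    while (length(queue) > 0) {
      k <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (k - 1L) %% nr + 1L
      c <- (k - 1L) %/% nr + 1L
      rr <- r + nbr[, "dr"]; cc <- c + nbr[, "dc"]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      kk <- (cc[ok] - 1L) * nr + rr[ok]
      kk <- kk[!is.na(cr[kk]) & cr[kk] == code & is.na(lab[kk])]
      if (length(kk) > 0) {
        lab[kk] <- cur
        queue <- c(queue, kk)
      }
    }
  }
  lab
}

#' Despeckle a classified raster
#'
#' Implements the small-patch rule of the map product: every pixel belonging
#' to a patch strictly smaller than `min_area_ha` (0.1 ha = 10 pixels at 10 m,
#' so patches of up to 9 pixels) is replaced by the majority code within a
#' Euclidean disc of radius `radius_m` (100 m = 10 pixels) centred on it.
#' The majority is computed on the *input* raster (order independent), over
#' in-bounds non-nodata pixels, ties broken by the smallest class code;
#' nodata never wins and is never assigned. Pixels of patches at or above the
#' threshold are returned bit-identical. A single pass is applied.
#'
#' @param cr Integer class matrix (codes 0-3; `NA` = nodata).
#' @param min_area_ha Patch-area threshold in hectares (default 0.1).
#' @param radius_m Majority-window radius in metres (default 100).
#' @param pixel_size Pixel side in metres (default 10).
#' @param connectivity Patch connectivity, 4 or 8 (default 8).
#' @return Integer class matrix of the same shape.
#' @export
despeckle <- function(cr, min_area_ha = 0.1, radius_m = 100, pixel_size = 10,
                      connectivity = 8L) {
  if (length(cr) == 0) stop("empty raster")
  if (all(is.na(cr))) stop("raster entirely nodata")
  nr <- nrow(cr); nc <- ncol(cr)
  min_pixels <- ceiling(min_area_ha * 1e4 / pixel_size^2) # < this => speckle
  lab <- label_patches(cr, connectivity)
  sizes <- tabulate(lab)
  small <- which(!is.na(lab) & sizes[lab] < min_pixels)
  if (length(small) == 0) return(cr)
  rad <- radius_m / pixel_size
  off <- expand.grid(dr = -floor(rad):floor(rad), dc = -floor(rad):floor(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  out <- cr
  for (k in small) {
    r <- (k - 1L) %% nr + 1L
    c <- (k - 1L) %/% nr + 1L
    rr <- r + off$dr; cc <- c + off$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    vals <- cr[(cc[ok] - 1L) * nr + rr[ok]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) next
    counts <- table(vals)
    win <- as.integer(names(counts)[which.max(counts)]) # ties: smallest code
    out[k] <- win
  }
  out
}

#' Count patches smaller than a threshold
#'
#' Diagnostic used to verify that a despeckling pass reduces speckle.
#'
#' @inheritParams despeckle
#' @return Integer count of patches under `min_area_ha`.
#' @export
count_small_patches <- function(cr, min_area_ha = 0.1, pixel_size = 10,
                                connectivity = 8L) {
  min_pixels <- ceiling(min_area_ha * 1e4 / pixel_size^2)
  lab <- label_patches(cr, connectivity)
  if (all(is.na(lab))) return(0L)
  sum(tabulate(lab) < min_pixels)
}
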