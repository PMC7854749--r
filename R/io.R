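#' Default run configuration
#'
#' All published pipeline constants in one auditable object: stage windows,
#' Savitzky-Golay settings (70-day / 7-point window, order 3), random-forest
#' settings (100 trees, min leaf 10, sqrt mtry, bag fraction 0.5), selection
#' settings (top 50 by MDI, cluster cut height 1), despeckler settings
#' (0.1 ha, 100 m radius) and the cloud-score threshold (0.2).
#'
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stage_windows = stage_windows(),
    sg = list(window_days = 70L, window_points = 7L, poly_order = 3L),
    rf = list(n_trees = 100L, min_leaf = 10L, variables_per_split = 0L,
              bag_fraction = 0.5), # 0 = automatic floor(sqrt(p))
    selection = list(top_k = 50L, cut_height = 1),
    despeckle = list(min_area_ha = 0.1, radius_m = 100, connectivity = 8L),
    cloud_threshold = 0.2,
    zones = zone_ids(),
    pixel_size = 10,
    nodata = 255L
  ), class = "run_config")
}

#' Save / load a run configuration (JSON)
#'
#' Round-trip safe: `load_config(save_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` the config.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$stage_windows <- lapply(cfg$stage_windows, as.integer)
  for (nm in c("window_days", "window_points", "poly_order"))
    cfg$sg[[nm]] <- as.integer(cfg$sg[[nm]])
  cfg$rf$n_trees <- as.integer(cfg$rf$n_trees)
  cfg$rf$min_leaf <- as.integer(cfg$rf$min_leaf)
  cfg$rf$variables_per_split <- as.integer(cfg$rf$variables_per_split)
  cfg$selection$top_k <- as.integer(cfg$selection$top_k)
  cfg$despeckle$connectivity <- as.integer(cfg$despeckle$connectivity)
  cfg$nodata <- as.integer(cfg$nodata)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a class raster as ESRI ASCII grid
#'
#' Plain-text raster interchange (readable by GDAL/QGIS/ArcGIS): row-major
#' from the top-left, nodata 255, default 10 m cells. `NA` cells are written
#' as the nodata value.
#'
#' @param cr Integer class matrix.
#' @param path Output path (conventionally `.asc`).
#' @param pixel_size Cell size in metres.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata Nodata code (default 255).
#' @return `write_class_raster` returns `path` invisibly; `read_class_raster`
#'   a list with `raster` (integer matrix, `NA` for nodata), `pixel_size`,
#'   `xll`, `yll`, `nodata`.
#' @export
write_class_raster <- function(cr, path, pixel_size = 10, xll = 0, yll = 0,
                               nodata = 255L) {
  vals <- cr
  vals[is.na(vals)] <- nodata
  header <- c(
    paste("ncols", ncol(cr)), paste("nrows", nrow(cr)),
    paste("xllcorner", xll), paste("yllcorner", yll),
    paste("cellsize", pixel_size), paste("NODATA_value", nodata))
  body <- apply(vals, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_class_raster
#' @export
read_class_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  nodata <- as.integer(vals[["nodata_value"]])
  body <- do.call(rbind, lapply(lines[7:(6 + nr)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])))
  body[body == nodata] <- NA_integer_
  list(raster = body, pixel_size = vals[["cellsize"]],
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]], nodata = nodata)
}

#' Write / read observation series as a CSV sample table
#'
#' Long format: one row per (series, observation) with id, zone, label,
#' subtype, doy, the 8 band columns, the 2 screening bands and the validity
#' flag.
#'
#' @param series_list List of `obs_series`.
#' @param path CSV path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   reconstructs the list of `obs_series`.
#' @export
write_series_csv <- function(series_list, path) {
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    data.frame(id = i, zone = s$zone, label = s$label, subtype = s$subtype,
               doy = s$doys, s$reflectance, s$screen,
               valid = as.integer(s$valid))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$id), function(d) {
    refl <- as.matrix(d[, band_names()])
    rownames(refl) <- NULL
    screen <- as.matrix(d[, c("aerosols", "green")])
    rownames(screen) <- NULL
    structure(list(doys = d$doy, reflectance = refl, screen = screen,
                   valid = d$valid == 1L, label = d$label[1],
                   class_label = crop_label(d$label[1]),
                   subtype = as.character(d$subtype[1]),
                   zone = as.character(d$zone[1])),
              class = "obs_series")
  })
}

#' Write a feature bank as CSV
#'
#' @param bank A `feature_bank`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_bank_csv <- function(bank, path) {
  df <- data.frame(label = bank$label, bank$features, check.names = FALSE)
  if (!is.null(bank$cropland)) df$cropland <- as.integer(bank$cropland)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a selection result as CSV
#'
#' @param sel A `crop_selection`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_selection_csv <- function(sel, path) {
  utils::write.csv(sel$table, path, row.names = FALSE)
  invisible(path)
}
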