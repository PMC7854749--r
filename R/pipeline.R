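#' Full synthetic-scene evaluation of the mapping pipeline
#'
#' Reproduces, on synthetic data, the method-comparison and hierarchical
#' mapping experiments of the workflow: (1) a labeled sample set (default
#' 2,000 series per class) is featurized with the 255-candidate crop bank;
#' over `n_seeds` random half/half train-validation splits, the random
#' forest with the optimal feature subset (RF-Opt) is compared against RF
#' with all candidates (RF-All) and against the spectral angle (SAM) and
#' spectral correlation (SCM) mappers on the same selected features;
#' (2) a two-scene experiment trains the hierarchical classifier (cropland
#' mask from a training scene's 184-feature bank, crop typing from the
#' sample set) and maps an independent test scene, despeckles the map and
#' scores it against the truth raster.
#'
#' @param seed Master seed controlling every random draw.
#' @param n_per_class Sample series per class (default 2000).
#' @param scene_side Side length of the train/test scenes in pixels
#'   (default 60).
#' @param n_seeds Number of split/training seeds for the comparison
#'   (default 5).
#' @param cfg An [rf_config()]; its seed field is overridden per split.
#' @param top_k,cut_height Feature-selection configuration.
#' @param quiet Suppress progress messages.
#' @return List with `comparison` (data.frame: seed, oa_rf_opt, oa_rf_all,
#'   oa_sam, oa_scm, n_selected), `hierarchical` (list: oa, oa_raw,
#'   confusion, n_test, mask_consistent), `n_per_class`.
#' @export
run_synthetic_evaluation <- function(seed = 1L, n_per_class = 2000L,
                                     scene_side = 60L, n_seeds = 5L,
                                     cfg = rf_config(),
                                     top_k = 50L, cut_height = 1,
                                     quiet = FALSE) {
  say <- function(...) if (!quiet) message("[evaluation] ", ...)
  params <- default_params()
  zone <- "SJ"

  say("simulating ", n_per_class, " series per class")
  series <- unlist(lapply(seq_along(params), function(i)
    simulate_series(params[[i]], n_per_class, seed = seed * 100L + i,
                    zone = zone)), recursive = FALSE)
  say("building the 255-feature crop bank")
  bank <- build_crop_bank(series)
  X <- bank$features
  y <- bank$label

  comparison <- do.call(rbind, lapply(seq_len(n_seeds), function(r) {
    seed_r <- seed * 1000L + r
    set.seed(seed_r)
    n <- nrow(X)
    tr <- sort(sample.int(n, n %/% 2L))
    va <- setdiff(seq_len(n), tr)
    cfg_r <- cfg
    cfg_r$seed <- seed_r
    sel <- select_features(X[tr, , drop = FALSE], y[tr], top_k = top_k,
                           cut_height = cut_height, cfg = cfg_r)
    Xtr_opt <- X[tr, sel$selected, drop = FALSE]
    Xva_opt <- X[va, sel$selected, drop = FALSE]
    rf_opt <- rf_fit(Xtr_opt, y[tr], cfg_r)
    rf_all <- rf_fit(X[tr, , drop = FALSE], y[tr], cfg_r)
    refs <- reference_spectra(Xtr_opt, y[tr])
    oa <- function(pred) mean(pred == y[va])
    out <- data.frame(
      seed = seed_r,
      oa_rf_opt = oa(predict(rf_opt, Xva_opt)),
      oa_rf_all = oa(predict(rf_all, X[va, , drop = FALSE])),
      oa_sam = oa(sam_classify(Xva_opt, refs)),
      oa_scm = oa(scm_classify(Xva_opt, refs)),
      n_selected = length(sel$selected))
    say(sprintf("split %d: RF-Opt %.3f RF-All %.3f SAM %.3f SCM %.3f (%d features)",
                r, out$oa_rf_opt, out$oa_rf_all, out$oa_sam, out$oa_scm,
                out$n_selected))
    out
  }))

  say("simulating ", scene_side, "x", scene_side, " train/test scenes")
  scene_tr <- simulate_scene(scene_side, scene_side, params = params,
                             seed = seed + 7L, zone = zone)
  scene_te <- simulate_scene(scene_side, scene_side, params = params,
                             seed = seed + 8L, zone = zone)
  say("building scene feature banks")
  bank_cl_tr <- build_cropland_bank(scene_tr)
  bank_cl_te <- build_cropland_bank(scene_te)
  bank_cr_te <- build_crop_bank(scene_te$series)

  cfg_h <- cfg
  cfg_h$seed <- seed
  say("training the hierarchical zone model")
  model <- train_zone(bank_cl_tr, bank, zone, cfg_h, top_k = top_k,
                      cut_height = cut_height)
  keep <- intersect(bank_cl_te$kept, bank_cr_te$kept)
  Xcl <- bank_cl_te$features[match(keep, bank_cl_te$kept), , drop = FALSE]
  Xcr <- bank_cr_te$features[match(keep, bank_cr_te$kept), , drop = FALSE]
  say("mapping and despeckling the test scene")
  codes <- predict_zone(model, Xcl, Xcr)
  stage1 <- predict(model$rf_cropland,
                    Xcl[, model$cropland_features, drop = FALSE])
  map <- matrix(NA_integer_, scene_side, scene_side)
  map[keep] <- codes
  map_ds <- despeckle(map)
  ok <- !is.na(map_ds)
  cm <- confusion_matrix(map_ds[ok], scene_te$truth[ok])
  oa_raw <- mean(map[ok] == scene_te$truth[ok])
  hier <- list(
    oa = accuracy_metrics(cm)$oa,
    oa_raw = oa_raw,
    confusion = cm,
    n_test = sum(ok),
    # crop codes must never appear outside the stage-1 cropland mask
    mask_consistent = all(codes[stage1 == 0L] == 3L),
    n_selected_cropland = length(model$cropland_features),
    n_selected_crop = length(model$crop_features))
  say(sprintf("hierarchical map OA %.3f (despeckled), %.3f (raw)",
              hier$oa, hier$oa_raw))
  list(comparison = comparison, hierarchical = hier,
       n_per_class = n_per_class)
}
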