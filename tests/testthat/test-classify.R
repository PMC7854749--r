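# Small synthetic banks shared by the classification tests (module-level
# fixture kept deliberately small; the full-scale behaviour is exercised in
# the acceptance suite).
.cls_fix <- local({
  par <- default_params()
  scene <- simulate_scene(16, 16, seed = 21)
  cropland <- suppressMessages(build_cropland_bank(scene))
  series <- unlist(lapply(seq_along(par), function(i)
    simulate_series(par[[i]], 40, seed = 30 + i)), recursive = FALSE)
  crop <- suppressMessages(build_crop_bank(series))
  scene_crop <- suppressMessages(build_crop_bank(scene$series))
  idx <- match(cropland$kept, scene_crop$kept)
  list(scene = scene, cropland = cropland, crop = crop,
       scene_crop_features = scene_crop$features[idx, , drop = FALSE])
})

test_that("train_zone validates inputs and learns both stages", {
  cfg <- rf_config(n_trees = 40L, seed = 3L)
  zm <- train_zone(.cls_fix$cropland, .cls_fix$crop, "SJ", cfg)
  expect_s3_class(zm, "zone_model")
  expect_true(length(zm$crop_features) <= 50)
  expect_true(all(zm$crop_features %in% colnames(.cls_fix$crop$features)))
  # training accuracy comfortably above the 4-class chance level
  pred <- predict(zm$rf_crop,
                  .cls_fix$crop$features[, zm$crop_features, drop = FALSE])
  expect_gt(mean(pred == .cls_fix$crop$label), 0.25)
  expect_error(train_zone(.cls_fix$cropland, .cls_fix$crop, "XX", cfg),
               "unknown zone")
  # missing crop class is reported with zone and class
  sub <- .cls_fix$crop
  keep <- sub$label != 2L
  sub$features <- sub$features[keep, , drop = FALSE]
  sub$label <- sub$label[keep]
  expect_error(train_zone(.cls_fix$cropland, sub, "SJ", cfg), "soybean")
})

test_that("zone models are deterministic and refuse mismatched features", {
  cfg <- rf_config(n_trees = 30L, seed = 11L)
  zm1 <- train_zone(.cls_fix$cropland, .cls_fix$crop, "SL", cfg, select = FALSE)
  zm2 <- train_zone(.cls_fix$cropland, .cls_fix$crop, "SL", cfg, select = FALSE)
  p1 <- predict_zone(zm1, .cls_fix$cropland$features,
                     .cls_fix$scene_crop_features)
  expect_true(all(p1 %in% 0:3))
  bad <- .cls_fix$crop$features[, sample(ncol(.cls_fix$crop$features))]
  colnames(bad) <- paste0("x_", colnames(bad))
  expect_error(predict(zm1$rf_crop, bad), "feature names")
  expect_identical(predict(zm1$rf_crop, .cls_fix$crop$features),
                   predict(zm2$rf_crop, .cls_fix$crop$features))
})

test_that("hierarchical prediction masks non-cropland as code 3", {
  cfg <- rf_config(n_trees = 30L, seed = 5L)
  zm <- train_zone(.cls_fix$cropland, .cls_fix$crop, "SJ", cfg, select = FALSE)
  # force stage 1 to predict non-cropland everywhere: replace the stage-1
  # forest with one trained to map everything to class 0
  zm_all3 <- zm
  Xcl <- .cls_fix$cropland$features
  # a stage-1 forest that cannot isolate the lone positive sample (min_leaf)
  # and therefore predicts non-cropland everywhere
  fake_X <- matrix(seq_len(nrow(Xcl)), ncol = 1,
                   dimnames = list(NULL, zm$cropland_features[1]))
  fake_X <- fake_X[, rep(1, length(zm$cropland_features)), drop = FALSE]
  colnames(fake_X) <- zm$cropland_features
  zm_all3$rf_cropland <- rf_fit(fake_X,
                                c(1L, rep(0L, nrow(Xcl) - 1L)),
                                rf_config(n_trees = 10L, min_leaf = 5L, seed = 1L))
  pred <- predict_zone(zm_all3, Xcl, .cls_fix$scene_crop_features)
  expect_true(all(pred == 3L))
  # zone routing errors on unknown zones
  models <- list(SJ = zm)
  expect_error(predict_hierarchical(models, Xcl,
                                    .cls_fix$scene_crop_features,
                                    zones = rep("LD", nrow(Xcl))),
               "no model for zone")
})

test_that("SAM geometry: zero angle, scale invariance, 2-D hand case", {
  refs <- rbind(`0` = c(1, 0), `1` = c(0, 1))
  colnames(refs) <- c("u", "v")
  X <- rbind(c(1, 0), c(3, 0), c(cos(pi / 6), sin(pi / 6)))
  colnames(X) <- c("u", "v")
  got <- sam_classify(X, refs)
  expect_identical(got, c(0L, 0L, 0L)) # 30 deg from r1, 60 deg from r2
  X2 <- rbind(c(cos(pi / 3), sin(pi / 3)))
  colnames(X2) <- c("u", "v")
  expect_identical(sam_classify(X2, refs), 1L)
  expect_error(sam_classify(rbind(c(0, 0)), refs), "zero-norm")
})

test_that("SCM is shift invariant and rejects anticorrelation", {
  refs <- rbind(`0` = c(1, 2, 3, 4), `1` = c(4, 1, 3, 2))
  colnames(refs) <- letters[1:4]
  x <- refs["0", ] + 10 # perfect correlation after centring
  X <- rbind(x, -refs["0", ])
  colnames(X) <- letters[1:4]
  got <- scm_classify(X, refs)
  expect_identical(got[1], 0L)
  # -r anticorrelates with class 0 (rho -1), never preferred over class 1
  expect_identical(got[2], 1L)
  expect_error(scm_classify(rbind(rep(2, 4)), refs), "zero-variance")
  # random-vector null: |rho| is small with high probability
  set.seed(12)
  p <- 100
  refs_big <- rbind(`0` = rnorm(p))
  r <- vapply(1:50, function(i) {
    x <- rnorm(p)
    stats::cor(x, refs_big[1, ])
  }, numeric(1))
  expect_lt(stats::quantile(abs(r), 0.9), 0.25)
})

test_that("reference spectra are class means", {
  X <- rbind(c(1, 2), c(3, 4), c(10, 20))
  colnames(X) <- c("u", "v")
  refs <- reference_spectra(X, c(0, 0, 1))
  expect_equal(refs["0", ], c(u = 2, v = 3))
  expect_equal(refs["1", ], c(u = 10, v = 20))
})
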