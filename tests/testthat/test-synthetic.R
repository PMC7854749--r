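test_that("fixed seed gives bit-identical simulations", {
  p <- phenology_params("maize")
  a <- simulate_series(p, 5, seed = 7)
  b <- simulate_series(p, 5, seed = 7)
  expect_identical(a, b)
  sa <- simulate_scene(15, 15, seed = 3)
  sb <- simulate_scene(15, 15, seed = 3)
  expect_identical(sa, sb)
  expect_false(identical(simulate_series(p, 5, seed = 8), a))
})

test_that("noiseless cloud-free series are deterministic with a flooding signal", {
  p <- phenology_params("rice", noise_sd = 0, cloud_prob = 0)
  ser <- simulate_series(p, 3, seed = 1)
  expect_identical(ser[[1]]$reflectance, ser[[2]]$reflectance)
  expect_identical(ser[[2]]$reflectance, ser[[3]]$reflectance)
  expect_true(all(ser[[1]]$valid))
  # within the flooding window rice LSWI exceeds the other crops' LSWI
  win <- function(s) s$doys >= 120 & s$doys <= 150
  lswi <- function(s) mean(spectral_index(s$reflectance, "lswi")[win(s)])
  soy <- simulate_series(phenology_params("soybean", noise_sd = 0,
                                          cloud_prob = 0), 1, seed = 1)[[1]]
  mz <- simulate_series(phenology_params("maize", noise_sd = 0,
                                         cloud_prob = 0), 1, seed = 1)[[1]]
  expect_gt(lswi(ser[[1]]), lswi(soy))
  expect_gt(lswi(ser[[1]]), lswi(mz))
})

test_that("cloud_prob boundaries behave", {
  all_cloud <- simulate_series(phenology_params("maize", cloud_prob = 1),
                               4, seed = 2)
  expect_true(all(vapply(all_cloud, function(s) all(!s$valid), logical(1))))
  no_cloud <- simulate_series(phenology_params("maize", cloud_prob = 0),
                              4, seed = 2)
  expect_true(all(vapply(no_cloud, function(s) all(s$valid), logical(1))))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(phenology_params("maize", noise_sd = -0.1), "noise_sd")
  expect_error(phenology_params("rice", flooding_window = c(150, 120)),
               "flooding_window")
  expect_error(phenology_params("rice", flooding_window = c(80, 120)),
               "flooding_window")
  expect_error(phenology_params("maize", cloud_prob = 1.5), "cloud_prob")
  expect_error(simulate_series(phenology_params("rice"), 0), "n must be")
  expect_error(phenology_params("wheat"))
})

test_that("class separability contract holds over 100 series per class", {
  n <- 100
  par <- default_params()
  sets <- lapply(par[c("rice", "maize", "soybean")], simulate_series,
                 n = n, seed = 1)
  win_mean <- function(s, proxy, lo, hi) {
    v <- spectral_index(s$reflectance, proxy)
    ok <- s$valid & s$doys >= lo & s$doys <= hi & is.finite(v)
    mean(v[ok])
  }
  cls_mean <- function(cl, proxy, lo, hi)
    mean(vapply(sets[[cl]], win_mean, numeric(1), proxy, lo, hi), na.rm = TRUE)
  # flooding window: rice SWIR depressed, LSWI elevated
  for (pr in c("swir1", "swir2")) {
    expect_lt(cls_mean("rice", pr, 120, 150), cls_mean("maize", pr, 120, 150))
    expect_lt(cls_mean("rice", pr, 120, 150), cls_mean("soybean", pr, 120, 150))
  }
  expect_gt(cls_mean("rice", "lswi", 120, 150), cls_mean("maize", "lswi", 120, 150))
  expect_gt(cls_mean("rice", "lswi", 120, 150), cls_mean("soybean", "lswi", 120, 150))
  # peak season: maize red-edge above soybean
  expect_gt(cls_mean("maize", "rendvi", 200, 240), cls_mean("soybean", "rendvi", 200, 240))
  expect_gt(cls_mean("maize", "rep", 200, 240), cls_mean("soybean", "rep", 200, 240))
  # all reflectances stay in [0, 1]
  for (st in sets)
    expect_true(all(vapply(st, function(s)
      all(s$reflectance >= 0 & s$reflectance <= 1), logical(1))))
})

test_that("scene construction respects mix, patches and small-patch requests", {
  mix <- c(0.3, 0.4, 0.3, 0)
  sc <- simulate_scene(100, 100, class_mix = mix, seed = 5)
  freq <- tabulate(sc$truth + 1L, 4L) / length(sc$truth)
  expect_true(all(abs(freq - mix) <= 0.05))
  expect_true(all(sc$truth %in% 0:3))
  expect_identical(dim(sc$truth), dim(sc$patch_id))
  # single-class scene
  sc1 <- simulate_scene(12, 12, class_mix = c(0, 1, 0, 0), seed = 2)
  expect_true(all(sc1$truth == 1L))
  # 9-pixel carved patch: 900 m^2 < 0.1 ha
  scs <- simulate_scene(30, 30, small_patch = list(class = "soybean", side = 3),
                        seed = 4)
  area_m2 <- 9 * scs$pixel_size^2
  expect_lt(area_m2, 1000)
  expect_true(any(scs$truth == 2L))
  expect_error(simulate_scene(0, 10), "non-empty")
  expect_error(simulate_scene(10, 10, class_mix = c(1, 1, 0, 0)), "summing")
})
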