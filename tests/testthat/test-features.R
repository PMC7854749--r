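fake_reg <- function(fill) {
  m <- matrix(fill, 10L, 22L, byrow = FALSE,
              dimnames = list(proxy_names(), interval_starts()))
  m
}

test_that("seasonal metrics take stage medians on the regular grid", {
  # constant series: every feature equals the constant
  sm <- seasonal_metrics(fake_reg(0.42))
  expect_length(sm, 30L)
  expect_true(all(sm == 0.42))
  # step at DOY 170: seeding 0, growth/harvest 1
  step <- fake_reg(0)
  step[, interval_starts() >= 170] <- 1
  sm2 <- seasonal_metrics(step)
  expect_true(all(sm2[grepl("_seeding$", names(sm2))] == 0))
  expect_true(all(sm2[grepl("_growth$", names(sm2))] == 1))
  expect_true(all(sm2[grepl("_harvest$", names(sm2))] == 1))
  # monotone series: growth median exceeds seeding median
  lin <- fake_reg(0)
  lin[] <- matrix(seq(0, 1, length.out = 22L), 10L, 22L, byrow = TRUE)
  sm3 <- seasonal_metrics(lin)
  expect_gt(sm3[["ndvi_med_growth"]], sm3[["ndvi_med_seeding"]])
})

test_that("annual metrics compute the 10 statistics per proxy", {
  am <- annual_metrics(fake_reg(0.1))
  expect_length(am, 100L)
  expect_true(all(am[grepl("_(min|max|mean|p05|p25|p50|p75|p95)$", names(am))] == 0.1))
  expect_true(all(am[grepl("_(std|amp)$", names(am))] == 0))
  # 1..22: amplitude 21, median 11.5
  seq_reg <- fake_reg(0)
  seq_reg[] <- matrix(1:22, 10L, 22L, byrow = TRUE)
  am2 <- annual_metrics(seq_reg)
  expect_equal(am2[["lswi_amp"]], 21)
  expect_equal(am2[["lswi_p50"]], 11.5)
  # percentile monotonicity on random series
  set.seed(3)
  rnd <- fake_reg(0)
  rnd[] <- matrix(rnorm(220), 10L, 22L)
  am3 <- annual_metrics(rnd)
  for (p in proxy_names()) {
    q <- am3[paste0(p, "_", c("p05", "p25", "p50", "p75", "p95"))]
    expect_true(all(diff(q) >= 0))
  }
})

test_that("GLCM features obey closed-form degenerate cases", {
  const <- glcm_features(matrix(0.5, 6, 6))
  expect_equal(const[["contrast"]], 0)
  expect_equal(const[["asm"]], 1)
  expect_equal(const[["entropy"]], 0)
  expect_equal(const[["mcc"]], 1)
  # checkerboard of extreme levels: horizontal/vertical offsets see only
  # (G-1)-jumps, diagonal offsets only equal pairs -> mean contrast (G-1)^2/2
  G <- 32L
  cb <- matrix(rep_len(c(0, 1), 25), 5, 5)
  tex <- glcm_features(cb, levels = G)
  expect_equal(tex[["contrast"]], (G - 1)^2 / 2)
  expect_error(glcm_features(matrix(1, 1, 1)), "smaller")
})

test_that("GLCM implementation matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:6) {
    img <- matrix(runif(64), 8, 8)
    got <- glcm_features(img)
    want <- glcm_oracle(img)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # structured image (gradient + noise) as a harder case
  img <- outer(1:10, 1:10, `+`) / 20 + matrix(runif(100, 0, 0.1), 10, 10)
  expect_equal(glcm_features(img), glcm_oracle(img), tolerance = 1e-10)
})

test_that("temporal composites pick the greenest/wettest observations", {
  doys <- seq.int(100L, 280L, 20L)
  refl <- flat_bands(length(doys), 0.2)
  refl[, "nir"] <- seq(0.2, 0.5, length.out = length(doys))
  refl[, "red"] <- 0.1
  refl[, "re1"] <- 0.12
  refl[, "re3"] <- 0.3
  refl[5, "nir"] <- 0.9 # NDVI peak at doys[5] = 180
  refl[, "swir1"] <- 0.15
  refl[7, "swir1"] <- 0.01 # LSWI peak at doys[7]
  s <- make_series(doys, refl)
  tc <- temporal_composites(s)
  expect_length(tc, 20L)
  pm <- proxy_matrix(refl)
  expect_equal(tc[["greenest_rep"]], unname(pm[5, "rep"]))
  expect_equal(tc[["wettest_swir1"]], 0.01)
  # single valid observation: both composites equal that observation
  one <- make_series(150L, flat_bands(1, 0.3))
  tc1 <- temporal_composites(one)
  expect_equal(unname(tc1[paste0("greenest_", proxy_names())]),
               unname(tc1[paste0("wettest_", proxy_names())]))
  # NDVI tie: earliest DOY wins
  refl2 <- flat_bands(3, 0.2)
  refl2[, "nir"] <- c(0.6, 0.6, 0.4)
  refl2[, "swir2"] <- c(0.11, 0.22, 0.33)
  tie <- make_series(c(120L, 180L, 240L), refl2)
  expect_equal(temporal_composites(tie)[["greenest_swir2"]], 0.11)
  # no valid observations: error
  bad <- make_series(150L, flat_bands(1, 0.3), valid = FALSE)
  expect_error(temporal_composites(bad), "no valid observation")
})

test_that("harmonic regression is exactly identifiable from its own model", {
  coef <- c(c = 0.5, a1 = 0.2, b1 = -0.1, a2 = 0.05, b2 = 0)
  doys <- seq.int(95L, 295L, 10L)
  vals <- hiercrop:::harmonic_eval(as.list(coef), doys)
  fit <- fit_harmonics(doys, vals)
  expect_lt(max(abs(unclass(fit) - coef)), 1e-10)
  # constant series: c = v, rest 0
  fitc <- fit_harmonics(doys, rep(0.3, length(doys)))
  expect_equal(unclass(fitc), c(c = 0.3, a1 = 0, b1 = 0, a2 = 0, b2 = 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_harmonics(c(100L, 120L, 140L, 160L), rep(1, 4)), ">= 5")
})

test_that("harmonic coefficient error shrinks with sample size", {
  coef <- list(c = 0.5, a1 = 0.2, b1 = -0.1, a2 = 0.05, b2 = 0.02)
  rmse_at <- function(n, seed) {
    set.seed(seed)
    doys <- sort(sample.int(365L, n))
    vals <- hiercrop:::harmonic_eval(coef, doys) + rnorm(n, 0, 0.05)
    sqrt(mean((unclass(fit_harmonics(doys, vals)) - unlist(coef))^2))
  }
  small <- mean(vapply(1:20, function(s) rmse_at(20L, s), numeric(1)))
  large <- mean(vapply(1:20, function(s) rmse_at(320L, s), numeric(1)))
  # ~ 1/sqrt(n): ratio should approach 4; demand at least 2
  expect_gt(small / large, 2)
})

test_that("feature banks have the exact published sizes and named groups", {
  par <- default_params(cloud_prob = 0.2)
  series <- unlist(lapply(par, simulate_series, n = 4, seed = 11),
                   recursive = FALSE)
  crop <- build_crop_bank(series)
  expect_identical(ncol(crop$features), 255L)
  expect_identical(colnames(crop$features), bank_manifest("crop")$name)
  expect_true(all(is.finite(crop$features)))
  expect_identical(as.integer(table(bank_manifest("crop")$group)[
    c("timeseries", "composite", "harmonic")]), c(220L, 20L, 15L))

  sc <- simulate_scene(14, 14, seed = 8)
  cl <- build_cropland_bank(sc)
  expect_identical(ncol(cl$features), 184L)
  expect_identical(colnames(cl$features), bank_manifest("cropland")$name)
  expect_true(all(is.finite(cl$features)))
  expect_identical(as.integer(table(bank_manifest("cropland")$group)[
    c("seasonal", "annual", "texture")]), c(30L, 100L, 54L))
})

test_that("unclassifiable series are dropped with a message", {
  par <- default_params()
  good <- simulate_series(par$maize, 3, seed = 1)
  bad <- simulate_series(phenology_params("rice", cloud_prob = 1), 2, seed = 2)
  expect_message(bank <- build_crop_bank(c(good, bad)), "dropped 2")
  expect_identical(nrow(bank$features), 3L)
  expect_identical(bank$kept, 1:3)
})
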