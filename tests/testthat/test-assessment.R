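test_that("confusion matrix counts map rows against reference columns", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), classes = 0:1,
                         labels = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
               dimnames = list(map = c("a", "b"), reference = c("a", "b"))),
               ignore_attr = FALSE)
  p <- c(0L, 1L, 2L, 3L, 2L)
  expect_true(all(diag(confusion_matrix(p, p)) == table(factor(p, 0:3))))
  expect_error(confusion_matrix(0:1, 0:2), "length")
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 9), c(0, 1)), "outside")
})

test_that("accuracy metrics follow the standard definitions", {
  cm <- matrix(c(8, 2, 0, 10), 2, 2, byrow = TRUE,
               dimnames = list(map = c("a", "b"), reference = c("a", "b")))
  m <- accuracy_metrics(cm)
  expect_equal(m$oa, 18 / 20)
  expect_equal(m$ua[["a"]], 0.8)
  expect_equal(m$pa[["a"]], 1.0)
  expect_equal(m$f1[["a"]], 0.8889, tolerance = 1e-4)
  # identity: all perfect
  id <- confusion_matrix(c(0, 1, 2, 3), c(0, 1, 2, 3))
  mi <- accuracy_metrics(id)
  expect_equal(mi$oa, 1)
  expect_equal(unname(mi$f1), rep(1, 4))
  # permutation invariance of OA
  pm <- c(2, 4, 1, 3)
  cm4 <- unclass(confusion_matrix(sample(0:3, 50, TRUE), sample(0:3, 50, TRUE)))
  expect_equal(accuracy_metrics(cm4)$oa, accuracy_metrics(cm4[pm, pm])$oa)
  expect_error(accuracy_metrics(matrix(0, 2, 2)), "all-zero")
  expect_warning(accuracy_metrics(matrix(c(5, 0, 0, 0), 2, 2)), "undefined")
})

test_that("F1 lies between UA and PA", {
  set.seed(19)
  for (i in 1:10) {
    cm <- matrix(rpois(16, 20) + 1, 4, 4)
    m <- accuracy_metrics(cm)
    expect_true(all(m$f1 >= pmin(m$ua, m$pa) - 1e-12))
    expect_true(all(m$f1 <= pmax(m$ua, m$pa) + 1e-12))
  }
})

test_that("half-up rounding matches table presentation", {
  expect_equal(round_half_up(0.875), 0.88)
  expect_equal(round_half_up(0.865), 0.87)
  expect_equal(round_half_up(-0.875), -0.88)
  expect_equal(round_half_up(0.8649), 0.86)
})

test_that("published matrices reproduce their printed diagnostics", {
  cms <- published_confusion_matrices()
  expect_identical(names(cms), c("2017", "2018", "2019"))
  expect_true(all(vapply(cms, function(m) all(m >= 0), logical(1))))
  m19 <- accuracy_metrics(cms[["2019"]])
  expect_equal(round_half_up(m19$oa), 0.87)
  expect_equal(round_half_up(accuracy_metrics(cms[["2017"]])$ua[["rice"]]), 0.87)
})

test_that("area comparison recovers exact affine relations", {
  at <- data.frame(region = rep(letters[1:5], 2),
                   crop = rep(c("rice", "maize"), each = 5),
                   reference_ha = rep(c(100, 200, 300, 400, 500), 2))
  at$mapped_ha <- ifelse(at$crop == "rice", at$reference_ha,
                         0.9 * at$reference_ha)
  res <- area_compare(at)
  expect_equal(res$r2, c(1, 1), tolerance = 1e-12)
  expect_equal(res$slope[res$crop == "maize"], 0.9, tolerance = 1e-12)
  expect_error(area_compare(at[1:2, ]), ">= 3")
  at_const <- at
  at_const$reference_ha <- 100
  expect_error(area_compare(at_const), "zero variance")
})

test_that("R^2 degrades monotonically with noise", {
  set.seed(23)
  ref <- seq(100, 1000, length.out = 12)
  r2_at <- function(sigma) {
    mean(vapply(1:30, function(i) {
      at <- data.frame(region = as.character(seq_along(ref)), crop = "soybean",
                       reference_ha = ref,
                       mapped_ha = pmax(0, ref + rnorm(length(ref), 0, sigma)))
      area_compare(at)$r2
    }, numeric(1)))
  }
  r2s <- vapply(c(10, 100, 300), r2_at, numeric(1))
  expect_true(all(diff(r2s) < 0))
  expect_gt(r2s[1], 0.99)
})

test_that("mapped areas convert pixel counts to hectares", {
  cr <- matrix(c(0L, 0L, 1L, NA), 2, 2)
  a <- mapped_area_ha(cr)
  expect_equal(a[["rice"]], 0.02)
  expect_equal(a[["maize"]], 0.01)
  expect_equal(a[["other"]], 0)
})
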