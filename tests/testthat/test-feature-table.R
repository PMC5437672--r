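test_that("first-order statistics match hand computation and conventions", {
  s <- aggregate_stats(c(1, 2, 3, 4, 5))
  expect_equal(s[["mean"]], 3)
  expect_equal(s[["median"]], 3)
  expect_equal(s[["sd"]], sqrt(2.5))
  expect_equal(s[["skewness"]], 0)
  # constant region: sd 0 and standardized moments 0 by convention
  sc <- aggregate_stats(rep(4, 10))
  expect_equal(as.numeric(sc), c(4, 4, 0, 0, 0))
  expect_true(isTRUE(attr(sc, "degenerate")))
  # moment oracle on random values
  x <- withr::with_seed(41, rgamma(500, shape = 2))
  m <- mean(x)
  cm <- function(k) mean((x - m)^k)
  s2 <- aggregate_stats(x)
  expect_equal(s2[["skewness"]], cm(3) / cm(2)^1.5, tolerance = 1e-12)
  expect_equal(s2[["kurtosis"]], cm(4) / cm(2)^2, tolerance = 1e-12)
  # non-excess kurtosis: a large normal sample sits near 3
  xn <- withr::with_seed(42, rnorm(20000))
  expect_lt(abs(aggregate_stats(xn)[["kurtosis"]] - 3), 0.15)
  expect_error(aggregate_stats(numeric(0)), "empty")
})

test_that("the feature id enumeration reproduces the radiomic design counts", {
  ids <- feature_ids()
  expect_equal(nrow(ids), 1995)
  rad <- ids[ids$family != "PK", ]
  expect_equal(nrow(rad), 1980)
  expect_equal(sum(rad$region == "intratumoral"), 990)
  expect_equal(sum(rad$region == "peritumoral"), 990)
  expect_equal(sum(rad$region == "intratumoral" & rad$phase == "initial"),
               495)
  expect_equal(nrow(ids[ids$family == "PK", ]), 15)
  expect_equal(anyDuplicated(ids$name), 0L)
})

test_that("phase selection takes the first postcontrast and the argmax", {
  make_series <- function(means) {
    arr <- array(0, c(1, 6, 6, length(means)))
    for (p in seq_along(means)) arr[1, , , p] <- means[p]
    structure(list(data = arr, times = seq_along(means) - 1,
                   pixel_spacing_mm = c(0.8, 0.8),
                   slice_thickness_mm = 3), class = "dce_series")
  }
  mask <- array(TRUE, c(1, 6, 6))
  rising <- select_phases(make_series(c(0, 1, 2, 3, 4, 5)), mask)
  expect_equal(rising$initial, 2)
  expect_equal(rising$peak, 6)
  washout <- select_phases(make_series(c(0, 5, 3, 2, 1, 0.5)), mask)
  expect_equal(washout$initial, 2)
  expect_equal(washout$peak, 2)
  expect_error(select_phases(make_series(c(0, 1)), mask), "postcontrast")
})

test_that("normalization maps the reference range onto [-1, 1] and clips", {
  ref <- matrix(c(2, 4, 6, 1, 1, 1), ncol = 2)
  norm <- normalize_features(ref)
  expect_equal(norm[, 1], c(-1, 0, 1))
  expect_equal(norm[, 2], c(0, 0, 0))  # constant column
  # frozen reference applied to new data, with clipping
  test <- matrix(c(0, 7, 4, 1, 2, 0), ncol = 2)
  tn <- normalize_features(test, reference = ref)
  expect_equal(tn[, 1], c(-1, 1, 0))
  expect_true(all(tn >= -1 & tn <= 1))
  # idempotence: renormalizing a normalized table is the identity
  x <- withr::with_seed(43, matrix(rnorm(60), 12, 5))
  n1 <- normalize_features(x)
  n2 <- normalize_features(n1)
  expect_equal(as.vector(n2), as.vector(n1), tolerance = 1e-12)
})

test_that("patient extraction fills every feature with no missing values", {
  cfg <- tiny_phantom(seed = 17, class_label = "non_pCR")
  ph <- generate_phantom(cfg)
  f <- extract_patient_features(ph$series, ph$tumor_mask)
  expect_length(f, 1995)
  expect_false(anyNA(f))
  expect_identical(names(f), feature_ids()$name)
  f_rad <- extract_patient_features(ph$series, ph$tumor_mask, pk = FALSE)
  expect_length(f_rad, 1980)
  # one region x one phase contributes 495 statistics
  expect_equal(sum(startsWith(names(f), "intratumoral_initial")), 495)
})
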