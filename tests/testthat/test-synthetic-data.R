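test_that("phantom generation is deterministic and respects its seed", {
  cfg <- tiny_phantom(seed = 11, class_label = "non_pCR")
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$tumor_mask, b$tumor_mask)
  cfg2 <- tiny_phantom(seed = 12, class_label = "non_pCR")
  expect_false(identical(generate_phantom(cfg2)$series$data, a$series$data))
})

test_that("zero texture effect and zero noise give a constant tumor region", {
  cfg <- tiny_phantom(
    seed = 1, noise_sd = 0,
    texture_effect = list(peritumoral_speckle_amplitude = 0,
                          gradient_disorder = 0,
                          enhancement_heterogeneity = 0)
  )
  ph <- generate_phantom(cfg)
  for (p in seq_along(cfg$phase_times_min)) {
    vox <- ph$series$data[, , , p][ph$tumor_mask]
    expect_equal(max(vox) - min(vox), 0)
  }
})

test_that("peritumoral intensity SD is monotone in the speckle amplitude", {
  sds <- vapply(c(0, 0.1, 0.25, 0.5), function(amp) {
    cfg <- tiny_phantom(
      seed = 7, noise_sd = 0,
      texture_effect = list(peritumoral_speckle_amplitude = amp,
                            gradient_disorder = 0,
                            enhancement_heterogeneity = 0)
    )
    ph <- generate_phantom(cfg)
    ring <- peritumoral_ring(ph$tumor_mask,
                             cfg$pixel_spacing_mm)$peritumoral_mask
    sd(ph$series$data[, , , 6][ring])
  }, 0)
  expect_true(all(diff(sds) > 0))
  expect_equal(sds[1], 0)
})

test_that("class defaults plant stronger peritumoral disorder in non-pCR", {
  pcr <- phantom_config(class_label = "pCR")$texture_effect
  non <- phantom_config(class_label = "non_pCR")$texture_effect
  expect_gt(non$peritumoral_speckle_amplitude,
            pcr$peritumoral_speckle_amplitude)
  expect_gt(non$gradient_disorder, pcr$gradient_disorder)
})

test_that("oversized tumors and bad configurations are rejected", {
  expect_error(tiny_phantom(tumor_radius_mm = 30), "larger than grid")
  expect_error(tiny_phantom(phase_times_min = c(0, 2, 2)), "increasing")
  expect_error(tiny_phantom(phase_times_min = c(1, 2, 3)), "precontrast")
  expect_error(
    tiny_phantom(texture_effect = list(peritumoral_speckle_amplitude = 0,
                                       gradient_disorder = 2,
                                       enhancement_heterogeneity = 0)),
    "gradient_disorder"
  )
})

test_that("cohort generation honors the requested class sizes", {
  spec <- cohort_spec(24, 54, seed = 3)
  # check sizes and labels without paying for 78 phantom builds
  labels <- c(rep("pCR", spec$n_pcr), rep("non_pCR", spec$n_non_pcr))
  expect_length(labels, 78)
  small <- generate_cohort(cohort_spec(2, 3, seed = 5), tiny_phantom())
  expect_length(small, 5)
  expect_equal(vapply(small, `[[`, "", "label"),
               c("pCR", "pCR", "non_pCR", "non_pCR", "non_pCR"))
  expect_length(generate_cohort(cohort_spec(0, 0), tiny_phantom()), 0)
  expect_equal(length(generate_cohort(cohort_spec(1, 2), tiny_phantom())) +
                 length(generate_cohort(cohort_spec(5, 7), tiny_phantom())),
               15)
  # per-patient seeds differ
  two <- generate_cohort(cohort_spec(2, 0, seed = 9), tiny_phantom())
  expect_false(identical(two[[1]]$series$data, two[[2]]$series$data))
})

test_that("planted feature tables carry retrievable ground truth", {
  # null table: single-feature AUCs hover at chance
  null_tab <- generate_feature_table(200, 50, 0, 0, seed = 21)
  aucs <- apply(null_tab$values, 2, function(col) {
    binary_metrics(col, null_tab$labels)[["auc"]]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  # d = 2 informative column: empirical AUC near Phi(d / sqrt(2)) = 0.921
  tab <- generate_feature_table(200, 30, 3, 2, seed = 22)
  expected <- pnorm(2 / sqrt(2))
  for (j in tab$informative) {
    auc <- binary_metrics(tab$values[, j], tab$labels)[["auc"]]
    expect_gt(auc, 0.9)
    expect_lt(abs(auc - expected), 0.05)
  }
  # table width can match the full radiomic dimension
  wide <- generate_feature_table(10, 1980, 0, 0, seed = 23)
  expect_equal(ncol(wide$values), 1980)
  expect_error(generate_feature_table(10, 5, 6, 1), "n_informative")
})
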