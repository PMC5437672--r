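test_that("Laws maps reproduce the separable-kernel identities", {
  const <- matrix(1, 10, 10)
  lm <- laws_maps(const)
  expect_length(lm, 25)
  expect_equal(names(lm)[1], "L5L5")
  # sum of outer(L5, L5) = 16^2
  expect_true(all(abs(lm$L5L5 - 256) < 1e-12))
  for (nm in setdiff(names(lm), "L5L5")) {
    expect_true(all(abs(lm[[nm]]) < 1e-10), info = nm)
  }
  expect_error(laws_maps(matrix(1, 4, 4)), "smaller")
})

test_that("direct and FFT filtering paths agree", {
  img <- withr::with_seed(3, matrix(rnorm(400), 20, 20))
  k <- matrix(rnorm(25), 5, 5)
  expect_equal(periradiomics:::conv2_mirror_cpp(img, k),
               periradiomics:::conv2_mirror_fft(img, k),
               tolerance = 1e-10)
})

test_that("Gabor bank has 48 zero-mean filters and rotates with the image", {
  img <- withr::with_seed(4, matrix(rnorm(32 * 32, 100, 10), 32, 32))
  g <- gabor_maps(img)
  expect_length(g, 48)
  # constant image: f > 0 filters respond ~0 relative to the level
  gc <- gabor_maps(matrix(50, 24, 24))
  f_pos <- grep("^f0_", names(gc), invert = TRUE, value = TRUE)
  for (nm in f_pos) expect_lt(max(gc[[nm]]), 1e-8 * 50)
  # 90-degree rotation maps theta to theta + 90 (interior pixels)
  rot <- t(img)[, rev(seq_len(nrow(img)))]  # counter-clockwise 90
  g_rot <- gabor_maps(rot)
  inner <- 9:24
  r1 <- g[["f8_th22.5"]][inner, inner]
  # response of the rotated image, rotated back onto the original frame
  back <- g_rot[["f8_th112.5"]][, rev(seq_len(ncol(img)))]
  back <- t(back)[inner, inner]
  expect_equal(r1, back, tolerance = 1e-6)
})

test_that("Haralick maps satisfy constant and checkerboard identities", {
  h <- haralick_maps(matrix(7, 9, 9), n_gray_levels = 16)
  expect_length(h, 13)
  expect_identical(names(h), glcm_statistic_names())
  expect_true(all(h$entropy == 0))
  expect_true(all(h$energy == 1))
  # 2-level checkerboard, horizontal offsets only: every pair differs by
  # exactly one level, so inertia (contrast) is 1
  cb <- matrix((outer(1:5, 1:5, "+") %% 2), 5, 5)
  hc <- haralick_maps(cb, n_gray_levels = 2,
                      directions = c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(abs(hc$contrast - 1) < 1e-12))
  expect_error(haralick_maps(cb, n_gray_levels = 1), "n_gray_levels")
})

test_that("CoLlAGe entropy vanishes on a planar ramp and rises with disorder", {
  ramp <- matrix(rep(seq_len(14), each = 14), 14, 14)
  cm <- collage_maps(ramp)
  expect_length(cm, 13)
  expect_true(all(cm$entropy == 0))
  noisy <- withr::with_seed(5, matrix(rnorm(196), 14, 14))
  expect_gt(mean(collage_maps(noisy)$entropy), mean(cm$entropy))
  # phantom with maximal gradient disorder beats the ordered ramp
  cfg <- tiny_phantom(
    seed = 2, noise_sd = 0,
    texture_effect = list(peritumoral_speckle_amplitude = 0,
                          gradient_disorder = 1,
                          enhancement_heterogeneity = 0.5)
  )
  ph <- generate_phantom(cfg)
  sl <- ph$series$data[3, , , 6]
  expect_gt(mean(collage_maps(sl)$entropy), 0)
})

test_that("the texture bank enumerates exactly 99 uniquely named maps", {
  img <- withr::with_seed(6, matrix(rnorm(256), 16, 16))
  bank <- texture_bank(img)
  expect_length(bank$maps, 99)
  expect_equal(as.vector(table(bank$family)), c(25, 48, 13, 13))
  expect_equal(anyDuplicated(names(bank$maps)), 0L)
  tab <- texture_descriptor_table()
  expect_equal(nrow(tab), 99)
  expect_identical(paste(tab$family, tab$descriptor, sep = "_"),
                   names(bank$maps))
})

test_that("maps are translation-equivariant and intensity-shift invariant", {
  img <- withr::with_seed(7, matrix(rnorm(484, 10, 3), 22, 22))
  shift <- rbind(img[5:22, ], img[1:4, ])  # integer row shift
  inner <- 8:14
  lw1 <- laws_maps(img)$E5S5
  lw2 <- laws_maps(shift)$E5S5
  expect_equal(lw1[inner + 4, inner], lw2[inner, inner],
               tolerance = 1e-10)
  # adding a constant leaves zero-sum Laws, Gabor f>0 and CoLlAGe alone
  img2 <- img + 11.5
  expect_equal(laws_maps(img)$S5R5, laws_maps(img2)$S5R5,
               tolerance = 1e-6)
  g1 <- gabor_maps(img)[["f4_th67.5"]]
  g2 <- gabor_maps(img2)[["f4_th67.5"]]
  expect_equal(g1, g2, tolerance = 1e-6)
  expect_equal(collage_maps(img), collage_maps(img2), tolerance = 1e-6)
})

test_that("windowed co-occurrence maps equal the naive reference exactly", {
  img <- withr::with_seed(8, matrix(rnorm(64), 8, 8))
  ref <- ref_haralick_maps(img, nlev = 8)
  got <- haralick_maps(img, n_gray_levels = 8)
  for (s in seq_len(13)) {
    expect_equal(got[[s]], ref[, , s], tolerance = 1e-12,
                 info = glcm_statistic_names()[s])
  }
})
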