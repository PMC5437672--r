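post_times <- c(2, 3.5, 5, 6.5, 8)

test_that("forward Tofts curves satisfy the model's structural limits", {
  # zero transfer
  expect_equal(tofts_forward(0, 0.5, c(0, post_times)), rep(0, 6))
  # linear in ktrans
  c1 <- tofts_forward(0.2, 0.7, c(0, post_times))
  c2 <- tofts_forward(0.4, 0.7, c(0, post_times))
  expect_equal(c2, 2 * c1)
  # kep -> 0 limit: cumulative AIF integral scaled by ktrans
  aif <- aif_biexponential()
  f0 <- tofts_forward(0.2, 0, c(0, post_times))
  cum <- vapply(post_times, function(tt) {
    0.2 * integrate(aif$cp, 0, tt, rel.tol = 1e-10)$value
  }, 0)
  expect_equal(f0[-1], cum, tolerance = 1e-6)
  expect_error(tofts_forward(-0.1, 0.5, post_times), "non-negative")
  expect_error(tofts_forward(0.1, 0.5, c(3, 1)), "sorted")
})

test_that("trapezoidal forward curve matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  aif <- aif_biexponential()
  sol <- deSolve::ode(
    c(ct = 0), times = c(0, post_times),
    func = function(t, y, p) list(p[1] * aif$cp(t) - p[2] * y),
    parms = c(0.2, 0.5), rtol = 1e-10, atol = 1e-12
  )
  fw <- tofts_forward(0.2, 0.5, c(0, post_times))
  expect_equal(fw[-1], unname(sol[-1, "ct"]), tolerance = 1e-3)
  expect_lt(max(abs(fw[-1] - sol[-1, "ct"]) / sol[-1, "ct"]), 0.001)
})

test_that("noiseless forward-then-fit recovers the parameters within 1%", {
  for (kt in c(0.05, 0.2, 0.5, 1)) {
    for (ke in c(0.1, 0.5, 1, 2)) {
      if (kt / ke > 1) next  # fits are constrained to ve <= 1
      curve <- tofts_forward(kt, ke, c(0, post_times))[-1]
      fit <- fit_tofts(curve, post_times)
      expect_lt(abs(fit$ktrans - kt) / kt, 0.01)
      expect_lt(abs(fit$kep - ke) / ke, 0.01)
      expect_equal(fit$ve, fit$ktrans / fit$kep, tolerance = 1e-12)
    }
  }
})

test_that("degenerate and noisy curves are handled as specified", {
  flat <- fit_tofts(rep(0, 5), post_times)
  expect_equal(flat[c("ktrans", "kep", "ve")],
               list(ktrans = 0, kep = 0, ve = 0))
  expect_equal(flat$flag, "flat")
  expect_error(fit_tofts(c(1, NA, 2), c(1, 2, 3)), "non-finite")
  expect_error(fit_tofts(c(1, 2), c(1, 2)), "3 samples")
  # Monte-Carlo: 5% of peak noise, median relative ktrans error < 10%
  clean <- tofts_forward(0.2, 0.5, c(0, post_times))[-1]
  noise_sd <- 0.05 * max(clean)
  errs <- withr::with_seed(31, vapply(seq_len(200), function(i) {
    f <- fit_tofts(clean + rnorm(5, sd = noise_sd), post_times)
    abs(f$ktrans - 0.2) / 0.2
  }, 0))
  expect_lt(median(errs), 0.10)
})

test_that("voxel-wise PK maps recover planted kinetics on a clean phantom", {
  cfg <- tiny_phantom(
    seed = 13, noise_sd = 0,
    texture_effect = list(peritumoral_speckle_amplitude = 0,
                          gradient_disorder = 0,
                          enhancement_heterogeneity = 0)
  )
  ph <- generate_phantom(cfg)
  region <- peritumoral_ring(ph$tumor_mask, cfg$pixel_spacing_mm)
  maps <- pk_maps(ph$series, region)
  kt_tumor <- maps$ktrans[region$tumor_mask]
  expect_lt(abs(median(kt_tumor) - cfg$pk$ktrans) / cfg$pk$ktrans, 0.05)
  ke_tumor <- maps$kep[region$tumor_mask]
  expect_lt(abs(median(ke_tumor) - cfg$pk$kep) / cfg$pk$kep, 0.05)
  # ve = ktrans / kep wherever kep > 0
  sel <- maps$region_mask & maps$kep > 0
  expect_equal(maps$ve[sel], maps$ktrans[sel] / maps$kep[sel],
               tolerance = 1e-12)
  expect_true(all(maps$ve <= 1 + 1e-12))
  # zero-enhancement phantom: all maps zero
  flat <- ph
  for (p in 2:6) flat$series$data[, , , p] <- flat$series$data[, , , 1]
  m0 <- pk_maps(flat$series, region)
  expect_true(all(m0$ktrans == 0) && all(m0$kep == 0) && all(m0$ve == 0))
})
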