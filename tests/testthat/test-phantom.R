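test_that("scatterer fields have the requested density and are seed-deterministic", {
  acq <- rf_acquisition(depth_mm = 10, width_mm = 10, snr_db = Inf)
  sp <- phantom_spec(density_per_mm2 = 20, seed = 7)
  fld <- generate_scatterer_field(sp, acq, seed = 7)
  # Poisson count around density * area
  expect_gt(nrow(fld), 2000 - 4 * sqrt(2000))
  expect_lt(nrow(fld), 2000 + 4 * sqrt(2000))
  fld2 <- generate_scatterer_field(sp, acq, seed = 7)
  expect_identical(fld, fld2)
  fld3 <- generate_scatterer_field(sp, acq, seed = 8)
  expect_false(nrow(fld3) == nrow(fld) &&
                 isTRUE(all.equal(fld3$x, fld$x)))
})

test_that("margin heterogeneity of zero leaves margin amplitude variance flat", {
  acq <- rf_acquisition(depth_mm = 20, width_mm = 20, snr_db = Inf)
  roi <- roi_ellipse(c(10, 10), c(4, 4), margin_mm = 4)
  sp <- phantom_spec(density_per_mm2 = 400, margin_heterogeneity = 0,
                     seed = 3)
  msp <- phantom_spec(density_per_mm2 = 400, aac_db = 0,
                      margin_heterogeneity = 0, seed = 3)
  fld <- generate_scatterer_field(sp, acq, roi = roi, margin_spec = msp,
                                  seed = 3)
  inm <- pracma::inpolygon(fld$x, fld$y, roi$outer[, 1], roi$outer[, 2]) &
    !pracma::inpolygon(fld$x, fld$y, roi$core[, 1], roi$core[, 2])
  mg <- fld[inm, ]
  # sliding angular sectors around the ring: variance should be flat
  ang <- atan2(mg$y - 10, mg$x - 10)
  sector <- cut(ang, breaks = seq(-pi, pi, length.out = 9))
  vars <- tapply(mg$amp, sector, stats::var)
  expect_lt(stats::sd(vars) / mean(vars), 0.10)
})

test_that("rf synthesis is bit-identical under a fixed seed", {
  acq <- rf_acquisition(depth_mm = 8, width_mm = 6, snr_db = 30)
  sp <- phantom_spec(density_per_mm2 = 300, seed = 2)
  fld <- generate_scatterer_field(sp, acq, seed = 2)
  f1 <- synthesize_rf_frame(fld, sp, acq, seed = 2)
  f2 <- synthesize_rf_frame(fld, sp, acq, seed = 2)
  expect_identical(f1$samples, f2$samples)
})

test_that("doubling the linear concentration raises the power spectrum by 3 dB", {
  acq <- rf_acquisition(depth_mm = 8, width_mm = 8, snr_db = Inf)
  cfg <- spectral_config(overlap_fraction = 0, skin_thickness_cm = 0)
  mean_spec <- function(aac_db, seed0) {
    acc <- 0
    for (s in 1:25) {
      sp <- phantom_spec(aac_db = aac_db, density_per_mm2 = 400,
                         seed = seed0 + s)
      fld <- generate_scatterer_field(sp, acq, seed = seed0 + s)
      fr <- synthesize_rf_frame(fld, sp, acq, seed = seed0 + s)
      ps <- average_power_spectrum(fr$samples[50:300, ], acq$fs_mhz, cfg)
      acc <- acc + 10^(ps$power_db / 10)
    }
    10 * log10(acc / 25)
  }
  s0 <- mean_spec(0, 100)
  s3 <- mean_spec(10 * log10(2), 200)
  expect_true(all(abs((s3 - s0) - 3.01) < 0.5))
})

test_that("zero attenuation leaves deep and shallow spectra equal", {
  acq <- rf_acquisition(depth_mm = 24, width_mm = 10, snr_db = Inf)
  sp <- phantom_spec(effective_radius_um = 10, density_per_mm2 = 400,
                     attenuation_db_cm_mhz = 0, seed = 4)
  cfg <- spectral_config(overlap_fraction = 0, skin_thickness_cm = 0)
  shallow <- deep <- 0
  for (s in 1:20) {
    sp$seed <- 4 + s
    fld <- generate_scatterer_field(sp, acq, seed = 4 + s)
    fr <- synthesize_rf_frame(fld, sp, acq, seed = 4 + s)
    shallow <- shallow +
      10^(average_power_spectrum(fr$samples[100:350, ], acq$fs_mhz,
                                 cfg)$power_db / 10)
    deep <- deep +
      10^(average_power_spectrum(fr$samples[900:1150, ], acq$fs_mhz,
                                 cfg)$power_db / 10)
  }
  expect_true(all(abs(10 * log10(deep / shallow)) < 1))
})

test_that("roi geometry: margin ring is disjoint from the core and about 5 mm wide", {
  roi <- roi_ellipse(c(15, 15), c(6, 4), margin_mm = 5)
  g <- expand.grid(x = seq(5, 25, by = 0.25), y = seq(5, 25, by = 0.25))
  masks <- rasterize_roi(roi, seq(5, 25, by = 0.25), seq(5, 25, by = 0.25))
  expect_false(any(masks$core & masks$margin))
  expect_gt(sum(masks$core), 0)
  expect_gt(sum(masks$margin), 0)
  # every margin point is within 5 mm (+ raster tolerance) of the core edge
  mg_pts <- g[as.vector(t(masks$margin)), ]
  d <- sapply(seq_len(nrow(mg_pts)), function(i) {
    min(sqrt((roi$core[, 1] - mg_pts$x[i])^2 +
               (roi$core[, 2] - mg_pts$y[i])^2))
  })
  expect_lt(max(d), 5 + 0.5)
})

test_that("cohort generation reproduces the study composition", {
  acq <- rf_acquisition(depth_mm = 26, width_mm = 30, snr_db = 30)
  base <- phantom_spec(density_per_mm2 = 150, seed = 1)
  coh <- generate_cohort(2, 3, frames_per_patient = 2, acq = acq,
                         base_spec = base, seed = 1)
  expect_length(coh, 5)
  labels <- vapply(coh, function(p) p$record$label, integer(1))
  expect_equal(sum(labels == 0), 2)
  expect_equal(sum(labels == 1), 3)
  expect_true(all(vapply(coh, function(p) length(p$frames), integer(1)) == 2))
  for (p in coh) {
    expect_equal(p$record$label, as.integer(p$record$odxrs > 15))
  }
  # reproducibility
  coh2 <- generate_cohort(2, 3, frames_per_patient = 2, acq = acq,
                          base_spec = base, seed = 1)
  expect_identical(coh[[1]]$frames[[1]]$samples, coh2[[1]]$frames[[1]]$samples)
})

test_that("minimal cohort of two patients yields valid ROI sets", {
  acq <- rf_acquisition(depth_mm = 26, width_mm = 30, snr_db = 30)
  base <- phantom_spec(density_per_mm2 = 100, seed = 2)
  coh <- generate_cohort(1, 1, frames_per_patient = 1, acq = acq,
                         base_spec = base, seed = 2)
  expect_length(coh, 2)
  for (p in coh) {
    roi <- p$rois[[1]]
    masks <- rasterize_roi(roi, lateral_positions(acq), axial_positions(acq))
    expect_gt(sum(masks$core), 0)
    expect_gt(sum(masks$margin), 0)
  }
})

test_that("envelope of homogeneous speckle is Rayleigh", {
  fr <- fixture_frame80()$frame
  env <- rf_envelope(fr)
  sub <- as.vector(env[seq(100, 1150, by = 30), seq(5, 195, by = 8)])
  s2 <- mean(sub^2) / 2
  ks <- stats::ks.test(sub, function(q) 1 - exp(-q^2 / (2 * s2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("analytic reference BSC matches the form-factor formula", {
  ref <- fixture_reference()$ref
  f <- 6.5
  k <- 2 * pi * f * 1e6 / 1540
  by_hand <- 1 * f^4 * exp(-2 * 0.827 * k^2 * (25e-6)^2)
  expect_equal(ref$bsc(f), by_hand, tolerance = 1e-12)
  # reference phantom has zero attenuation -> depth-independent truth
  expect_equal(ref$spec$attenuation_db_cm_mhz, 0)
})
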