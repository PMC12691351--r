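test_that("window grid step equals window size times one minus overlap", {
  acq <- rf_acquisition(depth_mm = 30, width_mm = 30)
  roi <- roi_ellipse(c(15, 15), c(6, 6), margin_mm = 3)
  pl <- sliding_window_grid(roi, acq, spectral_config())
  expect_equal(attr(pl, "step_mm"), 2 * (1 - 0.94), tolerance = 1e-12)
  expect_equal(attr(pl, "step_mm"), 0.12, tolerance = 1e-12)
  # overlap 0 -> step equals the window size
  pl0 <- sliding_window_grid(roi, acq, spectral_config(overlap_fraction = 0))
  expect_equal(attr(pl0, "step_mm"), 2)
  expect_setequal(unique(pl$region), c("core", "margin"))
})

test_that("window-centre count matches a brute-force grid scan for a square ROI", {
  acq <- rf_acquisition(depth_mm = 30, width_mm = 30)
  # near-square ROI via a fine-vertex ellipse inscribed in a 10x10 square
  sq <- cbind(c(10, 20, 20, 10), c(10, 10, 20, 20))
  roi <- structure(list(core = sq, outer = cbind(c(9, 21, 21, 9),
                                                 c(9, 9, 21, 21)),
                        margin_mm = 1, frame_id = "sq"), class = "roi_set")
  cfg <- spectral_config()
  pl <- sliding_window_grid(roi, acq, cfg)
  # brute force: enumerate the same grid and count points in core/outer
  step <- 2 * (1 - 0.94)
  gx <- seq(1, 29, by = step)
  gy <- seq(1, max(axial_positions(acq)) - 1, by = step)
  cnt <- 0
  for (x in gx) for (y in gy) {
    if (x >= 9 && x <= 21 && y >= 9 && y <= 21) cnt <- cnt + 1
  }
  expect_equal(nrow(pl), cnt)
})

test_that("average power spectrum finds tones, obeys scaling, and is flat for noise", {
  acq <- rf_acquisition()
  cfg <- spectral_config()
  n <- 256
  t_us <- (0:(n - 1)) / acq$fs_mhz
  block <- matrix(rep(sin(2 * pi * 5 * t_us), 4), ncol = 4)
  ps <- average_power_spectrum(block, acq$fs_mhz, cfg)
  expect_equal(ps$freq[which.max(ps$power_db)], 5, tolerance = 0.08)
  ps2 <- average_power_spectrum(2 * block, acq$fs_mhz, cfg)
  expect_equal(ps2$power_db - ps$power_db, rep(20 * log10(2), length(ps$freq)),
               tolerance = 1e-9)
  set.seed(1)
  wn <- matrix(rnorm(256 * 400), 256, 400)
  psn <- average_power_spectrum(wn, acq$fs_mhz, cfg)
  expect_lt(max(abs(psn$power_db - mean(psn$power_db))), 1)
  expect_error(average_power_spectrum(matrix(0, 64, 4), acq$fs_mhz, cfg),
               "degenerate")
})

test_that("attenuation correction is exact arithmetic and invertible", {
  spec <- structure(list(freq = c(3, 5, 8), power_db = c(0, 0, 0),
                         window_center = c(0, 0), n_lines_averaged = 1),
                    class = "spectrum_estimate")
  out <- correct_attenuation(spec, list(alpha_db_cm_mhz = 1,
                                        thickness_cm = 1))
  expect_equal(out$power_db, c(6, 10, 16))
  # zero thickness -> identity
  out0 <- correct_attenuation(spec, list(alpha_db_cm_mhz = 1,
                                         thickness_cm = 0))
  expect_equal(out0$power_db, spec$power_db)
})

test_that("spectral-difference attenuation recovers a closed-form decay exactly", {
  # synthetic spectra decaying exactly as 2 alpha f d never touch the RF path
  cfg <- spectral_config()
  alpha <- 0.54
  # emulate .window_spectra output by regressing directly on constructed data
  freq <- seq(3, 8, by = 0.25)
  depths <- seq(1, 3, by = 0.2) # cm
  power <- outer(depths, freq, function(d, f) 40 - 2 * alpha * f * d)
  dbar <- depths - mean(depths)
  slopes <- as.vector(crossprod(dbar, power)) / sum(dbar^2)
  alpha_hat <- -sum(freq * slopes) / (2 * sum(freq^2))
  expect_equal(alpha_hat, alpha, tolerance = 1e-12)
})

test_that("attenuation recovery from simulated phantoms hits the planted value", {
  acq <- test_acq()
  roi <- roi_ellipse(c(12, 12), c(9, 9), margin_mm = 1.5)
  cfg <- phantom_cfg(overlap = 0.5)
  sp0 <- phantom_spec(effective_radius_um = 40, seed = 77)
  fr0 <- synthesize_rf_frame(generate_scatterer_field(sp0, acq, seed = 77),
                             sp0, acq, seed = 77)
  a0 <- estimate_attenuation_spectral_difference(fr0, roi, cfg)
  expect_lt(abs(a0$alpha_db_cm_mhz), 0.05)
  sp7 <- phantom_spec(effective_radius_um = 40,
                      attenuation_db_cm_mhz = 0.7, seed = 6)
  fr7 <- synthesize_rf_frame(generate_scatterer_field(sp7, acq, seed = 6),
                             sp7, acq, seed = 6)
  a7 <- estimate_attenuation_spectral_difference(fr7, roi, cfg)
  expect_lt(abs(a7$alpha_db_cm_mhz - 0.7), 0.15)
  expect_gt(a7$fit_r2, 0.9)
})

test_that("round trip: correcting then re-estimating attenuation nulls it", {
  acq <- test_acq()
  roi <- roi_ellipse(c(12, 12), c(9, 9), margin_mm = 1.5)
  cfg <- phantom_cfg(overlap = 0.5)
  sp <- phantom_spec(effective_radius_um = 40,
                     attenuation_db_cm_mhz = 0.5, seed = 8)
  fr <- synthesize_rf_frame(generate_scatterer_field(sp, acq, seed = 8),
                            sp, acq, seed = 8)
  est <- estimate_attenuation_spectral_difference(fr, roi, cfg)
  # compensate every axial sample in the frequency domain would be the full
  # inverse; here we verify on the window statistics: corrected window
  # spectra no longer show a depth trend
  pl <- sliding_window_grid(roi, acq, cfg)
  ws <- qusrad:::.window_spectra(fr, pl, cfg)
  corr <- ws$power_db + outer(2 * est$alpha_db_cm_mhz * pl$center_y / 10,
                              ws$freq)
  depth <- pl$center_y / 10
  dbar <- depth - mean(depth)
  slopes <- as.vector(crossprod(dbar, corr)) / sum(dbar^2)
  residual <- -sum(ws$freq * slopes) / (2 * sum(ws$freq^2))
  expect_lt(abs(residual), 0.03)
})

test_that("BSC normalization is exact for identity and fixed offsets", {
  f <- seq(3, 8, by = 0.5)
  ref <- list(freq = f, power_db = rep(12, length(f)),
              bsc = function(ff) 2 * ff^4)
  spec <- structure(list(freq = f, power_db = rep(12, length(f))),
                    class = "spectrum_estimate")
  b1 <- normalize_to_bsc(spec, ref)
  expect_equal(b1$bsc, 2 * f^4, tolerance = 1e-12)
  spec$power_db <- spec$power_db + 3
  b2 <- normalize_to_bsc(spec, ref)
  expect_equal(b2$bsc, 10^0.3 * 2 * f^4, tolerance = 1e-12)
  expect_error(normalize_to_bsc(structure(list(freq = f + 1,
                                               power_db = f * 0),
                                          class = "spectrum_estimate"), ref),
               "band mismatch")
})

test_that("linear spectral fit returns exact parameters on exact lines", {
  f <- seq(3, 8, by = 0.25)
  spec <- structure(list(freq = f, power_db = 2 * f + 3),
                    class = "spectrum_estimate")
  p <- fit_linear_spectral(spec, spectral_config())
  expect_equal(unname(p["ss"]), 2, tolerance = 1e-12)
  expect_equal(unname(p["si"]), 3, tolerance = 1e-12)
  expect_equal(unname(p["mbf"]), 2 * 5.5 + 3, tolerance = 1e-12)
  flat <- structure(list(freq = f, power_db = rep(7, length(f))),
                    class = "spectrum_estimate")
  pf <- fit_linear_spectral(flat, spectral_config())
  expect_equal(unname(pf), c(7, 0, 7), tolerance = 1e-12)
})

test_that("linear fit is unbiased under noise and MBF identity always holds", {
  f <- seq(3, 8, by = 0.25)
  cfg <- spectral_config()
  set.seed(42)
  ests <- t(replicate(200, {
    spec <- structure(list(freq = f, power_db = 1.4 * f - 2 + rnorm(length(f))),
                      class = "spectrum_estimate")
    fit_linear_spectral(spec, cfg)
  }))
  se_ss <- stats::sd(ests[, "ss"]) / sqrt(200)
  se_si <- stats::sd(ests[, "si"]) / sqrt(200)
  expect_lt(abs(mean(ests[, "ss"]) - 1.4), 2 * se_ss + 1e-9)
  expect_lt(abs(mean(ests[, "si"]) + 2), 2 * se_si + 1e-9)
  expect_equal(ests[, "mbf"], ests[, "ss"] * 5.5 + ests[, "si"],
               tolerance = 1e-12)
})

test_that("gaussian form-factor inversion recovers its own model exactly", {
  f <- seq(3, 8, by = 0.2)
  ff <- form_factor_config()
  bsc <- list(freq = f, bsc = analytic_bsc(f, aac_db = 4, a_eff_um = 25, ff))
  fit <- fit_gaussian_form_factor(bsc, ff)
  expect_equal(fit$asd_um, 50, tolerance = 1e-9)
  expect_equal(fit$aac_db, 4, tolerance = 1e-9)
  expect_false(fit$flagged)
  # pure f^4 (zero-size limit) flags and returns ASD 0
  fit0 <- fit_gaussian_form_factor(list(freq = f, bsc = 3 * f^4), ff)
  expect_equal(fit0$asd_um, 0)
  expect_true(fit0$flagged)
  expect_error(fit_gaussian_form_factor(list(freq = f, bsc = -f^4), ff),
               "non-positive")
})

test_that("noisy form-factor fit agrees with a brute-force grid-search oracle", {
  f <- seq(3, 8, by = 0.2)
  ff <- form_factor_config()
  set.seed(7)
  truth <- analytic_bsc(f, aac_db = 2, a_eff_um = 40, ff)
  noisy <- truth * 10^(rnorm(length(f), 0, 1) / 10) # +-1 dB noise
  fit <- fit_gaussian_form_factor(list(freq = f, bsc = noisy), ff)
  # oracle: exhaustive grid over (ASD, AAC) minimizing dB RMS
  asd_grid <- seq(40, 120, by = 0.5)
  best <- c(Inf, NA, NA)
  for (asd in asd_grid) {
    model_shape <- analytic_bsc(f, 0, asd / 2, ff)
    aac <- mean(10 * log10(noisy / model_shape))
    rms <- sqrt(mean((10 * log10(noisy) - 10 * log10(model_shape) - aac)^2))
    if (rms < best[1]) best <- c(rms, asd, aac)
  }
  expect_lt(abs(fit$asd_um - best[2]) / best[2], 0.10)
  expect_lt(abs(fit$aac_db - best[3]), 1)
})

test_that("parametric maps are homogeneous on homogeneous phantoms and keep the grid contract", {
  fr <- fixture_frame80()$frame
  refspec <- fixture_reference()$spec
  roi <- roi_ellipse(c(12, 12), c(8, 8), margin_mm = 2)
  maps <- build_parametric_maps(fr, roi, refspec, phantom_cfg(),
                                alpha_tumor = 0)
  core_vals <- lapply(maps$channels, function(ch) ch[maps$core_mask])
  # ASD is a scale quantity: coefficient of variation applies; the dB-valued
  # channels are log quantities, so homogeneity is a bound on the dB spread
  expect_lt(stats::sd(core_vals$ASD) / mean(core_vals$ASD), 0.15)
  for (nm in c("MBF", "SI", "AAC")) {
    expect_lt(stats::sd(core_vals[[nm]]), 2) # dB
  }
  expect_lt(stats::sd(core_vals$SS), 0.5) # dB/MHz
  # MBF identity on every window
  expect_equal(maps$channels$MBF,
               maps$channels$SS * 5.5 + maps$channels$SI, tolerance = 1e-10)
  # default config grid spacing is 0.12 mm
  acq30 <- rf_acquisition(depth_mm = 30, width_mm = 30)
  pl <- sliding_window_grid(roi_ellipse(c(15, 15), c(5, 5)), acq30,
                            spectral_config())
  expect_equal(attr(pl, "step_mm"), 0.12, tolerance = 1e-12)
})

test_that("two-region phantoms produce the planted core/margin ASD contrast", {
  acq <- test_acq()
  roi <- roi_ellipse(c(12, 12), c(5, 5), margin_mm = 4)
  core_spec <- phantom_spec(effective_radius_um = 55, seed = 31)
  margin_spec <- phantom_spec(effective_radius_um = 25, seed = 31)
  fld <- generate_scatterer_field(core_spec, acq, roi = roi,
                                  margin_spec = margin_spec, seed = 31)
  # inside the core the background spec applies; margin has smaller a_eff
  fr <- synthesize_rf_frame(fld, core_spec, acq, seed = 31)
  maps <- build_parametric_maps(fr, roi, fixture_reference()$spec,
                                phantom_cfg(), alpha_tumor = 0)
  asd_core <- stats::median(maps$channels$ASD[maps$core_mask], na.rm = TRUE)
  asd_margin <- stats::median(maps$channels$ASD[maps$margin_mask],
                              na.rm = TRUE)
  expect_gt(asd_core, asd_margin)
})
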