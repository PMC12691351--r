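# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small acquisition used by the physics tests
test_acq <- function(snr_db = 30) {
  rf_acquisition(depth_mm = 24, width_mm = 24, snr_db = snr_db)
}

# phantom-friendly spectral config: no skin layer is simulated, so no skin
# correction is applied; non-overlapping windows give independent estimates
phantom_cfg <- function(overlap = 0) {
  spectral_config(overlap_fraction = overlap, skin_thickness_cm = 0)
}

fixture_reference <- function() {
  fixture("reference", function() {
    ref <- generate_reference_frames(test_acq(), n_frames = 3, seed = 11)
    list(ref = ref, spec = reference_spectrum(ref, phantom_cfg()))
  })
}

fixture_frame80 <- function() {
  fixture("frame80", function() {
    sp <- phantom_spec(effective_radius_um = 40, aac_db = 3, seed = 5)
    fld <- generate_scatterer_field(sp, test_acq(), seed = 5)
    list(spec = sp, field = fld,
         frame = synthesize_rf_frame(fld, sp, test_acq(), seed = 5))
  })
}

# synthetic parametric maps on a regular 0.12 mm grid (fast stand-in for the
# full physics chain when only the feature layer is under test)
synthetic_maps <- function(n = 48, seed = 3, margin_shift = 0) {
  set.seed(seed)
  gx <- seq(0, by = 0.12, length.out = n)
  gy <- gx
  roi <- roi_ellipse(c(mean(gx), mean(gy)),
                     c(0.12 * n * 0.21, 0.12 * n * 0.17), margin_mm = 1.2)
  masks <- rasterize_roi(roi, gx, gy)
  ch <- lapply(stats::setNames(1:5, c("MBF", "SS", "SI", "ASD", "AAC")),
               function(i) {
    m <- matrix(stats::rnorm(n * n, mean = i * 10, sd = 3), n, n)
    m[masks$margin] <- m[masks$margin] + margin_shift
    m[!(masks$core | masks$margin)] <- NA
    m
  })
  structure(list(channels = ch, grid_x = gx, grid_y = gy,
                 grid_spacing_mm = c(0.12, 0.12), core_mask = masks$core,
                 margin_mask = masks$margin, roi = roi),
            class = "qus_maps")
}

random_level_image <- function(seed, n = 32, ng = 6, na_frac = 0.15) {
  set.seed(seed)
  lv <- matrix(sample.int(ng, n * n, replace = TRUE), n, n)
  lv[stats::runif(n * n) < na_frac] <- NA
  storage.mode(lv) <- "integer"
  lv
}
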