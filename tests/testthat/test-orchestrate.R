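test_that("experiment configuration validates keys and carries protocol defaults", {
  cfg <- experiment_config()
  expect_equal(cfg$cohort$n_low, 10L)
  expect_equal(cfg$cohort$n_high, 21L)
  expect_equal(cfg$cohort$odxrs_threshold, 15L)
  expect_equal(cfg$spectral$window_mm, 2)
  expect_equal(cfg$spectral$overlap_fraction, 0.94)
  expect_equal(cfg$radiomics$bin_width, 15)
  expect_equal(cfg$pipeline$mrmr_k, 50)
  expect_equal(cfg$pipeline$sfs_k, 4)
  expect_equal(cfg$pipeline$contamination, 0.05)
  expect_error(experiment_config(bogus_section = list(a = 1)), "bogus_section")
  # YAML round trip honors overrides
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 9L, cohort = list(n_low = 2L)), path)
  cfg2 <- experiment_config(path)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$cohort$n_low, 2L)
  expect_equal(cfg2$cohort$n_high, 21L) # untouched default survives
})

test_that("run_experiment is deterministic and its report re-derives the counts", {
  coh <- simulate_feature_cohort(5, 7, p = 30, n_informative = 2,
                                 effect_sd = 2, seed = 8)
  fm <- list(X = coh$X, y = coh$y, patient_id = coh$patient_id,
             odxrs = coh$odxrs)
  cfg <- experiment_config(seed = 8L,
                           pipeline = list(mrmr_k = 5, sfs_k = 1,
                                           contamination = 0),
                           stats = list(n_tests = 5),
                           classifiers = "lda")
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  r1 <- suppressMessages(run_experiment(cfg, out1, feature_matrix = fm))
  r2 <- suppressMessages(run_experiment(cfg, out2, feature_matrix = fm))
  expect_identical(r1$cv$lda$counts, r2$cv$lda$counts)
  expect_true(file.exists(file.path(out1, "features.csv")))
  expect_true(file.exists(file.path(out1, "metrics.csv")))
  expect_true(file.exists(file.path(out1, "univariate_screen.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$n_patients, 12L)
  # feature CSV is bit-stable across the two runs
  expect_identical(readLines(file.path(out1, "features.csv")),
                   readLines(file.path(out2, "features.csv")))
  # the rendered report reproduces the metric panel from its own counts
  rep <- write_report(r1)
  cts <- r1$cv$lda$counts
  m <- compute_metrics(cts)
  line <- grep("recall", grep("^- lda:", rep, value = TRUE), value = TRUE)[1]
  expect_match(line, sprintf("recall %.0f%%", m$recall), fixed = TRUE)
  expect_match(line, sprintf("\\(%d/%d\\)", cts$TP, cts$TP + cts$FN))
  # a result without the stats stage is marked unavailable
  rep2 <- write_report(list(metrics_table = r1$metrics_table, cv = r1$cv))
  expect_true(any(grepl("unavailable", rep2)))
})

test_that("cohort serialization writes the documented directory layout", {
  acq <- rf_acquisition(depth_mm = 26, width_mm = 30, snr_db = 30)
  base <- phantom_spec(density_per_mm2 = 60, seed = 3)
  coh <- generate_cohort(1, 1, frames_per_patient = 1, acq = acq,
                         base_spec = base, seed = 3)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(clin), 2)
  expect_equal(clin$label, as.integer(clin$odxrs > 15))
  p1 <- file.path(dir, coh[[1]]$record$patient_id)
  expect_true(file.exists(file.path(p1, "frame01.csv")))
  sidecar <- jsonlite::read_json(file.path(p1, "frame01.json"))
  expect_equal(sidecar$fs_mhz, 40)
  expect_equal(unlist(sidecar$band_mhz), c(3, 8))
  roi <- jsonlite::read_json(file.path(p1, "roi01.json"),
                             simplifyVector = TRUE)
  expect_equal(roi$margin_mm, 5)
  expect_equal(ncol(roi$core), 2)
  samp <- as.matrix(utils::read.csv(file.path(p1, "frame01.csv"),
                                    header = FALSE))
  expect_equal(dim(samp), dim(coh[[1]]$frames[[1]]$samples))
})
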