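test_that("the full configuration yields exactly 4659 uniquely named features", {
  nms <- feature_names_full()
  expect_length(nms, 4659)
  expect_equal(anyDuplicated(nms), 0L)
  # closed form: 5 maps x 2 regions x 5 image types x (18 + 75) + 9
  expect_equal(5 * 2 * 5 * (18 + 24 + 16 + 16 + 5 + 14) + 9, 4659)
})

test_that("restricted configurations follow the counting arithmetic", {
  cfg <- radiomics_config(channels = "AAC", regions = "core",
                          image_types = "original", families = character(0),
                          include_shape = FALSE)
  maps <- synthetic_maps(n = 40, seed = 5)
  fv <- extract_frame_features(maps, cfg)
  expect_length(fv, 18)
  cfg2 <- radiomics_config(channels = c("AAC", "SS"), regions = "margin",
                           image_types = c("original", "wavelet-LL"),
                           families = "ngtdm", include_firstorder = FALSE,
                           include_shape = FALSE)
  fv2 <- extract_frame_features(maps, cfg2)
  expect_length(fv2, 2 * 1 * 2 * 5)
})

test_that("frame extraction produces the full finite 4659 vector with matching names", {
  maps <- synthetic_maps(n = 48, seed = 3)
  fv <- fixture("fv4659", function() extract_frame_features(maps))
  expect_length(fv, 4659)
  expect_identical(names(fv), feature_names_full())
  expect_true(all(is.finite(fv)))
  expect_gt(attr(fv, "roi_weight"), 0)
})

test_that("feature vectors are stable across speckle realizations of one phantom", {
  m1 <- synthetic_maps(n = 40, seed = 21)
  m2 <- synthetic_maps(n = 40, seed = 22)
  cfg <- radiomics_config(channels = c("AAC", "SI"),
                          image_types = c("original", "wavelet-LL"))
  f1 <- extract_frame_features(m1, cfg)
  f2 <- extract_frame_features(m2, cfg)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  expect_gt(stats::cor(z(as.numeric(f1)), z(as.numeric(f2))), 0.95)
})

test_that("patient aggregation is a ROI-weighted convex combination", {
  mkfv <- function(vals, w) {
    structure(vals, names = paste0("f", seq_along(vals)), roi_weight = w,
              class = "feature_vector")
  }
  expect_equal(as.numeric(aggregate_patient(list(mkfv(c(1, 5), 3)))),
               c(1, 5))
  expect_equal(as.numeric(aggregate_patient(list(mkfv(c(1, 1), 2),
                                                 mkfv(c(3, 3), 2)))),
               c(2, 2))
  agg <- aggregate_patient(list(mkfv(c(0, 0), 1), mkfv(c(4, 4), 3)))
  expect_equal(as.numeric(agg), c(3, 3))
  expect_equal(attr(agg, "roi_weight"), 4)
  # convexity on random inputs
  set.seed(4)
  fvs <- lapply(1:4, function(i) mkfv(rnorm(6), runif(1, 1, 5)))
  a <- as.numeric(aggregate_patient(fvs))
  V <- do.call(rbind, lapply(fvs, as.numeric))
  expect_true(all(a >= apply(V, 2, min) - 1e-12))
  expect_true(all(a <= apply(V, 2, max) + 1e-12))
  # mismatched names error
  bad <- mkfv(c(1, 2), 1)
  names(bad) <- c("x", "y")
  expect_error(aggregate_patient(list(mkfv(c(1, 2), 1), bad)), "mismatch")
})

test_that("features are invariant to adding a constant before normalization", {
  maps <- synthetic_maps(n = 40, seed = 9)
  cfg <- radiomics_config(channels = "MBF", image_types = "original",
                          include_shape = FALSE)
  f1 <- extract_frame_features(maps, cfg)
  maps$channels$MBF <- maps$channels$MBF + 55
  f2 <- extract_frame_features(maps, cfg)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-8)
})
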