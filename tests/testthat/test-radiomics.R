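test_that("preprocessing z-scores, scales by 100, and masks outliers", {
  set.seed(2)
  m <- matrix(rnorm(40 * 40, 50, 5), 40, 40)
  mask <- matrix(TRUE, 40, 40)
  pp <- preprocess_map(m, mask, c(0.12, 0.12), radiomics_config())
  v <- pp$img[pp$mask]
  expect_lt(abs(mean(v)), 2)
  expect_equal(stats::sd(v), 100, tolerance = 0.05 * 100)
  # a planted extreme pixel is excluded from the processed mask
  m2 <- m
  m2[5, 5] <- mean(m) + 10 * stats::sd(m)
  pp2 <- preprocess_map(m2, mask, c(0.12, 0.12), radiomics_config())
  expect_false(pp2$mask[5, 5])
  # constant map flags and zeroes
  pp3 <- preprocess_map(matrix(4, 10, 10), matrix(TRUE, 10, 10),
                        c(0.12, 0.12), radiomics_config())
  expect_true(pp3$flag_constant)
  expect_true(all(pp3$img[pp3$mask] == 0))
})

test_that("cubic resampling reproduces an analytic ramp away from edges", {
  ny <- 30; nx <- 26
  sp <- c(0.2, 0.2)
  ramp <- outer(seq_len(ny) - 1, seq_len(nx) - 1,
                function(r, c) 3 + 0.7 * r * sp[1] + 1.1 * c * sp[2])
  rs <- resample_image(ramp, matrix(TRUE, ny, nx), sp, 0.12)
  new_y <- seq(0, (ny - 1) * sp[1], by = 0.12)
  new_x <- seq(0, (nx - 1) * sp[2], by = 0.12)
  expected <- outer(new_y, new_x, function(y, x) 3 + 0.7 * y + 1.1 * x)
  interior_r <- 4:(length(new_y) - 4)
  interior_c <- 4:(length(new_x) - 4)
  rel <- abs(rs$img - expected) / abs(expected)
  expect_lt(max(rel[interior_r, interior_c]), 0.01)
})

test_that("preprocessing resamples coarse map grids to the 0.12 mm target", {
  set.seed(8)
  m <- matrix(rnorm(20 * 18, 10, 2), 20, 18)
  mask <- matrix(TRUE, 20, 18)
  mask[1:2, ] <- FALSE
  pp <- preprocess_map(m, mask, spacing_mm = c(1, 1), radiomics_config())
  # 19 mm extent at 0.12 mm spacing
  expect_equal(nrow(pp$img), length(seq(0, 19, by = 0.12)))
  expect_equal(ncol(pp$img), length(seq(0, 17, by = 0.12)))
  expect_equal(dim(pp$img), dim(pp$mask))
  expect_true(any(pp$mask) && !all(pp$mask))
  expect_true(all(is.finite(pp$img[pp$mask])))
})

test_that("fixed-bin-width discretization follows floor arithmetic", {
  img <- matrix(c(0, 14.9, 15, 45), 2, 2)
  d <- discretize_map(img, matrix(TRUE, 2, 2), bin_width = 15)
  expect_equal(as.vector(d$levels), c(1L, 1L, 2L, 4L))
  expect_equal(d$n_levels, 4L)
  dc <- discretize_map(matrix(7, 3, 3), matrix(TRUE, 3, 3), 15)
  expect_equal(dc$n_levels, 1L)
  # uniform samples on [0, 150) occupy 10 levels
  set.seed(1)
  u <- matrix(runif(10000, 0, 150 - 1e-9), 100, 100)
  du <- discretize_map(u, matrix(TRUE, 100, 100), 15)
  expect_equal(du$n_levels, 10L)
  expect_setequal(unique(as.vector(du$levels)), 1:10)
})

test_that("first-order features match hand arithmetic and conventions", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  f <- firstorder_features(img, matrix(TRUE, 2, 2), bin_width = 1,
                           pixel_area_mm2 = 1)
  expect_equal(unname(f["firstorder_Mean"]), 2.5)
  expect_equal(unname(f["firstorder_Variance"]), 1.25)
  expect_equal(unname(f["firstorder_Range"]), 3)
  expect_equal(unname(f["firstorder_Energy"]), 30)
  # constant region conventions
  fc <- firstorder_features(matrix(7, 2, 2), matrix(TRUE, 2, 2))
  expect_equal(unname(fc["firstorder_Variance"]), 0)
  expect_equal(unname(fc["firstorder_Skewness"]), 0)
  expect_equal(unname(fc["firstorder_Uniformity"]), 1)
  # Monte-Carlo: standard normal skewness ~ 0, kurtosis ~ 3
  set.seed(11)
  g <- matrix(rnorm(1000), 40, 25)
  fg <- firstorder_features(g, matrix(TRUE, 40, 25))
  expect_lt(abs(fg["firstorder_Skewness"]), 0.25)
  expect_lt(abs(fg["firstorder_Kurtosis"] - 3), 0.5)
  # oracle agreement on random data
  o <- oracle_firstorder(as.vector(g), bin_width = 15)
  expect_close(unname(fg), unname(o), rel = 1e-10)
})

test_that("shape features match analytic circles and ellipses", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(10 * cos(th) + 20, 10 * sin(th) + 20)
  f <- shape2d_features(circle, raster_mm = 0.12)
  expect_equal(unname(f["shape2D_MeshSurface"]), pi * 100, tolerance = 0.02 * pi * 100)
  expect_equal(unname(f["shape2D_Sphericity"]), 1, tolerance = 0.02)
  expect_equal(unname(f["shape2D_MaximumDiameter"]), 20, tolerance = 0.1)
  ellipse <- cbind(10 * cos(th) + 20, 5 * sin(th) + 20)
  fe <- shape2d_features(ellipse, raster_mm = 0.12)
  expect_equal(unname(fe["shape2D_Elongation"]), 0.5, tolerance = 0.05 * 0.5)
  expect_equal(unname(fe["shape2D_MajorAxisLength"]), 20, tolerance = 0.5)
  # square vs circle of equal area: the circle is more spherical
  side <- sqrt(pi * 100)
  square <- cbind(c(0, side, side, 0) + 10, c(0, 0, side, side) + 10)
  fs <- shape2d_features(square, raster_mm = 0.12)
  expect_lt(unname(fs["shape2D_Sphericity"]), unname(f["shape2D_Sphericity"]))
  expect_error(shape2d_features(cbind(c(0, 1), c(0, 1))), "degenerate")
})
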