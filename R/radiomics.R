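#' Radiomics extraction configuration
#'
#' Preprocessing and discretization settings: in-mask z-normalization scaled
#' by 100, outlier removal at 3 standard deviations, resampling to an
#' isotropic 0.12 mm grid with cubic interpolation, fixed bin width 15,
#' GLCM distances 1-5 averaged at the feature level, and single-level Coif1
#' wavelet subbands.
#'
#' @param normalize_scale scale applied after z-normalization.
#' @param outlier_sigma z cut-off beyond which pixels are masked out.
#' @param resample_mm target grid spacing (mm), isotropic.
#' @param bin_width fixed discretization bin width (in normalized units).
#' @param distances GLCM neighbor distances.
#' @param channels map channels extracted.
#' @param regions regions extracted.
#' @param image_types image types (original + wavelet subbands).
#' @param families texture families.
#' @param include_firstorder,include_shape toggles.
#' @return object of class `radiomics_config`.
#' @export
radiomics_config <- function(normalize_scale = 100, outlier_sigma = 3,
                             resample_mm = 0.12, bin_width = 15,
                             distances = 1:5,
                             channels = c("MBF", "SS", "SI", "ASD", "AAC"),
                             regions = c("core", "margin"),
                             image_types = c("original", "wavelet-LL",
                                             "wavelet-LH", "wavelet-HL",
                                             "wavelet-HH"),
                             families = c("glcm", "glrlm", "glszm", "ngtdm",
                                          "gldm"),
                             include_firstorder = TRUE,
                             include_shape = TRUE) {
  stopifnot(bin_width > 0, all(distances >= 1))
  structure(list(normalize_scale = normalize_scale,
                 outlier_sigma = outlier_sigma, resample_mm = resample_mm,
                 bin_width = bin_width, distances = as.integer(distances),
                 channels = channels, regions = regions,
                 image_types = image_types, families = families,
                 include_firstorder = include_firstorder,
                 include_shape = include_shape),
            class = "radiomics_config")
}

# separable cubic-convolution (Keys, a = -0.5) interpolation weight
.cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

#' Resample a 2-D image to a new grid spacing with cubic interpolation
#'
#' Separable cubic-convolution interpolation (exact on linear ramps); the
#' mask is resampled by nearest neighbor with a 0.5 threshold.
#'
#' @param img numeric matrix (rows axial, cols lateral).
#' @param mask logical matrix, same shape.
#' @param spacing_mm current (row, col) spacing.
#' @param target_mm target isotropic spacing.
#' @return list `img`, `mask` on the new grid.
#' @export
resample_image <- function(img, mask, spacing_mm, target_mm) {
  spacing_mm <- rep(spacing_mm, length.out = 2)
  target_mm <- rep(target_mm, length.out = 2)
  if (all(abs(spacing_mm - target_mm) < 1e-9)) {
    return(list(img = img, mask = mask))
  }
  src_y <- (seq_len(nrow(img)) - 1) * spacing_mm[1]
  src_x <- (seq_len(ncol(img)) - 1) * spacing_mm[2]
  new_y <- seq(0, max(src_y), by = target_mm[1])
  new_x <- seq(0, max(src_x), by = target_mm[2])
  fill <- img
  fill[!mask] <- mean(img[mask])
  interp_1d <- function(m, src, new, along_rows) {
    # along_rows: interpolate over the row coordinate of m
    pos <- (new - src[1]) / (src[2] - src[1])
    i0 <- floor(pos)
    out <- matrix(0, length(new), ncol(m))
    for (k in -1:2) {
      idx <- pmin(pmax(i0 + k + 1, 1), length(src))
      w <- .cubic_kernel(pos - (i0 + k))
      out <- out + m[idx, , drop = FALSE] * w
    }
    out
  }
  tmp <- interp_1d(fill, src_y, new_y)
  out <- t(interp_1d(t(tmp), src_x, new_x))
  nn_y <- pmin(pmax(round((new_y - src_y[1]) / spacing_mm[1]) + 1, 1),
               nrow(img))
  nn_x <- pmin(pmax(round((new_x - src_x[1]) / spacing_mm[2]) + 1, 1),
               ncol(img))
  list(img = out, mask = mask[nn_y, nn_x, drop = FALSE])
}

#' Preprocess a parametric-map channel for feature extraction
#'
#' In-mask z-normalization scaled by `normalize_scale`, outlier masking at
#' `outlier_sigma` standard deviations, then resampling to the target grid.
#' A constant channel cannot be z-scored and yields an all-zero map, flagged.
#'
#' @param channel numeric matrix (map values; NA allowed outside mask).
#' @param mask logical matrix of valid pixels.
#' @param spacing_mm current (row, col) grid spacing.
#' @param cfg `radiomics_config`.
#' @return list `img`, `mask`, `flag_constant`.
#' @export
preprocess_map <- function(channel, mask, spacing_mm,
                           cfg = radiomics_config()) {
  mask <- mask & is.finite(channel)
  if (sum(mask) < 2) stop("preprocess_map needs at least 2 valid pixels")
  v <- channel[mask]
  s <- stats::sd(v)
  flag <- FALSE
  z <- channel
  if (s == 0 || !is.finite(s)) {
    z[] <- 0
    flag <- TRUE
  } else {
    z <- (channel - mean(v)) / s * cfg$normalize_scale
    out <- abs(z) > cfg$outlier_sigma * cfg$normalize_scale
    mask <- mask & !(out & !is.na(out))
  }
  z[!mask] <- NA_real_
  res <- resample_image(z, mask, spacing_mm, rep(cfg$resample_mm, 2))
  res$flag_constant <- flag
  res
}

#' Discretize an image with a fixed bin width
#'
#' `level(x) = floor((x - min) / bin_width) + 1` over the in-mask minimum.
#'
#' @param img numeric matrix.
#' @param mask logical matrix.
#' @param bin_width bin width.
#' @return list `levels` (integer matrix, NA outside mask), `n_levels`.
#' @export
discretize_map <- function(img, mask, bin_width = 15) {
  stopifnot(sum(mask) >= 1)
  v <- img[mask]
  lv <- matrix(NA_integer_, nrow(img), ncol(img))
  lv[mask] <- as.integer(floor((img[mask] - min(v)) / bin_width)) + 1L
  list(levels = lv, n_levels = max(lv, na.rm = TRUE))
}

#' First-order statistical features (18)
#'
#' Standard first-order radiomics set: energy, total energy, entropy (on the
#' fixed-bin-width histogram), minimum, 10th/90th percentiles, maximum, mean,
#' median, interquartile range, range, mean absolute deviation, robust MAD
#' (10-90 percentile subset), RMS, skewness, kurtosis (non-excess), variance
#' (population), uniformity. Constant regions take the documented degenerate
#' values: variance 0, skewness 0, kurtosis 0, uniformity 1.
#'
#' @param img numeric matrix.
#' @param mask logical matrix.
#' @param bin_width histogram bin width for entropy/uniformity.
#' @param pixel_area_mm2 pixel area for total energy.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(img, mask, bin_width = 15,
                                pixel_area_mm2 = 0.12^2) {
  x <- img[mask & is.finite(img)]
  if (length(x) < 2) stop("firstorder_features needs at least 2 valid pixels")
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  sub <- x[x >= q[1] & x <= q[5]]
  lv <- floor((x - min(x)) / bin_width)
  p <- tabulate(lv + 1L, nbins = max(lv) + 1L) / n
  p <- p[p > 0]
  skew <- if (v > 0) mean((x - m)^3) / v^1.5 else 0
  kurt <- if (v > 0) mean((x - m)^4) / v^2 else 0
  c(firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = pixel_area_mm2 * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = q[1],
    firstorder_90Percentile = q[5],
    firstorder_Maximum = max(x),
    firstorder_Mean = m,
    firstorder_Median = q[3],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - m)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(sub) > 0) mean(abs(sub - mean(sub))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = v,
    firstorder_Uniformity = sum(p^2))
}

#' Two-dimensional shape features (9)
#'
#' Computed from the tumor-core contour: mesh surface (polygon area by the
#' shoelace formula), pixel surface, perimeter, perimeter-to-surface ratio,
#' sphericity, maximum 2-D diameter, major and minor axis lengths (from the
#' principal components of the rasterized pixel coordinates, 4 sqrt(lambda)),
#' and elongation (sqrt of the minor/major eigenvalue ratio).
#'
#' @param polygon n x 2 matrix of contour vertices (mm).
#' @param raster_mm rasterization spacing for pixel-based quantities.
#' @return named numeric vector of 9 features.
#' @export
shape2d_features <- function(polygon, raster_mm = 0.12) {
  if (nrow(polygon) < 3) stop("degenerate polygon for shape features")
  x <- polygon[, 1]; y <- polygon[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  area <- abs(sum(x * y2 - x2 * y)) / 2
  if (area <= 0) stop("degenerate polygon for shape features")
  perim <- sum(sqrt((x2 - x)^2 + (y2 - y)^2))
  gx <- seq(min(x), max(x), by = raster_mm)
  gy <- seq(min(y), max(y), by = raster_mm)
  g <- expand.grid(px = gx, py = gy)
  inside <- pracma::inpolygon(g$px, g$py, x, y)
  npix <- sum(inside)
  pts <- as.matrix(g[inside, ])
  ev <- eigen(stats::cov(pts), only.values = TRUE)$values
  ev <- pmax(sort(ev, decreasing = TRUE), 0)
  dd <- as.matrix(stats::dist(polygon))
  c(shape2D_MeshSurface = area,
    shape2D_PixelSurface = npix * raster_mm^2,
    shape2D_Perimeter = perim,
    shape2D_PerimeterSurfaceRatio = perim / area,
    shape2D_Sphericity = 2 * sqrt(pi * area) / perim,
    shape2D_MaximumDiameter = max(dd),
    shape2D_MajorAxisLength = 4 * sqrt(ev[1]),
    shape2D_MinorAxisLength = 4 * sqrt(ev[2]),
    shape2D_Elongation = sqrt(ev[2] / ev[1]))
}
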