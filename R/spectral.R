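#' Spectral analysis configuration
#'
#' Sliding-window spectrum estimation settings: a 2 mm x 2 mm window moved at
#' 94% overlap in both directions (0.12 mm step), analysis band 3-8 MHz, and
#' an assumed attenuation for the intervening skin layer.
#'
#' @param window_mm window side length (mm); square windows.
#' @param overlap_fraction overlap between successive windows, in `[0, 1)`.
#' @param band_mhz analysis band (MHz).
#' @param skin_alpha_db_cm_mhz assumed skin attenuation coefficient.
#' @param skin_thickness_cm assumed skin thickness.
#' @param nfft_min minimum FFT length for window spectra.
#' @return object of class `spectral_config`.
#' @export
spectral_config <- function(window_mm = 2, overlap_fraction = 0.94,
                            band_mhz = c(3, 8),
                            skin_alpha_db_cm_mhz = 0.8,
                            skin_thickness_cm = 0.2,
                            nfft_min = 256L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1,
            window_mm > 0, band_mhz[1] < band_mhz[2])
  structure(list(window_mm = window_mm, overlap_fraction = overlap_fraction,
                 band_mhz = band_mhz,
                 skin_alpha_db_cm_mhz = skin_alpha_db_cm_mhz,
                 skin_thickness_cm = skin_thickness_cm,
                 nfft_min = as.integer(nfft_min)),
            class = "spectral_config")
}

#' Gaussian form-factor configuration
#'
#' The spherical Gaussian form factor `exp(-2 b_ff k^2 a_eff^2)` (intensity)
#' relating the backscatter coefficient to the effective scatterer radius.
#' The standard literature constant 0.827 is adopted.
#'
#' @param b_ff dimensionless Gaussian form-factor constant.
#' @param sound_speed_m_s speed of sound used to convert frequency to
#'   wavenumber.
#' @return object of class `form_factor_config`.
#' @export
form_factor_config <- function(b_ff = 0.827, sound_speed_m_s = 1540) {
  stopifnot(b_ff > 0)
  structure(list(b_ff = b_ff, sound_speed_m_s = sound_speed_m_s),
            class = "form_factor_config")
}

#' Sliding-window placements over an ROI
#'
#' Windows are stepped by `window_mm * (1 - overlap_fraction)` in both the
#' axial and lateral directions (an isotropic map grid); a placement is kept
#' when its centre lies inside the core or margin, and is tagged accordingly.
#'
#' @param roi `roi_set`.
#' @param acq `rf_acquisition` (frame geometry).
#' @param cfg `spectral_config`.
#' @return data.frame with columns `center_x`, `center_y` (mm), `row`, `col`
#'   (map grid indices), `region` ("core"/"margin"); attributes `grid_x`,
#'   `grid_y` (full map grid coordinates) and `step_mm`.
#' @export
sliding_window_grid <- function(roi, acq, cfg = spectral_config()) {
  step <- cfg$window_mm * (1 - cfg$overlap_fraction)
  half <- cfg$window_mm / 2
  x_min <- half
  x_max <- acq$width_mm - half
  y_min <- half
  y_max <- max(axial_positions(acq)) - half
  if (x_max < x_min || y_max < y_min)
    stop("window does not fit inside the frame")
  gx <- seq(x_min, x_max, by = step)
  gy <- seq(y_min, y_max, by = step)
  masks <- rasterize_roi(roi, gx, gy)
  keep <- masks$core | masks$margin
  if (!any(keep)) {
    stop("ROI smaller than one analysis window: minimum lesion extent is ",
         cfg$window_mm, " mm")
  }
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(center_x = gx[idx[, 2]], center_y = gy[idx[, 1]],
                    row = idx[, 1], col = idx[, 2],
                    region = ifelse(masks$core[keep], "core", "margin"),
                    stringsAsFactors = FALSE)
  attr(out, "grid_x") <- gx
  attr(out, "grid_y") <- gy
  attr(out, "step_mm") <- step
  out
}

#' Averaged power spectrum of an RF block
#'
#' Each lateral line of the block is Hanning-tapered along the axial (range)
#' direction, Fourier transformed, and squared; the per-line power spectra
#' are averaged in linear power, converted to dB, and restricted to the
#' analysis band.
#'
#' @param rf_block numeric matrix, axial samples x lateral lines (>= 2 lines).
#' @param fs_mhz axial sampling frequency (MHz).
#' @param cfg `spectral_config`.
#' @param center_mm optional window-centre coordinates recorded in the result.
#' @return object of class `spectrum_estimate`: list with `freq` (MHz),
#'   `power_db`, `window_center`, `n_lines_averaged`.
#' @export
average_power_spectrum <- function(rf_block, fs_mhz, cfg = spectral_config(),
                                   center_mm = c(NA_real_, NA_real_)) {
  stopifnot(is.matrix(rf_block), ncol(rf_block) >= 2)
  if (all(rf_block == 0)) stop("degenerate spectrum: all-zero RF block")
  n <- nrow(rf_block)
  w <- hanning_window(n)
  nfft <- max(cfg$nfft_min, 2^ceiling(log2(n)))
  tap <- rf_block * w
  X <- stats::mvfft(rbind(tap, matrix(0, nfft - n, ncol(tap))))
  pw <- rowMeans(Mod(X)^2)
  freq <- (seq_len(nfft) - 1) * fs_mhz / nfft
  sel <- freq >= cfg$band_mhz[1] & freq <= cfg$band_mhz[2]
  structure(list(freq = freq[sel], power_db = 10 * log10(pw[sel]),
                 window_center = center_mm,
                 n_lines_averaged = ncol(rf_block)),
            class = "spectrum_estimate")
}

#' Hanning taper
#' @param n window length.
#' @return numeric vector.
#' @export
hanning_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Internal: per-window band power spectra for a frame over a window grid.
# Computes one tapered FFT per (axial grid row, lateral line), then averages
# across the lines spanned by each window via cumulative sums. Returns the
# in-band dB spectra for every placement plus the band grid.
.window_spectra <- function(frame, placements, cfg) {
  acq <- frame$acq
  ax <- axial_positions(acq)
  lat <- lateral_positions(acq)
  dz <- ax[2] - ax[1]
  win_ax <- max(2L, round(cfg$window_mm / dz))
  half_lat <- cfg$window_mm / 2
  gy <- attr(placements, "grid_y")
  gx <- attr(placements, "grid_x")
  rows_used <- sort(unique(placements$row))
  nfft <- max(cfg$nfft_min, 2^ceiling(log2(win_ax)))
  freq <- (seq_len(nfft) - 1) * acq$fs_mhz / nfft
  bsel <- which(freq >= cfg$band_mhz[1] & freq <= cfg$band_mhz[2])
  w <- hanning_window(win_ax)
  n_lat <- length(lat)
  # power stack: for each used grid row, in-band power per lateral line
  pw <- array(NA_real_, c(length(rows_used), n_lat, length(bsel)))
  for (ri in seq_along(rows_used)) {
    r <- rows_used[ri]
    i0 <- max(1L, round((gy[r] - cfg$window_mm / 2) / dz) + 1L)
    i1 <- i0 + win_ax - 1L
    if (i1 > nrow(frame$samples)) {
      i1 <- nrow(frame$samples); i0 <- i1 - win_ax + 1L
    }
    seg <- frame$samples[i0:i1, , drop = FALSE] * w
    X <- stats::mvfft(rbind(seg, matrix(0, nfft - win_ax, n_lat)))
    pw[ri, , ] <- t(Mod(X[bsel, , drop = FALSE])^2)
  }
  # cumulative sum across lines for fast window averages
  cs <- array(0, c(length(rows_used), n_lat + 1L, length(bsel)))
  cs[, 2:(n_lat + 1L), ] <- aperm(apply(pw, c(1, 3), cumsum), c(2, 1, 3))
  spectra <- matrix(NA_real_, nrow(placements), length(bsel))
  n_lines <- integer(nrow(placements))
  for (i in seq_len(nrow(placements))) {
    ri <- match(placements$row[i], rows_used)
    j0 <- max(1L, which(lat >= placements$center_x[i] - half_lat)[1])
    j1 <- max(which(lat <= placements$center_x[i] + half_lat))
    n_lines[i] <- j1 - j0 + 1L
    avg <- (cs[ri, j1 + 1L, ] - cs[ri, j0, ]) / n_lines[i]
    spectra[i, ] <- 10 * log10(avg)
  }
  list(freq = freq[bsel], power_db = spectra, n_lines = n_lines)
}

#' Tumor attenuation by the spectral difference method
#'
#' For each in-band frequency, the mean dB power of in-ROI windows is
#' regressed against window depth; the per-frequency slope equals
#' `-2 alpha f` (round trip), and `alpha` is recovered by a least-squares fit
#' of the slope magnitudes against frequency.
#'
#' @param frames list of `rf_frame` (or a single frame).
#' @param roi `roi_set`.
#' @param cfg `spectral_config`.
#' @param region which windows enter the regression ("core" for the tumor).
#' @return object of class `attenuation_estimate`: `alpha_db_cm_mhz`,
#'   `fit_r2`, `depth_span_cm`, `flag_negative`.
#' @export
estimate_attenuation_spectral_difference <- function(frames, roi,
                                                     cfg = spectral_config(),
                                                     region = "core") {
  if (inherits(frames, "rf_frame")) frames <- list(frames)
  acc <- list()
  for (fr in frames) {
    pl <- sliding_window_grid(roi, fr$acq, cfg)
    pl_r <- pl[pl$region %in% region, , drop = FALSE]
    attr(pl_r, "grid_x") <- attr(pl, "grid_x")
    attr(pl_r, "grid_y") <- attr(pl, "grid_y")
    if (nrow(pl_r) == 0) next
    ws <- .window_spectra(fr, pl_r, cfg)
    acc[[length(acc) + 1]] <- list(freq = ws$freq, power = ws$power_db,
                                   depth = pl_r$center_y / 10) # cm
  }
  if (length(acc) == 0) stop("no in-ROI windows for attenuation estimation")
  freq <- acc[[1]]$freq
  power <- do.call(rbind, lapply(acc, `[[`, "power"))
  depth <- unlist(lapply(acc, `[[`, "depth"))
  rows_span <- diff(range(depth)) / (cfg$window_mm / 10)
  if (rows_span < 2)
    stop("ROI depth span below two window rows; cannot regress attenuation")
  dbar <- depth - mean(depth)
  sxx <- sum(dbar^2)
  slopes <- as.vector(crossprod(dbar, power)) / sxx       # dB/cm per freq
  # slope(f) = -2 alpha f  =>  alpha = -sum(f*slope) / (2 sum(f^2))
  alpha <- -sum(freq * slopes) / (2 * sum(freq^2))
  pred <- -2 * alpha * freq
  ss_res <- sum((slopes - pred)^2)
  ss_tot <- sum((slopes - mean(slopes))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(alpha_db_cm_mhz = alpha, fit_r2 = r2,
                 depth_span_cm = diff(range(depth)),
                 flag_negative = alpha < 0),
            class = "attenuation_estimate")
}

#' Compensate a spectrum for layered attenuation
#'
#' Adds the round-trip attenuation `sum_layers 2 * alpha_l * f * d_l` (dB)
#' back onto the spectrum; the frequency grid is unchanged.
#'
#' @param spec `spectrum_estimate`.
#' @param layers data.frame/list with `alpha_db_cm_mhz` and `thickness_cm`.
#' @return corrected `spectrum_estimate`.
#' @export
correct_attenuation <- function(spec, layers) {
  alpha <- layers$alpha_db_cm_mhz
  d <- layers$thickness_cm
  stopifnot(length(alpha) == length(d), all(d >= 0))
  total <- sum(2 * alpha * d)
  spec$power_db <- spec$power_db + total * spec$freq
  spec
}

#' Backscatter coefficient by reference-phantom normalization
#'
#' Divides the sample spectrum by the averaged reference-phantom spectrum
#' (in dB: subtraction) and multiplies by the known reference BSC, cancelling
#' the system transfer function.
#'
#' @param spec `spectrum_estimate` of the sample (attenuation-corrected).
#' @param reference list with `freq`, `power_db` (averaged reference
#'   spectrum) and `bsc` (linear reference BSC on the same grid, or a
#'   function of frequency).
#' @return list with `freq` and `bsc` (linear units).
#' @export
normalize_to_bsc <- function(spec, reference) {
  if (length(reference$freq) != length(spec$freq) ||
      max(abs(reference$freq - spec$freq)) > 1e-9)
    stop("band mismatch between sample and reference spectra")
  bsc_ref <- if (is.function(reference$bsc)) reference$bsc(spec$freq)
             else reference$bsc
  if (any(!is.finite(reference$power_db)))
    stop("reference power must be finite over the analysis band")
  list(freq = spec$freq,
       bsc = 10^((spec$power_db - reference$power_db) / 10) * bsc_ref)
}

#' Linear-fit spectral parameters (MBF, SS, SI)
#'
#' Ordinary least squares of the dB spectrum on frequency over the analysis
#' band. SS is the slope (dB/MHz), SI the intercept at 0 MHz (dB), and MBF
#' the fitted value at the band midpoint: `MBF = SS * f_mid + SI` exactly.
#'
#' @param spec `spectrum_estimate`.
#' @param cfg `spectral_config` (supplies the band midpoint).
#' @return named numeric vector `c(mbf, ss, si)`.
#' @export
fit_linear_spectral <- function(spec, cfg = spectral_config()) {
  f <- spec$freq
  if (length(f) < 3) stop("need at least 3 in-band frequency points")
  if (stats::var(f) == 0) stop("singular design: single frequency")
  p <- spec$power_db
  fb <- f - mean(f)
  ss <- sum(fb * p) / sum(fb^2)
  si <- mean(p) - ss * mean(f)
  f_mid <- mean(cfg$band_mhz)
  c(mbf = ss * f_mid + si, ss = ss, si = si)
}

#' Gaussian form-factor inversion of a backscatter coefficient
#'
#' Linearizes the model `BSC(f) = linear(AAC) f^4 exp(-2 b_ff k^2 a^2)` as
#' `ln BSC - 4 ln f = ln linear(AAC) - 2 b_ff (2 pi / c)^2 a^2 f^2` and
#' solves by least squares of the left side on `f^2`. ASD is twice the
#' recovered effective radius; AAC is the intercept on the dB scale. A
#' non-negative slope (non-physical size) yields ASD 0 with AAC from the
#' f^4-only fit, flagged.
#'
#' @param bsc list with `freq` (MHz) and `bsc` (linear, positive in band).
#' @param ff `form_factor_config`.
#' @return named list `asd_um`, `aac_db`, `flagged`.
#' @export
fit_gaussian_form_factor <- function(bsc, ff = form_factor_config()) {
  f <- bsc$freq
  v <- bsc$bsc
  if (any(v <= 0)) stop("non-positive BSC in band; cannot linearize")
  y <- log(v) - 4 * log(f)
  x <- f^2
  xb <- x - mean(x)
  s <- sum(xb * y) / sum(xb^2)
  c0 <- mean(y) - s * mean(x)
  # k = 2 pi f 1e6 / c  (f in MHz) ; slope = -2 b (2 pi 1e6 / c)^2 a^2
  kk <- (2 * pi * 1e6 / ff$sound_speed_m_s)^2
  if (s < 0) {
    a_m <- sqrt(-s / (2 * ff$b_ff * kk))
    list(asd_um = 2 * a_m * 1e6, aac_db = 10 * c0 / log(10), flagged = FALSE)
  } else {
    list(asd_um = 0, aac_db = 10 * mean(y) / log(10), flagged = TRUE)
  }
}

#' Build the five QUS spectral parametric maps for a frame
#'
#' Runs the full per-window chain: averaged power spectrum, attenuation
#' correction (assumed skin layer plus the frame-level tumor attenuation
#' estimate applied over each window's in-tumor depth), linear-fit parameters
#' (MBF, SS, SI), reference-phantom BSC normalization, and Gaussian
#' form-factor inversion (ASD, AAC). Values are written at the window-centre
#' grid nodes; nodes outside core and margin are NA.
#'
#' @param frame `rf_frame`.
#' @param roi `roi_set`.
#' @param reference reference spectrum list: `freq`, `power_db`, `bsc` (see
#'   [reference_spectrum()]).
#' @param cfg `spectral_config`.
#' @param ff `form_factor_config`.
#' @param alpha_tumor optional known tumor attenuation (dB/cm/MHz); when NULL
#'   it is estimated from the frame by the spectral difference method.
#' @return object of class `qus_maps`: list with `channels` (named list of
#'   matrices MBF, SS, SI, ASD, AAC on the map grid), `grid_x`, `grid_y`,
#'   `grid_spacing_mm`, `core_mask`, `margin_mask`, `alpha_tumor`,
#'   `ff_flagged` (count).
#' @export
build_parametric_maps <- function(frame, roi, reference,
                                  cfg = spectral_config(),
                                  ff = form_factor_config(),
                                  alpha_tumor = NULL) {
  placements <- sliding_window_grid(roi, frame$acq, cfg)
  gx <- attr(placements, "grid_x")
  gy <- attr(placements, "grid_y")
  ws <- .window_spectra(frame, placements, cfg)
  if (is.null(alpha_tumor)) {
    at <- tryCatch(
      estimate_attenuation_spectral_difference(frame, roi, cfg),
      error = function(e) NULL)
    alpha_tumor <- if (is.null(at)) 0 else max(0, at$alpha_db_cm_mhz)
  }
  f <- ws$freq
  # attenuation correction per window: skin layer + tumor path down to the
  # window centre (measured from the top of the ROI outer contour)
  roi_top_cm <- min(roi$outer[, 2]) / 10
  tumor_path_cm <- pmax(0, placements$center_y / 10 - roi_top_cm)
  corr_db <- outer(2 * (cfg$skin_alpha_db_cm_mhz * cfg$skin_thickness_cm +
                          alpha_tumor * tumor_path_cm), f)
  W <- ws$power_db + corr_db
  # vectorized linear fits over the band
  fb <- f - mean(f)
  sxx <- sum(fb^2)
  ss <- as.vector(W %*% fb) / sxx
  si <- rowMeans(W) - ss * mean(f)
  f_mid <- mean(cfg$band_mhz)
  mbf <- ss * f_mid + si
  # vectorized BSC + form-factor fits
  if (length(reference$freq) != length(f) ||
      max(abs(reference$freq - f)) > 1e-9)
    stop("reference spectrum band does not match the analysis band")
  bsc_ref <- if (is.function(reference$bsc)) reference$bsc(f) else reference$bsc
  Y <- (W - matrix(reference$power_db, nrow(W), length(f), byrow = TRUE)) *
    (log(10) / 10) + matrix(log(bsc_ref) - 4 * log(f), nrow(W), length(f),
                            byrow = TRUE)
  x <- f^2
  xb <- x - mean(x)
  s_ff <- as.vector(Y %*% xb) / sum(xb^2)
  c0 <- rowMeans(Y) - s_ff * mean(x)
  kk <- (2 * pi * 1e6 / ff$sound_speed_m_s)^2
  neg <- s_ff < 0
  asd <- ifelse(neg, 2e6 * sqrt(pmax(-s_ff, 0) / (2 * ff$b_ff * kk)), 0)
  aac <- ifelse(neg, 10 * c0 / log(10), 10 * rowMeans(Y) / log(10))
  put <- function(v) {
    m <- matrix(NA_real_, length(gy), length(gx))
    m[cbind(placements$row, placements$col)] <- v
    m
  }
  core_mask <- matrix(FALSE, length(gy), length(gx))
  core_mask[cbind(placements$row, placements$col)] <-
    placements$region == "core"
  margin_mask <- matrix(FALSE, length(gy), length(gx))
  margin_mask[cbind(placements$row, placements$col)] <-
    placements$region == "margin"
  structure(list(channels = list(MBF = put(mbf), SS = put(ss), SI = put(si),
                                 ASD = put(asd), AAC = put(aac)),
                 grid_x = gx, grid_y = gy,
                 grid_spacing_mm = c(attr(placements, "step_mm"),
                                     attr(placements, "step_mm")),
                 core_mask = core_mask, margin_mask = margin_mask,
                 alpha_tumor = alpha_tumor, ff_flagged = sum(!neg),
                 roi = roi),
            class = "qus_maps")
}

#' Averaged reference spectrum from reference phantom frames
#'
#' Computes the window-averaged power spectrum of homogeneous reference
#' frames over a regular (non-overlapping) window grid, averaged over all
#' windows and frames. With a zero-attenuation reference the result is
#' depth-independent.
#'
#' @param ref output of [generate_reference_frames()].
#' @param cfg `spectral_config`.
#' @return list with `freq`, `power_db`, `bsc` (function), suitable for
#'   [normalize_to_bsc()] and [build_parametric_maps()].
#' @export
reference_spectrum <- function(ref, cfg = spectral_config()) {
  cfg0 <- cfg
  cfg0$overlap_fraction <- 0 # independent windows suffice for the average
  acc <- NULL
  n <- 0
  for (fr in ref$frames) {
    acq <- fr$acq
    roi <- roi_ellipse(c(acq$width_mm / 2, acq$depth_mm / 2),
                       c(acq$width_mm / 2 - cfg$window_mm - 5,
                         acq$depth_mm / 2 - cfg$window_mm - 5),
                       margin_mm = 4.9)
    pl <- sliding_window_grid(roi, acq, cfg0)
    ws <- .window_spectra(fr, pl, cfg0)
    lin <- 10^(ws$power_db / 10)
    acc <- if (is.null(acc)) colSums(lin) else acc + colSums(lin)
    n <- n + nrow(lin)
    freq <- ws$freq
  }
  list(freq = freq, power_db = 10 * log10(acc / n), bsc = ref$bsc)
}
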