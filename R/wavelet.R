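#' Coiflet-1 filter bank
#'
#' Orthonormal Coif1 (6-tap) decomposition filters; the high-pass is the
#' quadrature mirror of the low-pass. Reconstruction filters are the
#' time-reversed pair.
#' @return list with `lo`, `hi` (decomposition), `lo_r`, `hi_r`
#'   (reconstruction).
#' @export
coif1_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi, lo_r = rev(lo), hi_r = rev(hi))
}

# circular convolution of each column of x with kernel h (aligned so that
# analysis followed by time-reversed synthesis telescopes to the identity)
.circ_filter_cols <- function(x, h) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(h)) {
    idx <- ((seq_len(n) - 1 + (k - 1)) %% n) + 1
    out <- out + h[k] * x[idx, , drop = FALSE]
  }
  out
}

.circ_filter_rows <- function(x, h) t(.circ_filter_cols(t(x), h))

#' Single-level undecimated 2-D wavelet transform (periodic core)
#'
#' Separable stationary (no downsampling) analysis with circular boundary
#' handling; all four subbands have the shape of the input and the transform
#' is exactly invertible by [iswt2()].
#'
#' @param image numeric matrix.
#' @param filters filter bank from [coif1_filters()].
#' @return list of matrices `LL`, `LH`, `HL`, `HH`. Subband labels follow the
#'   row/column filter order: the first letter is the row (vertical) filter,
#'   the second the column (horizontal) filter.
#' @export
swt2 <- function(image, filters = coif1_filters()) {
  lo_c <- .circ_filter_cols(image, filters$lo)
  hi_c <- .circ_filter_cols(image, filters$hi)
  list(LL = .circ_filter_rows(lo_c, filters$lo),
       LH = .circ_filter_rows(lo_c, filters$hi),
       HL = .circ_filter_rows(hi_c, filters$lo),
       HH = .circ_filter_rows(hi_c, filters$hi))
}

#' Inverse of [swt2()]
#' @param sb subband list from [swt2()].
#' @param filters filter bank.
#' @return reconstructed matrix.
#' @export
iswt2 <- function(sb, filters = coif1_filters()) {
  lo_c <- .circ_filter_rows(sb$LL, filters$lo_r) +
    .circ_filter_rows(sb$LH, filters$hi_r)
  hi_c <- .circ_filter_rows(sb$HL, filters$lo_r) +
    .circ_filter_rows(sb$HH, filters$hi_r)
  z <- (.circ_filter_cols(lo_c, filters$lo_r) +
          .circ_filter_cols(hi_c, filters$hi_r)) / 4
  # analysis + time-reversed synthesis leaves a circular lag of L-1 per axis
  s <- length(filters$lo) - 1L
  roll <- function(i, n) ((i - 1 - s) %% n) + 1
  z[roll(seq_len(nrow(z)), nrow(z)), roll(seq_len(ncol(z)), ncol(z)),
    drop = FALSE]
}

#' Wavelet subbands of an image with symmetric boundary extension
#'
#' Pads the image by symmetric reflection, applies the undecimated Coif1
#' transform, and crops back, so each subband keeps the input shape and the
#' original ROI mask applies unchanged.
#'
#' @param image numeric matrix, at least as large as the filter length (6)
#'   in both dimensions.
#' @param filters filter bank.
#' @return list of matrices `LL`, `LH`, `HL`, `HH`.
#' @export
wavelet_subbands <- function(image, filters = coif1_filters()) {
  L <- length(filters$lo)
  if (nrow(image) < L || ncol(image) < L)
    stop("image smaller than the wavelet filter length (", L, ")")
  p <- L
  ri <- c(rev(seq_len(p)), seq_len(nrow(image)),
          nrow(image) - seq_len(p) + 1)
  ci <- c(rev(seq_len(p)), seq_len(ncol(image)),
          ncol(image) - seq_len(p) + 1)
  padded <- image[ri, ci, drop = FALSE]
  sb <- swt2(padded, filters)
  # analysis is a forward correlation; crop 2 early to roughly centre the
  # 6-tap filter support on each output pixel
  off <- p - 2L
  crop <- function(m) m[off + seq_len(nrow(image)),
                        off + seq_len(ncol(image)), drop = FALSE]
  lapply(sb, crop)
}
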