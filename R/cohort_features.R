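#' Simulate a cohort directly at the feature-matrix level
#'
#' A fast companion to the RF phantom chain for experiments that probe the
#' cross-validation protocol itself (permutation nulls, planted-effect power,
#' complexity sweeps): patients are drawn as standard-normal feature vectors
#' and a chosen number of informative features receive a class mean shift.
#' Informative features are given margin-texture style names (the kind of
#' feature the imaging chain finds discriminative); the rest are generic.
#'
#' @param n_low,n_high class sizes (labels 0 and 1).
#' @param p number of features.
#' @param n_informative number of class-shifted features.
#' @param effect_sd mean shift in within-class standard deviations.
#' @param rho equicorrelation among the informative features.
#' @param seed integer.
#' @return list `X`, `y`, `patient_id`, `odxrs` (scores consistent with the
#'   labels under the threshold-15 dichotomy).
#' @export
simulate_feature_cohort <- function(n_low = 10, n_high = 21, p = 200,
                                    n_informative = 4, effect_sd = 1.5,
                                    rho = 0.3, seed = 1L) {
  stopifnot(n_informative <= p)
  set.seed(as.integer(seed))
  n <- n_low + n_high
  y <- c(rep(0L, n_low), rep(1L, n_high))
  X <- matrix(stats::rnorm(n * p), n, p)
  if (n_informative > 0 && rho > 0) {
    shared <- stats::rnorm(n)
    X[, seq_len(n_informative)] <-
      sqrt(rho) * shared + sqrt(1 - rho) * X[, seq_len(n_informative)]
  }
  if (n_informative > 0) {
    X[y == 1, seq_len(n_informative)] <-
      X[y == 1, seq_len(n_informative)] + effect_sd
  }
  info_templates <- c("original_glcm_Correlation_margin_AAC",
                      "wavelet-LL_glcm_Correlation_margin_AAC",
                      "wavelet-HL_firstorder_Skewness_margin_SI",
                      "wavelet-HL_gldm_DependenceEntropy_margin_SS",
                      "wavelet-LH_ngtdm_Complexity_margin_SS",
                      "wavelet-HH_firstorder_MeanAbsoluteDeviation_margin_SI")
  nms <- sprintf("noise_feature_%04d", seq_len(p))
  ninfo <- min(n_informative, length(info_templates))
  if (ninfo > 0) nms[seq_len(ninfo)] <- info_templates[seq_len(ninfo)]
  colnames(X) <- nms
  odxrs <- ifelse(y == 1L, sample(16:35, n, replace = TRUE),
                  sample(3:15, n, replace = TRUE))
  list(X = X, y = y, patient_id = sprintf("P%02d", seq_len(n)),
       odxrs = odxrs)
}
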