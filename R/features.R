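#' Full feature-name vector for a configuration
#'
#' Names are encoded as
#' `{image_type}_{class}_{feature}_{region}_{map}`; shape features are
#' computed once per patient from the core contour and carry no map suffix.
#' For the full configuration the vector has exactly
#' `5 maps x 2 regions x 5 image types x (18 + 75) + 9 = 4659` entries.
#'
#' @param cfg `radiomics_config`.
#' @return character vector of feature names (fixed order).
#' @export
feature_names_full <- function(cfg = radiomics_config()) {
  fam_names <- list(
    firstorder = sub("^firstorder_", "",
                     names(firstorder_features(matrix(c(1, 2, 3, 4), 2),
                                               matrix(TRUE, 2, 2)))),
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy", "MCC",
             "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
              "RunPercentage", "GrayLevelVariance", "RunVariance",
              "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
              "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
              "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity",
              "Strength"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"))
  classes <- c(if (cfg$include_firstorder) "firstorder", cfg$families)
  nms <- character(0)
  for (map in cfg$channels) for (region in cfg$regions) {
    for (it in cfg$image_types) for (cl in classes) {
      nms <- c(nms, paste(it, cl, fam_names[[cl]], region, map, sep = "_"))
    }
  }
  if (cfg$include_shape) {
    shp <- c("MeshSurface", "PixelSurface", "Perimeter",
             "PerimeterSurfaceRatio", "Sphericity", "MaximumDiameter",
             "MajorAxisLength", "MinorAxisLength", "Elongation")
    nms <- c(nms, paste("original_shape2D", shp, "core", sep = "_"))
  }
  nms
}

#' Extract the radiomics feature vector for one frame's QUS maps
#'
#' For each channel and region, the map is preprocessed (z-normalized,
#' scaled, outlier-masked, resampled), decomposed into Coif1 wavelet
#' subbands, discretized with the fixed bin width, and passed through the
#' first-order and texture feature sets. Shape features are computed once
#' from the core contour. The ROI weight (total valid pixel count) used for
#' patient-level aggregation is attached.
#'
#' @param maps `qus_maps` object.
#' @param cfg `radiomics_config`.
#' @return object of class `feature_vector`: named numeric vector with
#'   attribute `roi_weight`.
#' @export
extract_frame_features <- function(maps, cfg = radiomics_config()) {
  classes <- c(if (cfg$include_firstorder) "firstorder", cfg$families)
  vals <- numeric(0)
  nms <- character(0)
  roi_weight <- 0
  for (map in cfg$channels) {
    channel <- maps$channels[[map]]
    if (is.null(channel)) stop("missing map channel ", map)
    for (region in cfg$regions) {
      mask <- if (region == "core") maps$core_mask else maps$margin_mask
      if (sum(mask & is.finite(channel)) < 4) {
        stop("region '", region, "' of channel ", map,
             " is fully masked out or too small")
      }
      pp <- preprocess_map(channel, mask, maps$grid_spacing_mm, cfg)
      roi_weight <- roi_weight + sum(pp$mask)
      images <- list(original = pp$img)
      if (any(grepl("^wavelet", cfg$image_types))) {
        fillv <- pp$img
        fillv[!pp$mask] <- mean(pp$img[pp$mask])
        sb <- wavelet_subbands(fillv)
        images[["wavelet-LL"]] <- sb$LL
        images[["wavelet-LH"]] <- sb$LH
        images[["wavelet-HL"]] <- sb$HL
        images[["wavelet-HH"]] <- sb$HH
      }
      for (it in cfg$image_types) {
        img <- images[[it]]
        dz <- discretize_map(img, pp$mask, cfg$bin_width)
        lv <- dz$levels
        for (cl in classes) {
          fv <- if (cl == "firstorder") {
            firstorder_features(img, pp$mask, cfg$bin_width,
                                pixel_area_mm2 = cfg$resample_mm^2)
          } else {
            texture_features(lv, dz$n_levels, cl, cfg$distances)
          }
          vals <- c(vals, unname(fv))
          nms <- c(nms, paste(it, cl, sub("^[a-z0-9]+_", "", names(fv)),
                              region, map, sep = "_"))
        }
      }
    }
  }
  if (cfg$include_shape) {
    fv <- shape2d_features(maps$roi$core, raster_mm = cfg$resample_mm)
    vals <- c(vals, unname(fv))
    nms <- c(nms, paste("original", "shape2D",
                        sub("^shape2D_", "", names(fv)), "core", sep = "_"))
  }
  names(vals) <- nms
  if (anyNA(vals)) {
    bad <- nms[is.na(vals)]
    stop("NaN feature values: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  structure(vals, roi_weight = roi_weight, class = "feature_vector")
}

#' ROI-size-weighted aggregation of frame feature vectors
#'
#' Per-patient feature vector as the weighted average of frame vectors,
#' weights being each frame's ROI pixel count. The aggregate is a convex
#' combination of the frame values.
#'
#' @param frame_vectors list of `feature_vector`.
#' @return `feature_vector` with summed ROI weight.
#' @export
aggregate_patient <- function(frame_vectors) {
  stopifnot(length(frame_vectors) >= 1)
  nms <- names(frame_vectors[[1]])
  for (fv in frame_vectors) {
    if (!identical(names(fv), nms)) stop("feature name mismatch across frames")
  }
  w <- vapply(frame_vectors, function(fv) attr(fv, "roi_weight"), numeric(1))
  V <- do.call(rbind, lapply(frame_vectors, as.numeric))
  out <- as.vector(crossprod(V, w / sum(w)))
  names(out) <- nms
  structure(out, roi_weight = sum(w), class = "feature_vector")
}

#' Assemble a cohort feature matrix
#'
#' @param patient_vectors named list of aggregated `feature_vector`s.
#' @param records list of clinical records (see [clinical_record()]).
#' @return list with `X` (patients x features matrix), `y` (binary labels),
#'   `patient_id`, `odxrs`.
#' @export
feature_matrix <- function(patient_vectors, records) {
  stopifnot(length(patient_vectors) == length(records))
  X <- do.call(rbind, lapply(patient_vectors, as.numeric))
  colnames(X) <- names(patient_vectors[[1]])
  rownames(X) <- vapply(records, `[[`, character(1), "patient_id")
  list(X = X,
       y = vapply(records, `[[`, integer(1), "label"),
       patient_id = rownames(X),
       odxrs = vapply(records, `[[`, integer(1), "odxrs"))
}
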