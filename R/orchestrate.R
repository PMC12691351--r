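#' Experiment configuration
#'
#' One nested configuration drives the whole chain; every protocol constant
#' (2 mm window, 94% overlap, 0.12 mm grid, bin width 15, MRMR 50, SFS 4,
#' 5% contamination, ODXRS threshold 15) is a named field defaulting to its
#' protocol value.
#'
#' @param path optional YAML file; fields override the defaults.
#' @param ... further overrides (named sub-lists).
#' @return list of class `experiment_config` with components `cohort`,
#'   `spectral`, `form_factor`, `radiomics`, `pipeline`, `stats`, `seed`.
#' @export
experiment_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    cohort = list(n_low = 10L, n_high = 21L, frames_per_patient = 3L,
                  odxrs_threshold = 15L),
    acquisition = as.list(unclass(rf_acquisition())),
    spectral = as.list(unclass(spectral_config())),
    form_factor = as.list(unclass(form_factor_config())),
    radiomics = as.list(unclass(radiomics_config())),
    pipeline = as.list(unclass(pipeline_config())),
    stats = as.list(unclass(stats_config())),
    classifiers = c("lda", "knn", "svm-linear", "svm-rbf", "rf"))
  override <- list()
  if (!is.null(path)) override <- yaml::read_yaml(path)
  override <- utils::modifyList(override, list(...))
  known <- names(cfg)
  unknown <- setdiff(names(override), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, override)
  class(cfg) <- "experiment_config"
  cfg
}

.rebuild <- function(lst, ctor) do.call(ctor, lst[names(lst) %in%
                                                    names(formals(ctor))])

#' Run the full experiment end to end
#'
#' Simulate (or ingest) a cohort, build QUS parametric maps against a
#' simulated reference phantom, extract and aggregate radiomics features,
#' run the nested-LOOCV evaluation for each requested classifier, screen the
#' selected features univariately, and write all tables plus a
#' reproducibility manifest to `out_dir`. Idempotent under a fixed
#' configuration and seed.
#'
#' @param cfg `experiment_config`.
#' @param out_dir output directory (created).
#' @param feature_matrix optional precomputed feature matrix (list with `X`,
#'   `y`) to skip the imaging stages.
#' @return invisible list with `features`, `cv` (per classifier), `screen`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = tempdir(),
                           feature_matrix = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timers <- list()
  acq <- .rebuild(cfg$acquisition, rf_acquisition)
  scfg <- .rebuild(cfg$spectral, spectral_config)
  ff <- .rebuild(cfg$form_factor, form_factor_config)
  rcfg <- .rebuild(cfg$radiomics, radiomics_config)
  pcfg <- .rebuild(cfg$pipeline, pipeline_config)
  pcfg$seed <- as.integer(cfg$seed)
  if (is.null(feature_matrix)) {
    message("stage: simulate")
    cohort <- generate_cohort(cfg$cohort$n_low, cfg$cohort$n_high,
                              cfg$cohort$frames_per_patient, acq,
                              seed = cfg$seed, ff = ff)
    timers$simulate <- as.numeric(Sys.time() - t0, units = "secs")
    message("stage: maps + features")
    ref <- generate_reference_frames(acq, n_frames = 3L, seed = cfg$seed)
    refspec <- reference_spectrum(ref, scfg)
    vecs <- lapply(cohort, function(pat) {
      fvs <- mapply(function(fr, roi) {
        maps <- build_parametric_maps(fr, roi, refspec, scfg, ff)
        extract_frame_features(maps, rcfg)
      }, pat$frames, pat$rois, SIMPLIFY = FALSE)
      aggregate_patient(fvs)
    })
    fm <- feature_matrix(vecs, lapply(cohort, `[[`, "record"))
    timers$features <- as.numeric(Sys.time() - t0, units = "secs")
  } else {
    fm <- feature_matrix
  }
  utils::write.csv(
    data.frame(patient_id = if (!is.null(fm$patient_id)) fm$patient_id
               else rownames(fm$X),
               label = fm$y, fm$X, check.names = FALSE),
    file.path(out_dir, "features.csv"), row.names = FALSE)
  message("stage: fit")
  cv <- list()
  for (kind in cfg$classifiers) {
    cv[[kind]] <- nested_loocv_run(fm$X, fm$y, classifier_spec(kind), pcfg)
  }
  timers$fit <- as.numeric(Sys.time() - t0, units = "secs")
  message("stage: stats")
  sel <- mrmr_select(standardize_fit_apply(fm$X)$dev, fm$y,
                     k = min(pcfg$mrmr_k, ncol(fm$X)), eps = pcfg$mrmr_eps)
  screen <- screen_features(fm$X[, sel, drop = FALSE], fm$y,
                            .rebuild(cfg$stats, stats_config))
  utils::write.csv(screen, file.path(out_dir, "univariate_screen.csv"),
                   row.names = FALSE)
  metric_rows <- do.call(rbind, lapply(names(cv), function(k) {
    m <- cv[[k]]$metrics
    data.frame(classifier = k, recall = m$recall,
               specificity = m$specificity, accuracy = m$accuracy,
               balanced_accuracy = m$balanced_accuracy,
               precision = m$precision, npv = m$npv, f1 = m$f1,
               auroc = m$auroc, auprc = m$auprc,
               TP = m$counts$TP, FP = m$counts$FP, TN = m$counts$TN,
               FN = m$counts$FN)
  }))
  utils::write.csv(metric_rows, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cfg$seed,
                   classifiers = cfg$classifiers,
                   n_patients = nrow(fm$X), n_features = ncol(fm$X),
                   timers_sec = timers,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = fm, cv = cv, screen = screen,
                 metrics_table = metric_rows))
}

#' Render a plain-text report of an experiment
#'
#' @param results return value of [run_experiment()].
#' @param path output file.
#' @return the report lines, invisibly.
#' @export
write_report <- function(results, path = NULL) {
  lines <- c("# Classification report", "")
  if (!is.null(results$metrics_table)) {
    mt <- results$metrics_table
    lines <- c(lines, "## Metric panel (aggregated LOO test predictions)", "")
    for (i in seq_len(nrow(mt))) {
      r <- mt[i, ]
      lines <- c(lines, sprintf(
        "- %s: recall %.0f%% (%d/%d), specificity %.0f%% (%d/%d), accuracy %.0f%%, balanced accuracy %.0f%%, precision %.0f%%, NPV %.0f%%, F1 %.0f%%, AUROC %.2f, AUPRC %.2f",
        r$classifier, r$recall, r$TP, r$TP + r$FN, r$specificity, r$TN,
        r$TN + r$FP, r$accuracy, r$balanced_accuracy, r$precision, r$npv,
        r$f1, r$auroc, r$auprc))
    }
  } else {
    lines <- c(lines, "## Metric panel: unavailable")
  }
  lines <- c(lines, "")
  if (!is.null(results$cv)) {
    lines <- c(lines, "## Most frequently selected features", "")
    for (k in names(results$cv)) {
      f <- utils::head(results$cv[[k]]$selection_frequency, 5)
      lines <- c(lines, sprintf("- %s: %s", k,
                                paste(sprintf("%s (%d)", names(f), f),
                                      collapse = ", ")))
    }
  }
  lines <- c(lines, "")
  if (!is.null(results$screen)) {
    lines <- c(lines, "## Univariate screen (top features)", "")
    top <- utils::head(results$screen, 10)
    for (i in seq_len(nrow(top))) {
      lines <- c(lines, sprintf("- %s: %s test, p = %.3g%s", top$feature[i],
                                top$test[i], top$p_value[i],
                                ifelse(top$bonferroni_pass[i], " (**)",
                                       ifelse(top$raw_pass[i], " (*)", ""))))
    }
  } else {
    lines <- c(lines, "## Univariate screen: unavailable")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a simulated cohort to a directory tree
#'
#' One sub-directory per patient: RF frames as CSV matrices with a JSON
#' sidecar (sampling, pitch, centre frequency, band, sound speed), ROIs as
#' closed polygons in JSON (mm; x lateral, y axial depth), and a cohort-level
#' clinical CSV (patient_id, odxrs, label).
#'
#' @param cohort output of [generate_cohort()].
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  clin <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$record$patient_id, odxrs = p$record$odxrs,
               label = p$record$label)
  }))
  utils::write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
  for (p in cohort) {
    pd <- file.path(dir, p$record$patient_id)
    dir.create(pd, showWarnings = FALSE)
    for (i in seq_along(p$frames)) {
      fr <- p$frames[[i]]
      utils::write.table(fr$samples,
                         file.path(pd, sprintf("frame%02d.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(fs_mhz = fr$acq$fs_mhz, pitch_mm = fr$acq$pitch_mm,
             fc_mhz = fr$acq$fc_mhz, band_mhz = fr$acq$band_mhz,
             sound_speed_m_s = fr$acq$sound_speed_m_s),
        file.path(pd, sprintf("frame%02d.json", i)), auto_unbox = TRUE,
        digits = NA)
      roi <- p$rois[[i]]
      jsonlite::write_json(
        list(core = unname(apply(roi$core, 1, as.numeric, simplify = FALSE)),
             outer = unname(apply(roi$outer, 1, as.numeric,
                                  simplify = FALSE)),
             margin_mm = roi$margin_mm),
        file.path(pd, sprintf("roi%02d.json", i)), digits = NA)
    }
  }
  invisible(dir)
}
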