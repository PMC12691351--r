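#!/usr/bin/env Rscript
# Build the five QUS spectral parametric maps (MBF, SS, SI, ASD, AAC) for
# every cohort frame: sliding-window averaged spectra, attenuation
# correction (spectral-difference tumor estimate; no skin layer is simulated
# so none is compensated), reference-phantom BSC normalization, and Gaussian
# form-factor inversion. Prints per-class map summaries showing the planted
# margin contrast.
#
# Desk-scale choice: 50% window overlap for the map grid (the protocol's 94%
# yields a 0.12 mm grid and ~20x more windows; the grid identity is checked
# in the tests, the coarser grid keeps this driver fast).

library(qusrad)

st <- readRDS("scratch/cohort.rds")
cfg <- spectral_config(overlap_fraction = 0.5, skin_thickness_cm = 0)
refspec <- reference_spectrum(st$reference, cfg)

message("building parametric maps for 31 frames ...")
t0 <- Sys.time()
maps_per_patient <- lapply(seq_along(st$cohort), function(i) {
  pat <- st$cohort[[i]]
  lapply(seq_along(pat$frames), function(j) {
    build_parametric_maps(pat$frames[[j]], pat$rois[[j]], refspec, cfg)
  })
})
message(sprintf("  done in %.1f min", as.numeric(Sys.time() - t0, "mins")))

labels <- vapply(st$cohort, function(p) p$record$label, integer(1))
marg_aac <- vapply(maps_per_patient, function(ms) {
  stats::median(ms[[1]]$channels$AAC[ms[[1]]$margin_mask], na.rm = TRUE)
}, numeric(1))
alpha_est <- vapply(maps_per_patient, function(ms) ms[[1]]$alpha_tumor,
                    numeric(1))
message(sprintf("  margin AAC median: low-risk %.2f dB, high-risk %.2f dB (planted delta +3 dB)",
                stats::median(marg_aac[labels == 0]),
                stats::median(marg_aac[labels == 1])))
message(sprintf("  tumor attenuation estimates: median %.3f dB/cm/MHz (planted 0)",
                stats::median(alpha_est)))

saveRDS(maps_per_patient, "scratch/maps.rds")
message("wrote scratch/maps.rds")
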