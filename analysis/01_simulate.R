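#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Simulates (a) a 191-patient cohort (101 training / 90 validation, mirroring
# the D1/D2 split sizes) with class-conditional NE features, survival,
# stromal measurements and clinical covariates, and (b) one three-phase CT
# phantom per delta class, written as NIfTI volumes so stage 2 can exercise
# the image-domain quantification path.

suppressPackageStartupMessages(library(qdelta))

seed <- 1L
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

message("Simulating cohort (n = 191, prevalence of high delta 0.43) ...")
sim <- simulate_cohort(cohort_params(n_patients = 191, seed = seed))
write.csv(sim$cohort, file.path(outdir, "cohort.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(outdir, "cohort_truth.csv"), row.names = FALSE)
message("  classes: ", sum(sim$cohort$delta_label == "high"), " high / ",
        sum(sim$cohort$delta_label == "low"), " low")

message("Simulating one phantom per delta class (40^3 voxels, 1.25 mm) ...")
for (cls in c("high", "low")) {
  ph <- simulate_phantom(phantom_params(
    grid_shape = c(40, 40, 40), voxel_spacing_mm = 1.25,
    tumor_radius_mm = 8, class_label = cls,
    seed = seed + match(cls, c("high", "low"))))
  pdir <- file.path(outdir, "phantoms", cls)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  sp <- ph$study$spacing_mm
  write_volume(ph$study$nc, file.path(pdir, "nc.nii"), sp)
  write_volume(ph$study$ar, file.path(pdir, "ar.nii"), sp)
  write_volume(ph$study$pv, file.path(pdir, "pv.nii"), sp)
  write_volume(ph$masks$tumor, file.path(pdir, "tumor_mask.nii"), sp)
  write_volume(ph$masks$npp, file.path(pdir, "npp_mask.nii"), sp)
  write_volume(ph$masks$aaf, file.path(pdir, "aaf_mask.nii"), sp)
  message("  ", cls, ": tumor ", sum(ph$masks$tumor), " voxels")
}
message("Done; inputs under ", outdir, "/")
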