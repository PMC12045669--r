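#!/usr/bin/env Rscript
# Cohort summary tables and the regional distribution read-outs: slice-wise
# Gd-quantity profiles (ventral-dorsal and right-left), area profiles, and
# maximum intensity projections of the concentration map.

suppressPackageStartupMessages(library(lungsurf))

reports <- readRDS("scratch/cohort/reports.rds")
cohort <- run_cohort(reports)
write.csv(cohort, "results/cohort_summary.csv", row.names = FALSE)
message("cohort summary (mean / SD / CoV per metric):")
print(cohort, digits = 4)

# distribution profiles of the first specimen
ds <- readRDS("scratch/cohort/specimen_1.rds")
run <- run_specimen(dataset = ds, specimen = "1")
sp <- ds$spec$spacing

for (ax in c("ventral-dorsal", "right-left")) {
  prof <- slice_profile(run$concentration, ds$truth_labels, sp, ax,
                        "quantity")
  out <- sprintf("results/profile_quantity_%s.csv", gsub("-", "_", ax))
  write.csv(prof, out, row.names = FALSE)
  half <- floor(nrow(prof) / 2)
  message(sprintf(
    "%s profile: first-half PER %.1f umol vs second-half %.1f umol -> %s",
    ax, sum(prof$PER[seq_len(half)]), sum(prof$PER[-seq_len(half)]), out))
}
area <- slice_profile(NULL, ds$truth_labels, sp, "ventral-dorsal", "area")
write.csv(area, "results/profile_area_ventral_dorsal.csv", row.names = FALSE)

# MIPs of the concentration map (front view of the thorax)
cm <- run$concentration$concentration
cm$data[is.na(cm$data)] <- 0
cm$data <- pmax(cm$data, 0)
mip <- mip_render(cm, "ventral-dorsal")
write.csv(as.data.frame(unclass(mip)), "scratch/mip_concentration.csv",
          row.names = FALSE)
if (requireNamespace("png", quietly = TRUE)) {
  img <- t(mip[, rev(seq_len(ncol(mip)))]) / max(mip)
  png::writePNG(img, "scratch/mip_concentration.png")
  message("wrote scratch/mip_concentration.png (MIP, front view)")
}
message(sprintf(
  "dorsal half of PER carries %.0f%% of the peripheral Gd (dependent-region pooling)",
  100 * sum(slice_profile(run$concentration, ds$truth_labels, sp,
                          "ventral-dorsal", "quantity")$PER[
            -seq_len(floor(dim(ds$post_volume$data)[2] / 2))]) /
    gd_amount(run$concentration, ds$truth_labels, sp, "PER")))
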