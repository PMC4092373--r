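#!/usr/bin/env Rscript
# Generate the synthetic study data: the DPV fixture registry (noise-free
# and at default noise), the FMN titration series, and the chronoamperometry
# trace set for the enhancement panels. Everything downstream reads these
# files, so this script is the single source of the simulated measurements.

suppressPackageStartupMessages(library(dpvkit))
set.seed(1)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- voltammogram fixtures")
for (nm in names(dpv_fixture_registry())) {
  for (noise in c(0, NA)) {  # NA = generator default (0.5% of max peak)
    v <- if (is.na(noise)) make_dpv_fixture(nm, seed = 1)
         else make_dpv_fixture(nm, noise_sd = noise, seed = 1)
    tag <- if (is.na(noise)) "noisy" else "clean"
    v$metadata$truth$baseline <- NULL  # keep files small; peaks table kept
    v$metadata$truth$peaks <- NULL
    write_voltammogram(v, file.path(out, sprintf("dpv_%s_%s.csv", nm, tag)))
  }
}

message("-- titration series (Kd 10 uM; 52 uM point calibrated to 7 uA cm-2)")
tt <- make_titration(seed = 1)            # 5% magnitude noise
tt0 <- make_titration(noise_frac = 0)
write_titration(tt, file.path(out, "titration_default.csv"))
write_titration(tt0, file.path(out, "titration_noisefree.csv"))
write_voltammogram(tt0$voltammograms[["52"]],
                   file.path(out, "dpv_titration_52uM_noisefree.csv"))

message("-- chronoamperometry traces")
grid <- expand.grid(flavin = c("FMN", "RF"),
                    potential = c(-0.2, 0.4, 0.8), stringsAsFactors = FALSE)
for (i in seq_len(nrow(grid))) {
  ev <- flavin_addition(40 * 3600, grid$flavin[i], 2)
  tr <- make_current_trace("WT", grid$flavin[i], 2, grid$potential[i], 7.8,
                           events = list(ev), seed = i)
  write_current_trace(tr, file.path(out, sprintf(
    "trace_WT_%s_%+.1fV.csv", grid$flavin[i], grid$potential[i])))
}
for (strain in c("dOmcA", "dMtrC")) for (fl in c("none", "RF", "FMN")) {
  tr <- make_current_trace(strain, fl, if (fl == "none") 0 else 2,
                           0.4, 7.8, seed = 1)
  write_current_trace(tr, file.path(out, sprintf("trace_%s_%s.csv",
                                                 strain, fl)))
}

message("wrote ", length(list.files(out)), " files under ", out)
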