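#!/usr/bin/env Rscript
# Generate the synthetic study inputs every later stage consumes:
# per-visit stethoscope WAVs whose band amplitudes encode a known HLPR,
# per-patient wall-shear-stress fields with known oscillatory fractions,
# and the Doppler-ultrasound measurement table. Everything is a pure
# function of the seed; a manifest ties the files to patient-visits.

suppressMessages(library(avfsound))
seed <- 101
set.seed(seed)

out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

co <- gen_cohort(seed = seed)        # study shape: 6 patients x 6 visits
write.csv(co$records, file.path(out, "cohort_truth.csv"), row.names = FALSE)

manifest <- list()
for (i in seq_len(nrow(co$records))) {
  r <- co$records[i, ]
  # tone pair encodes the cohort HLPR; the low-band amplitude L is chosen
  # so the analyzed maximum peak equals the cohort's amplitude outcome
  # (the raised-cosine envelope, depth 0.3, scales peaks by its mean 0.85)
  L <- r$max_peak_amplitude / (0.85 * max(1, r$hlpr))
  rec <- gen_phonoangiogram(rbind(c(150, L), c(600, L * r$hlpr)),
                            noise_sd = 0.005, seed = seed + i,
                            label = paste(r$patient_id, r$visit))
  p <- file.path(out, sprintf("audio_%s_%s.wav", r$patient_id, r$visit))
  write_wav(rec, p, bits = 32)
  manifest[[length(manifest) + 1]] <-
    data.frame(kind = "audio", path = p,
               patient_id = r$patient_id, visit = r$visit)
}

# one WSS field per patient-visit of the first three visits, oscillatory
# fraction tied to that visit's HLPR so OSI and sound co-vary
wss_rows <- co$records[co$records$visit %in% c("3d", "3w", "3m"), ]
for (i in seq_len(nrow(wss_rows))) {
  r <- wss_rows[i, ]
  frac <- min(max(r$hlpr / 1.5, 0), 1)
  g <- gen_wss_field(400, n_timesteps = 100, fraction_oscillatory = frac,
                     seed = seed + 1000 + i)
  p <- file.path(out, sprintf("wss_%s_%s.csv", r$patient_id, r$visit))
  write_wss_csv(g$field, p)
  manifest[[length(manifest) + 1]] <-
    data.frame(kind = "wss", path = p,
               patient_id = r$patient_id, visit = r$visit)
}

# ultrasound axes/velocities chosen so the brachial BFV equals the
# cohort's generating BFV (circular 5 mm lumen: v = BFV / (CSA * 60))
us <- do.call(rbind, lapply(seq_len(nrow(co$records)), function(i) {
  r <- co$records[i, ]
  csa_ba <- cross_sectional_area(5, 5)
  rbind(
    data.frame(patient_id = r$patient_id, visit = r$visit, vessel = "BA",
               short_axis_mm = 5, long_axis_mm = 5,
               tav_velocity_cm_s = r$brachial_bfv_ml_min / (csa_ba * 60)),
    data.frame(patient_id = r$patient_id, visit = r$visit, vessel = "PA",
               short_axis_mm = 4, long_axis_mm = 4.4,
               tav_velocity_cm_s = runif(1, 30, 70)),
    data.frame(patient_id = r$patient_id, visit = r$visit, vessel = "DA",
               short_axis_mm = 3, long_axis_mm = 3.3,
               tav_velocity_cm_s = runif(1, 10, 40)))
}))
write.csv(us, file.path(out, "us.csv"), row.names = FALSE)
manifest[[length(manifest) + 1]] <-
  data.frame(kind = "us", path = file.path(out, "us.csv"),
             patient_id = "", visit = "")

manifest <- do.call(rbind, manifest)
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

cat(sprintf("Simulated %d audio recordings, %d WSS fields and %d US rows\n",
            sum(manifest$kind == "audio"), sum(manifest$kind == "wss"),
            nrow(us)))
cat("Manifest written to", file.path(out, "manifest.csv"), "\n")
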