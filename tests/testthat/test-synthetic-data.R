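test_that("phonoangiogram generation is seed-deterministic and band-faithful", {
  comps <- rbind(c(150, 1.0))
  # single pure tone, no noise/modulation: low peak at 150 Hz, amplitude ~1
  rec <- gen_phonoangiogram(comps, modulation_depth = 0, noise_sd = 0)
  expect_gte(duration(rec), 5)
  feats <- analyze_recording(rec)
  expect_equal(feats$low_peak_hz, 150)
  expect_equal(feats$low_peak_amp, 1.0, tolerance = 0.01)
  # two tones: the whole chain recovers HLPR = H/L within 5%
  two <- gen_phonoangiogram(rbind(c(150, 0.8), c(600, 0.4)),
                            noise_sd = 0.01, seed = 8)
  expect_equal(analyze_recording(two)$hlpr, 0.5, tolerance = 0.05)
  # same seed -> bit-identical waveform
  a <- gen_phonoangiogram(comps, noise_sd = 0.2, seed = 9)
  b <- gen_phonoangiogram(comps, noise_sd = 0.2, seed = 9)
  expect_identical(a$samples, b$samples)
  expect_error(gen_phonoangiogram(rbind(c(3000, 1)), sample_rate = 4000),
               "Nyquist")
  expect_error(gen_phonoangiogram(comps, noise_sd = 0.1), "seed")
})

test_that("generated WSS fields carry their reference OSI", {
  g <- gen_wss_field(300, seed = 10)
  osi <- compute_osi(g$field)
  expect_lt(max(abs(osi$osi - g$reference_osi)), 1e-3)
  # fraction 0 -> no high-OSI area; fraction 1 -> all of it
  g0 <- gen_wss_field(50, fraction_oscillatory = 0, seed = 11)
  expect_equal(high_osi_area_percent(compute_osi(g0$field), g0$field), 0)
  g1 <- gen_wss_field(50, fraction_oscillatory = 1, seed = 12)
  expect_equal(high_osi_area_percent(compute_osi(g1$field), g1$field), 100)
  # fraction 0.5: area percent near 50 within sampling error
  gh <- gen_wss_field(2000, fraction_oscillatory = 0.5, seed = 13)
  pct <- high_osi_area_percent(compute_osi(gh$field), gh$field)
  expect_gt(pct, 45); expect_lt(pct, 55)
  # same seed reproduces the same field
  r1 <- gen_wss_field(20, seed = 14); r2 <- gen_wss_field(20, seed = 14)
  expect_identical(r1$field$tau, r2$field$tau)
})

test_that("cohort generation has the specified linear and variance structure", {
  # no noise at all: the slope is recovered exactly
  co0 <- gen_cohort(patient_sd = 0, residual_sd = 0, seed = 15)
  fit <- fit_random_intercept_model(co0$records$max_peak_amplitude,
                                    co0$records$brachial_bfv_ml_min,
                                    co0$records$patient_id,
                                    n_boot = 20, seed = 1)
  expect_equal(fit$slope, co0$truth$slope, tolerance = 1e-6)
  # determinism
  c1 <- gen_cohort(seed = 16); c2 <- gen_cohort(seed = 16)
  expect_identical(c1$records, c2$records)
  # empirical variance components approach the targets at large n
  big <- gen_cohort(n_patients = 200, visits_per_patient = 6, seed = 17)
  fit_big <- fit_random_intercept_model(big$records$max_peak_amplitude,
                                        big$records$brachial_bfv_ml_min,
                                        big$records$patient_id,
                                        n_boot = 2, seed = 1)
  expect_equal(fit_big$patient_intercept_sd, 14.97, tolerance = 0.1)
  expect_equal(fit_big$residual_sd, 31.05, tolerance = 0.1)
  # HLPR deltas couple negatively to BFV deltas
  d <- longitudinal_deltas(big$records)
  expect_equal(unname(coef(lm(d$delta_hlpr ~ d$delta_bfv))[2]),
               big$truth$hlpr_coupling, tolerance = 0.1)
})

test_that("the published fixture is intact", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 12)
  expect_equal(sort(unique(t1$patient_id)), c("P1", "P2", "P3", "P4"))
  expect_equal(sort(unique(t1$visit)), c("1y", "3d", "3w"))
  # frozen checksums guard against silent edits
  expect_equal(sum(t1$hlpr), 6.33, tolerance = 1e-9)
  expect_equal(sum(t1$osi_area_percent), 247.75, tolerance = 1e-9)
  # spot values
  expect_equal(t1$hlpr[t1$patient_id == "P3" & t1$visit == "1y"], 0.49)
  expect_equal(t1$osi_area_percent[t1$patient_id == "P3" & t1$visit == "1y"],
               34.09)
  expect_equal(t1$hlpr[t1$patient_id == "P2" & t1$visit == "3d"], 0.18)
  expect_equal(t1$osi_area_percent[t1$patient_id == "P2" & t1$visit == "3d"],
               0.71)
  expect_equal(t1$hlpr[t1$patient_id == "P4" & t1$visit == "1y"], 0.75)
})
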