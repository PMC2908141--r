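test_that("templates have the stated extremum, baseline and band-pass survival", {
  tpl <- make_template(100, 1, "negative", window = 64)
  expect_equal(min(tpl$waveform), -100)
  expect_equal(max(abs(tpl$waveform)), 100)
  expect_lte(max(abs(tpl$waveform[c(1, 64)])), 1)

  pos <- make_template(40, 0.5, "positive")
  expect_equal(max(pos$waveform), 40)

  expect_error(make_template(0, 1, "negative"), "invalid template")
  expect_error(make_template(-5, 1, "negative"), "invalid template")
  expect_error(make_template(100, 2.0, "negative", window = 64),
               "width too large")

  # oracle: the implemented band-pass applied to an embedded template
  fs <- 20000
  for (w in c(0.3, 0.5, 1.0)) {
    tpl <- make_template(100, w, "negative", fs = fs)
    tr <- numeric(fs)
    tr[9969:10032] <- tpl$waveform
    filt <- bandpass_trace(tr, fs)
    expect_gte(max(abs(filt)) / 100, 0.70)
  }
})

test_that("template library spans 8-15x noise SD with distinct shapes", {
  tpls <- template_library(7, noise_sd_uv = 5)
  peaks <- vapply(tpls, function(t) max(abs(t$waveform)), numeric(1))
  expect_true(all(peaks / 5 >= 8))
  expect_true(all(peaks / 5 <= 15))
  expect_equal(length(unique(round(peaks, 6))), 7)
  expect_error(template_library(8), "1..7")
})

test_that("refractory Poisson trains have the stated effective rate and hard dead time", {
  expect_identical(simulate_spike_train(0, 50), numeric(0))
  expect_error(simulate_spike_train(-1, 50), "invalid parameter")
  expect_error(simulate_spike_train(600, 50, refractory_ms = 2),
               "not realizable")

  set.seed(42)
  counts <- replicate(1000, length(simulate_spike_train(6, 50, refractory_ms = 2)))
  se <- sd(counts) / sqrt(length(counts))
  # rate is the effective rate: expected count = 6 * 50 = 300
  expect_lt(abs(mean(counts) - 300), 3 * se)

  set.seed(7)
  for (i in 1:20) {
    st <- simulate_spike_train(40, 5, refractory_ms = 2)
    if (length(st) > 1) expect_gte(min(diff(st)), 0.002)
    expect_true(all(st >= 0 & st <= 5))
    expect_false(is.unsorted(st))
  }
})

test_that("condition presets carry the reported group statistics", {
  p <- build_preset("control", "basal")
  expect_equal(p$n_active_electrodes, 15L)
  expect_equal(p$units_per_active_electrode, 5L)
  expect_equal(p$aggregate_rate_hz, 6.08)

  expect_equal(build_preset("SMA", "basal")$n_active_electrodes, 6L)
  expect_equal(build_preset("SMA", "basal")$aggregate_rate_hz, 5.48)
  expect_equal(build_preset("control", "serotonin")$n_active_electrodes, 25L)
  expect_equal(build_preset("control", "serotonin")$aggregate_rate_hz, 10.20)
  expect_equal(build_preset("SMA", "serotonin")$n_active_electrodes, 11L)
  expect_equal(build_preset("control", "GABA")$aggregate_rate_hz, 5.74)
  expect_equal(build_preset("SMA", "bicuculline")$aggregate_rate_hz, 6.18)

  expect_error(build_preset("mutant", "basal"), "unknown condition")
  expect_error(build_preset("control", "ketamine"), "unknown condition")

  # every preset realizable on the default mask, active sites >= 1 Hz,
  # background below criterion
  mask_n <- length(default_ventral_mask())
  for (g in c("control", "SMA"))
    for (d in c("basal", "serotonin", "acetylcholine", "bicuculline", "GABA")) {
      p <- build_preset(g, d)
      expect_lte(p$n_active_electrodes, mask_n)
      expect_gte(p$aggregate_rate_hz, 1)
      expect_lt(p$inactive_rate_hz, 1)
    }
})

test_that("geometry validates its tissue mask", {
  g <- array_geometry()
  expect_equal(g$n_electrodes, 64L)
  expect_equal(length(g$ventral_horn_mask), 36L)
  expect_error(array_geometry(ventral_horn_mask = integer(0)), "non-empty")
  expect_error(array_geometry(ventral_horn_mask = c(1, 65)), "1..64")
})

test_that("silent render is exactly zero and pure noise has the configured SD", {
  geom <- array_geometry()
  silent <- build_preset("control", "basal")
  silent$n_active_electrodes <- 0L
  silent$inactive_rate_hz <- 0

  rec <- render_recording(geom, silent,
                          noise_model(sd_uv = 0, drift_amplitude_uv = 0,
                                      ramp_uv = 0),
                          duration_s = 1, seed = 1)
  expect_true(all(rec$segment$samples == 0))

  rec <- render_recording(geom, silent,
                          noise_model(sd_uv = 5, drift_amplitude_uv = 0,
                                      ramp_uv = 0),
                          duration_s = 2, seed = 2)
  sds <- apply(rec$segment$samples, 2, sd)
  expect_true(all(abs(sds - 5) / 5 < 0.02))
})

test_that("noise-free render reconstructs exactly from the ground truth", {
  geom <- array_geometry(ventral_horn_mask = 1:25)
  p <- build_preset("control", "basal")
  p$n_active_electrodes <- 1L
  p$units_per_active_electrode <- 1L
  p$aggregate_rate_hz <- 30     # dense train in a short segment
  p$inactive_rate_hz <- 0
  fs <- 20000
  rec <- render_recording(geom, p,
                          noise_model(sd_uv = 0, drift_amplitude_uv = 0,
                                      ramp_uv = 0),
                          duration_s = 2, fs = fs, seed = 3, jitter_sd = 0)
  e <- rec$truth$active_sites
  tpl <- rec$truth$templates[[1]]
  st <- rec$truth$units[[e]][[1]]$spike_times
  expect_gt(length(st), 0)
  recon <- numeric(nrow(rec$segment$samples))
  for (t_sp in st) {
    pk <- round(t_sp * fs) + 1L
    lo <- pk - (tpl$peak_index - 1L); hi <- lo + 63L
    if (lo >= 1 && hi <= length(recon))
      recon[lo:hi] <- recon[lo:hi] + tpl$waveform
  }
  expect_equal(rec$segment$samples[, e], recon, tolerance = 1e-12)
})

test_that("rendering is deterministic and honours the activity criterion by construction", {
  geom <- array_geometry()
  p <- build_preset("SMA", "basal")
  r1 <- render_recording(geom, p, duration_s = 5, seed = 11)
  r2 <- render_recording(geom, p, duration_s = 5, seed = 11)
  expect_identical(r1$segment$samples, r2$segment$samples)
  expect_identical(r1$truth$active_sites, r2$truth$active_sites)

  r3 <- render_recording(geom, p, duration_s = 5, seed = 12)
  expect_false(identical(r1$segment$samples, r3$segment$samples))

  # planted counts: active sites meet the (pro-rated) criterion, others don't
  crit <- 50 * 5 / 50
  for (e in geom$ventral_horn_mask) {
    cnt <- truth_spike_count(r1$truth, e)
    if (e %in% r1$truth$active_sites) expect_gte(cnt, crit)
    else expect_lt(cnt, crit)
  }

  # conservation: per-electrode truth counts sum to the total
  total <- truth_spike_count(r1$truth)
  by_el <- sum(vapply(seq_len(64), function(e) truth_spike_count(r1$truth, e),
                      integer(1)))
  expect_identical(total, by_el)
})

test_that("a preset larger than the tissue mask is a capacity error", {
  geom <- array_geometry(ventral_horn_mask = 1:10)
  p <- build_preset("control", "serotonin")  # wants 25 sites
  expect_error(render_recording(geom, p, duration_s = 1, seed = 1),
               "capacity")
})
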