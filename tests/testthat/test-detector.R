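# Two-stage detector: filtering, event detection, segmentation, features,
# candidate retention.

test_that("bandpass passes 50 kHz and rejects 1 kHz tones", {
  t <- seq(0, 0.05, by = 1 / FS)
  rms <- function(x) sqrt(mean(x^2))
  mid <- 2001:8000  # avoid filter edge transients
  tone50 <- sin(2 * pi * 50000 * t)
  out50 <- bandpass(tone50, FS)
  expect_lt(abs(20 * log10(rms(out50[mid]) / rms(tone50[mid]))), 1)
  tone1 <- sin(2 * pi * 1000 * t)
  out1 <- bandpass(tone1, FS)
  expect_lt(20 * log10(rms(out1[mid]) / rms(tone1[mid])), -20)
  expect_equal(bandpass(numeric(1000), FS), numeric(1000))
})

test_that("band edges at or beyond Nyquist are a configuration error", {
  expect_error(bandpass(numeric(100), 8000, detector_config()), "Nyquist")
})

test_that("event detection thresholds at 118 dB and merges below 2.5 ms", {
  tpl <- probe_template()
  snip <- make_click_template(tpl, FS, probe_components(tpl))
  one_click <- function(db) {
    x <- place_clicks(round(0.1 * FS), scale_to_db(snip, db), 5000)
    detect_events(bandpass(x, FS), FS, CAL)
  }
  expect_equal(nrow(one_click(115)), 0)
  expect_gte(nrow(one_click(118)), 1)
  pair <- function(sep_ms) {
    i2 <- 5000 + length(snip) + round(sep_ms * 1e-3 * FS)
    x <- place_clicks(round(0.1 * FS), scale_to_db(snip, 125), c(5000, i2))
    nrow(detect_events(bandpass(x, FS), FS, CAL))
  }
  expect_equal(pair(2.0), 1)   # merged
  expect_equal(pair(10), 2)    # separate events
})

test_that("event lists are sorted, non-overlapping and padded", {
  set.seed(12)
  tpl <- probe_template()
  snip <- scale_to_db(make_click_template(tpl, FS, probe_components(tpl)), 125)
  for (rep in 1:5) {
    onsets <- sort(sample(2000:(FS / 2), 8))
    onsets <- onsets[c(TRUE, diff(onsets) > 3 * length(snip))]
    x <- place_clicks(round(0.6 * FS), snip, onsets,
                      noise_sd = db_to_p2p(75, CAL) / 7)
    ev <- detect_events(bandpass(x, FS), FS, CAL)
    expect_false(is.unsorted(ev$start_s, strictly = TRUE))
    if (nrow(ev) > 1) expect_true(all(diff(ev$start_idx) > 0) &&
                                    all(ev$end_idx[-nrow(ev)] < ev$start_idx[-1]))
    expect_true(all(ev$end_idx - ev$start_idx >= 2 * 0.0025 * FS * 0.9))
  }
})

test_that("segmentation isolates, merges below 100 us, and drops clipped clicks", {
  tpl <- probe_template()
  snip <- make_click_template(tpl, FS, probe_components(tpl))
  scaled <- scale_to_db(snip, 125)
  n <- 4000
  # isolated click
  x <- place_clicks(n, scaled, 1800)
  b <- segment_clicks(x, FS, CAL)
  expect_equal(nrow(b), 1)
  peak_sample <- 1800 + (length(snip) - 1) / 2
  expect_true(b[1, "start"] <= peak_sample && b[1, "end"] >= peak_sample)
  # pair 50 us apart -> merged
  i2 <- 1800 + length(snip) + round(50e-6 * FS)
  x2 <- place_clicks(n, scaled, c(1800, i2))
  expect_equal(nrow(segment_clicks(x2, FS, CAL)), 1)
  # pair 500 us apart -> two
  i3 <- 1800 + length(snip) + round(500e-6 * FS)
  x3 <- place_clicks(n, scaled, c(1800, i3))
  expect_equal(nrow(segment_clicks(x3, FS, CAL)), 2)
  # clipped click discarded
  xc <- place_clicks(n, snip * 1.2, 1800)
  expect_equal(nrow(segment_clicks(pmin(1, pmax(-1, xc)), FS, CAL)), 0)
  # degenerate event: constant samples
  expect_equal(nrow(segment_clicks(rep(0.5, 500), FS, CAL)), 0)
})

test_that("segmentation matches the literal brute-force oracle on random events", {
  set.seed(77)
  tpl <- probe_template()
  snip <- make_click_template(tpl, FS, probe_components(tpl))
  mismatches <- 0
  for (rep in 1:100) {
    n <- 3000
    k <- sample(1:3, 1)
    onsets <- sort(sample(seq(200, n - length(snip) - 200, by = 7), k))
    levels <- runif(k, 119, 129)
    x <- rnorm(n, sd = db_to_p2p(runif(1, 70, 90), CAL) / 7)
    for (j in seq_len(k)) {
      i0 <- onsets[j]
      x[i0:(i0 + length(snip) - 1)] <-
        x[i0:(i0 + length(snip) - 1)] + scale_to_db(snip, levels[j])
    }
    pp <- sliding_p2p(x, FS)
    got <- segment_clicks(x, FS, CAL, p2p = pp)
    want <- segment_oracle(pp, smoothed_energy(x, FS), x, FS)
    same <- nrow(got) == nrow(want) &&
      all(as.numeric(got) == as.numeric(want))
    if (!same) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("click features have 500 Hz resolution and recover a pure Gabor", {
  tpl <- probe_template(peak_khz = 40, bw_khz = 10, duration_us = 300)
  snip <- make_click_template(tpl, FS, probe_components(tpl))
  f <- click_features(snip, FS, CAL)
  expect_length(f$spectrum_db, 200)
  expect_equal(f$peak_freq_khz, 40.0)
  expect_length(f$envelope, 200)
  # envelope peaks near the center for a symmetric click
  expect_lt(abs(which.max(f$envelope) - 100), 15)
})

test_that("Gg-template clicks recover the catalog bandwidth in noise", {
  set.seed(41)
  snip <- make_click_template("Gg", FS)
  bws <- vapply(seq_len(200), function(i) {
    x <- scale_to_db(snip, 125) + rnorm(length(snip),
                                        sd = db_to_p2p(80, CAL) / 7)
    click_features(x, FS, CAL)$bw3db_khz
  }, numeric(1))
  expect_lte(abs(median(bws) - 4.5), 1)
})

test_that("candidate filtering discards by peak frequency and duration with reasons", {
  low <- probe_template(peak_khz = 4, bw_khz = 2, duration_us = 300)
  snip_low <- make_click_template(low, FS, probe_components(low))
  rec_low <- click_features(snip_low, FS, CAL)
  rec_gg <- click_features(make_click_template("Gg", FS), FS, CAL)
  # 5 ms narrowband ping
  ping <- sin(2 * pi * 25000 * seq(0, 5e-3, by = 1 / FS)) *
    sin(pi * seq(0, 1, length.out = 5e-3 * FS + 1))
  rec_ping <- click_features(ping, FS, CAL)
  cs <- click_set(list(rec_low, rec_gg, rec_ping), FS, CAL)
  fc <- filter_candidates(cs)
  expect_equal(fc$reason, c("low_peak_freq", "keep", "duration"))
  expect_equal(nrow(fc$kept$clicks), 1)
  expect_equal(fc$discarded$reason, c("low_peak_freq", "duration"))
})

test_that("detector recalls >=99% of loud clicks and keeps time accuracy", {
  spec <- scene_spec(duration_s = 16, seed = 8, noise_floor_db = 75, bouts = list(
    list(template = "Gg", start_s = 0.5, n_clicks = 40, rl_db_pp = 125),
    list(template = "UD28", start_s = 8, n_clicks = 60, rl_db_pp = 122)))
  sc <- synth_scene(spec, CAL)
  det <- detect_clicks(sc$wave, sc$fs_hz, CAL)
  matched <- vapply(sc$truth$click_time_s, function(tt)
    any(abs(det$clicks$clicks$peak_s - tt) < 1e-3), logical(1))
  expect_gte(mean(matched), 0.99)
})

test_that("a sonar ping train produces events but no retained click-type candidates", {
  spec <- scene_spec(duration_s = 4, seed = 13, confounders = list(
    list(kind = "sonar", start_s = 0.5, freq_khz = 25, duration_ms = 5,
         rl_db_pp = 130, n_pings = 3, ping_interval_s = 1)))
  sc <- synth_scene(spec, CAL)
  det <- detect_clicks(sc$wave, sc$fs_hz, CAL)
  expect_gte(nrow(det$events), 3)
  expect_equal(nrow(det$clicks$clicks), 0)
  expect_true(all(det$discarded$reason == "duration"))
})
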