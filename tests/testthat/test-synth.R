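# Synthetic soundscape generator: calibration, templates, trains, scenes.

test_that("calibration round-trips within 0.01 dB", {
  cal <- calibration(140)
  for (db in seq(100, 135, by = 2.5)) {
    expect_lt(abs(p2p_to_db(db_to_p2p(db, cal), cal) - db), 0.01)
  }
})

test_that("every catalog template synthesizes with its nominal peak frequency", {
  cal <- calibration(140)
  tpl <- click_type_templates()
  for (nm in tpl$name) {
    f <- click_features(make_click_template(nm, 200000), 200000, cal)
    expect_lte(abs(f$peak_freq_khz - tpl$peak_freq_khz[tpl$name == nm]),
               0.5, label = paste(nm, "peak frequency"))
  }
})

test_that("template bandwidth is recovered within 1 kHz (dense-FFT oracle)", {
  # independent oracle: 16x zero-padded plain FFT of the raw snippet
  bw_oracle <- function(snippet, fs) {
    nfft <- 16 * 400
    X <- abs(fft(c(snippet, numeric(nfft - length(snippet)))))
    half <- X[seq_len(nfft / 2)]
    pk <- which.max(half)
    lim <- half[pk] / 10^(3 / 20)
    lo <- pk
    while (lo > 1 && half[lo - 1] >= lim) lo <- lo - 1
    hi <- pk
    while (hi < length(half) && half[hi + 1] >= lim) hi <- hi + 1
    (hi - lo + 1) * fs / nfft / 1000
  }
  tpl <- click_type_templates()
  for (nm in c("Gg", "Mb", "UD28", "Pm", "Zc")) {
    snip <- make_click_template(nm, 200000)
    want <- tpl$bw3db_khz[tpl$name == nm]
    expect_lte(abs(bw_oracle(snip, 200000) - want), 1,
               label = paste(nm, "-3dB bandwidth"))
  }
})

test_that("peak frequency at half-Nyquist lands on bin 100 of 200", {
  tpl <- probe_template(peak_khz = 50, bw_khz = 8, duration_us = 200)
  snip <- make_click_template(tpl, 200000, probe_components(tpl))
  f <- click_features(snip, 200000, CAL)
  expect_equal(which.max(f$spectrum_db) - 1L, 100L)
  expect_length(f$spectrum_db, 200L)
})

test_that("templates above Nyquist are rejected, near-Nyquist Kogia allowed", {
  expect_error(make_click_template("Kogia", 150000), "Nyquist")
  expect_silent(make_click_template("Kogia", 200000))
  bad <- probe_template()
  bad$duration_us <- 0
  expect_error(make_click_template(bad, 200000), "duration")
})

test_that("zero-jitter trains have exactly modal inter-click intervals", {
  tr <- synth_click_train("UD28", 100, 120, cal = CAL, fs_hz = FS,
                          seed = 1, ici_jitter_cv = 0)
  ici <- diff(tr$truth$click_time_s)
  expect_length(ici, 99)
  expect_true(all(abs(ici - 0.075) < 1e-5))  # onset rounding to samples
})

test_that("jittered UD28 trains have histogram mode at the modal ICI", {
  set.seed(11)
  ici <- draw_icis(2000, 0.075, 0.15)
  expect_lt(abs(modal_ici(ici_histogram(ici)) - 0.075), 0.005 + 1e-9)
})

test_that("synthesized p2p levels match the requested level within 0.1 dB", {
  for (db in seq(110, 125, by = 5)) {
    tr <- synth_click_train("Gg", 1, db, cal = CAL, fs_hz = FS, seed = 1)
    measured <- p2p_to_db(max(tr$wave) - min(tr$wave), CAL)
    expect_lt(abs(measured - db), 0.1)
  }
})

test_that("clipping levels error unless clipping is requested", {
  expect_error(synth_click_train("Gg", 1, 150, cal = CAL, fs_hz = FS),
               "clip")
  tr <- synth_click_train("Gg", 1, 150, cal = CAL, fs_hz = FS,
                          allow_clipping = TRUE)
  expect_gt(max(abs(tr$wave)), 1)
})

test_that("scenes are bit-identical given the same spec and seed", {
  spec <- scene_spec(duration_s = 1, seed = 99,
                     bouts = list(list(template = "UD28", start_s = 0.2,
                                       n_clicks = 5, rl_db_pp = 123)),
                     confounders = list(list(kind = "shrimp",
                                             rate_per_s = 3, rl_db_pp = 119)))
  s1 <- synth_scene(spec, CAL)
  s2 <- synth_scene(spec, CAL)
  expect_identical(s1$wave, s2$wave)
  expect_identical(s1$truth, s2$truth)
  # and through 16-bit quantization
  p1 <- tempfile(fileext = ".wav"); p2 <- tempfile(fileext = ".wav")
  write_wav(s1$wave, p1, s1$fs_hz)
  write_wav(s2$wave, p2, s2$fs_hz)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("truth table row count equals the sum of bout click counts", {
  spec <- scene_spec(duration_s = 400, seed = 5, bouts = list(
    list(template = "Gg", start_s = 1, n_clicks = 12, rl_db_pp = 124),
    list(template = "UD28", start_s = 301, n_clicks = 20, rl_db_pp = 124)))
  sc <- synth_scene(spec, CAL)
  expect_equal(nrow(sc$truth), 32)
  expect_false(is.unsorted(sc$truth$click_time_s))
})

test_that("WAV files round-trip to 16-bit precision", {
  set.seed(2)
  x <- runif(5000, -0.9, 0.9)
  p <- tempfile(fileext = ".wav")
  write_wav(x, p, 200000)
  w <- read_wav(p)
  expect_equal(w$fs_hz, 200000)
  expect_equal(w$x, x, tolerance = 1 / 32767)
})

test_that("a pure-noise scene yields zero retained clicks", {
  sc <- synth_scene(scene_spec(duration_s = 1.5, seed = 21), CAL)
  det <- detect_clicks(sc$wave, sc$fs_hz, CAL)
  expect_equal(nrow(det$clicks$clicks), 0)
})

test_that("per-template median peak frequency holds over noisy level-varied clicks", {
  # spectral-fidelity invariant at reduced but informative scale
  set.seed(31)
  cal <- CAL
  for (nm in c("Gg", "Kogia", "Mb", "UD19")) {
    want <- get_template(nm)$peak_freq_khz
    snip <- make_click_template(nm, FS)
    meds <- vapply(seq_len(120), function(i) {
      x <- scale_to_db(snip, runif(1, 120, 130)) +
        rnorm(length(snip), sd = db_to_p2p(80, cal) / 7)
      click_features(x, FS, cal)$peak_freq_khz
    }, numeric(1))
    expect_lte(abs(median(meds) - want), 0.5, label = nm)
  }
})
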