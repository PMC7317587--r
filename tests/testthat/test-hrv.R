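test_that("R-peak detection recovers a constant-rate template train", {
  rr <- generate_rr_series(rr_gen_spec(duration_s = 300, mean_rr = 1000,
                                       lf_amp = 0, hf_amp = 0, noise_sd = 0))
  ecg <- generate_ecg(rr, fs = 1000, seed = 1)
  pk <- detect_r_peaks(ecg)
  expect_true(abs(length(pk$peak_times) - 300) <= 1)
  expect_lt(abs(mean(diff(pk$peak_times)) * 1000 - 1000), 2)
  expect_true(all(diff(pk$peak_times) >= 0.2))
})

test_that("R-peak detection recovers alternating intervals beat by beat", {
  rr_true <- rep(c(800, 900), 150)
  ecg <- generate_ecg(rr_true, fs = 1000, noise_sd = 0.02, seed = 2)
  pk <- detect_r_peaks(ecg)
  got <- diff(pk$peak_times) * 1000
  expect_equal(length(got), length(rr_true))
  expect_true(all(abs(got - rr_true) <= 10))
})

test_that("detection recall and precision reach 0.99 on clean ECG", {
  rr <- generate_rr_series(rr_gen_spec(mean_rr = 850, lf_amp = 40,
                                       hf_amp = 30, noise_sd = 25,
                                       seed = 3))
  ecg <- generate_ecg(rr, fs = 500, seed = 4)
  pk <- detect_r_peaks(ecg)
  d_true <- vapply(rr$beat_times,
                   function(bt) min(abs(pk$peak_times - bt)), numeric(1))
  d_det <- vapply(pk$peak_times,
                  function(pt) min(abs(rr$beat_times - pt)), numeric(1))
  expect_gte(mean(d_true < 0.05), 0.99)  # recall
  expect_gte(mean(d_det < 0.05), 0.99)   # precision
})

test_that("flatline and zero input raise a detection error", {
  expect_error(detect_r_peaks(rep(0, 20000), fs = 1000), "no QRS")
  expect_error(detect_r_peaks(rnorm(1000), fs = 1000), "10 s")
})

test_that("the 20% filter removes ectopic intervals sequentially", {
  nn <- clean_nn(c(800, 810, 1200, 805, 800))
  expect_equal(nn$removed, 3L)   # |1200 - 810| / 810 = 48% > 20%
  expect_equal(nn$intervals, c(800, 810, 805, 800))
  expect_error(clean_nn(c(800, 810, 1200, 805)), "too short")

  same <- clean_nn(rep(800, 100))
  expect_length(same$removed, 0)
  expect_equal(same$intervals, rep(800, 100))

  # 19% change sits inside the boundary
  ok <- clean_nn(c(1000, 1190, 1000, 1190))
  expect_length(ok$removed, 0)

  # physiological gate precedes the relative filter
  gated <- clean_nn(c(800, 810, 150, 805, 3500, 790))
  expect_true(all(c(3L, 5L) %in% gated$removed))
  expect_true(all(gated$intervals > 200 & gated$intervals < 3000))

  expect_error(clean_nn(c(800, 810)), "at least 4")
})

test_that("the 20% filter is idempotent and catches injected ectopics", {
  rr <- generate_rr_series(rr_gen_spec(noise_sd = 15, ectopic_rate = 0.05,
                                       seed = 5))
  nn1 <- clean_nn(rr)
  nn2 <- clean_nn(nn1$intervals, onset_times = nn1$onset_times)
  expect_length(nn2$removed, 0)
  expect_identical(nn2$intervals, nn1$intervals)
  # ground-truth ectopics are removed (their successors may also go)
  expect_true(all(which(rr$ectopic) %in% nn1$removed))
})

test_that("tachogram interpolation is exact on flats and lines", {
  const <- clean_nn(rep(1000, 100))
  tach <- interpolate_tachogram(const)
  expect_true(all(abs(tach$values - 1000) < 1e-9))

  ramp <- seq(800, 900, length.out = 200)
  nn <- clean_nn(ramp)
  tach2 <- interpolate_tachogram(nn)
  line <- approx(nn$onset_times, nn$intervals, xout = tach2$times)$y
  expect_true(all(abs(tach2$values - line) < 0.5))

  rr <- generate_rr_series(rr_gen_spec(noise_sd = 10, seed = 6))
  tach3 <- interpolate_tachogram(clean_nn(rr))
  expect_true(abs(length(tach3$values) - 1200) < 20)
  expect_lt(abs(mean(tach3$values) - mean(rr$intervals)) /
              mean(rr$intervals), 0.01)
})

test_that("AR band powers recover sinusoidal modulation (Parseval)", {
  fs <- 4
  tt <- seq(0, 300, by = 1 / fs)
  set.seed(7)
  hf_sig <- 50 * sin(2 * pi * 0.25 * tt) + rnorm(length(tt), 0, 5)
  sp <- ar_spectrum(hf_sig, fs_interp = fs)
  expect_lt(abs(sp$hf_power - 50^2 / 2) / (50^2 / 2), 0.10)
  expect_gt(sp$hf_power, 10 * sp$lf_power)

  lf_sig <- 50 * sin(2 * pi * 0.10 * tt) + rnorm(length(tt), 0, 5)
  sp2 <- ar_spectrum(lf_sig, fs_interp = fs)
  expect_gt(sp2$lf_power, 10 * sp2$hf_power)
})

test_that("AR total power tracks the series variance", {
  set.seed(8)
  x <- rnorm(1200, 0, 30)
  sp <- ar_spectrum(x, fs_interp = 4)
  expect_lt(abs(sp$total_power - var(x)) / var(x), 0.15)
})

test_that("white tachogram splits LF/HF in proportion to bandwidth", {
  set.seed(9)
  ratios <- replicate(10, {
    sp <- ar_spectrum(rnorm(1200, 0, 30), fs_interp = 4)
    sp$lf_power / sp$hf_power
  })
  expect_lt(abs(mean(ratios) - 0.11 / 0.25), 0.15)
})

test_that("degenerate tachograms raise errors", {
  expect_error(ar_spectrum(rep(1000, 500), fs_interp = 4), "degenerate")
  expect_error(ar_spectrum(rnorm(30), fs_interp = 4), "longer than")
})

test_that("time-domain summary matches hand enumeration", {
  td <- time_domain(c(800, 860, 870, 805, 810))
  expect_equal(td$pnn50, 50)
  expect_equal(td$rmssd, sqrt(mean(c(60, 10, 65, 5)^2)))
  expect_equal(td$rmssd, sqrt(1987.5))

  const <- time_domain(rep(1000, 301))
  expect_equal(const$sdnn, 0)
  expect_equal(const$sdnni, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$pnn50, 0)
  expect_equal(const$hr, 60)
})

test_that("RMSSD squared equals the mean squared successive difference", {
  set.seed(10)
  for (i in 1:5) {
    x <- 800 + rnorm(50, 0, 40)
    td <- time_domain(x)
    acc <- 0
    for (k in 2:length(x)) acc <- acc + (x[k] - x[k - 1])^2
    expect_equal(td$rmssd^2, acc / (length(x) - 1))
  }
})

test_that("SDNNi separates segment-level from global variability", {
  # six 50-s segments, each internally constant at a different level
  levels_ms <- c(500, 625, 500, 625, 500, 625)
  rr <- unlist(lapply(levels_ms, function(L) rep(L, 50000 / L)))
  td <- time_domain(rr)
  expect_equal(td$sdnni, 0)
  expect_gt(td$sdnn, 0)
})

test_that("measured HF power rises monotonically with injected amplitude", {
  amps <- seq(5, 50, length.out = 10)
  hf <- vapply(seq_along(amps), function(i) {
    rr <- generate_rr_series(rr_gen_spec(hf_amp = amps[i], lf_amp = 10,
                                         noise_sd = 10, seed = 100 + i))
    hrv_summary(rr)$HF
  }, numeric(1))
  expect_gt(cor(amps, hf, method = "spearman"), 0.9)
})

test_that("generator LF/HF ratio is recovered end to end", {
  ratios <- vapply(1:20, function(s) {
    rr <- generate_rr_series(rr_gen_spec(lf_amp = 40, hf_amp = 25,
                                         noise_sd = 8, seed = 200 + s))
    row <- hrv_summary(rr)
    row$LF / row$HF
  }, numeric(1))
  target <- 40^2 / 25^2
  expect_lt(abs(mean(ratios) - target) / target, 0.20)
})
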