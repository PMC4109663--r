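test_that("ERP template peaks where and how it is told to", {
  # zero amplitude -> zero waveform
  expect_equal(make_erp_template(peak_amplitude = 0)$waveform, numeric(200))
  # 500 ms at 200 Hz is 0-based sample 100, value equal to the peak amplitude
  tpl <- make_erp_template(peak_latency_ms = 500, peak_amplitude = 10, fwhm_ms = 200)
  expect_equal(which.max(tpl$waveform) - 1L, 100L)
  expect_equal(tpl$waveform[101], 10)
  # half maximum at half the FWHM from the peak
  expect_equal(tpl$waveform[101 + 100 / 5], 5, tolerance = 1e-12)
  # hard zero beyond three FWHM, soft decay towards the edges
  expect_true(all(tpl$waveform[seq_len(200) - 1 > (500 + 3 * 200) / 5] == 0))
  expect_lt(abs(tpl$waveform[1]), 0.05 * tpl$peak_amplitude)
  expect_error(make_erp_template(peak_latency_ms = 1200), "poststimulus window")
  expect_error(make_erp_template(peak_latency_ms = 0), "poststimulus window")
})

test_that("AR noise sampler reproduces AR(1) theory", {
  expect_error(noise_spec(ar_coeffs = 1.2), "stable")
  expect_equal(sample_ar_noise(white_spec(0), 50, seed = 1), numeric(50))
  x <- sample_ar_noise(ar1_spec(0.8, 1), 1e5, seed = 42)
  # theoretical lag-1 autocorrelation 0.8, variance 1/(1 - 0.64)
  expect_equal(cor(x[-1], x[-length(x)]), 0.8, tolerance = 0.01 / 0.8)
  expect_equal(var(x), 1 / (1 - 0.64), tolerance = 0.03)
})

test_that("generated noise spectrum matches the theoretical AR spectrum", {
  a <- c(1.0, -0.45, 0.15, -0.05)
  x <- sample_ar_noise(noise_spec(ar_coeffs = a, innovation_var = 1), 1e5, seed = 7)
  pg <- spec.pgram(ts(x, frequency = 1), taper = 0, plot = FALSE, detrend = FALSE)
  theory <- 1 / Mod(1 - sapply(pg$freq, function(f) {
    sum(a * exp(-2i * pi * f * seq_along(a)))
  }))^2
  bands <- cut(seq_along(pg$freq), 10)
  ratio <- tapply(pg$spec, bands, mean) / tapply(theory, bands, mean)
  expect_true(all(abs(ratio - 1) < 0.1))
})

test_that("epochs carry the requested SNR construction", {
  tpl <- make_erp_template()
  ns <- ar1_spec()
  # +Inf SNR: poststimulus window is exactly the template
  ep <- make_epoch(tpl, ns, "target", snr_db = Inf, seed = 1)
  expect_equal(ep$post[[1]], tpl$waveform)
  # nontarget: no signal at any SNR
  ep <- make_epoch(tpl, ns, "nontarget", snr_db = 20, seed = 2)
  expect_equal(ep$signal[[1]], numeric(200))
  expect_equal(ep$post[[1]] - ep$signal[[1]], ep$post[[1]])
  # 0 dB: realized power ratio of the two generated components is exactly 1
  ep <- make_epoch(tpl, ns, "target", snr_db = 0, seed = 3)
  p_sig <- mean(ep$signal[[1]]^2)
  p_noise <- mean((ep$post[[1]] - ep$signal[[1]])^2)
  expect_equal(p_sig / p_noise, 1, tolerance = 1e-10)
  expect_length(ep$pre[[1]], 100)
  expect_length(ep$post[[1]], 200)
})

test_that("study generator follows the five-day protocol structure", {
  study <- generate_study(n_subjects = 2, seed = 99)
  cal <- dplyr::filter(study, day == "calibration")
  # 8 calibration sessions per subject, 13-16 flashes each
  sizes <- dplyr::count(cal, subject_id, session)
  expect_equal(nrow(sizes), 16)
  expect_true(all(sizes$n >= 13 & sizes$n <= 16))
  # exactly one target per block, everywhere
  per_block <- dplyr::count(study, subject_id, day, session, block,
                            wt = label == "target")
  expect_true(all(per_block$n == 1))
  # 4 testing days x 4 sessions x 16 flashes
  t1 <- dplyr::filter(study, day == "T1", subject_id == "S01")
  expect_equal(nrow(t1), 64)
  expect_setequal(unique(study$day), c("calibration", paste0("T", 1:4)))
  # target fraction in full blocks is exactly 1/4
  expect_equal(mean(t1$label == "target"), 0.25)
})

test_that("study generation is reproducible and supports calibration-only datasets", {
  s1 <- generate_study(1, seed = 5)
  s2 <- generate_study(1, seed = 5)
  expect_identical(s1, s2)
  cal_only <- generate_study(1, sessions_per_day = 0, seed = 5)
  expect_equal(unique(cal_only$day), "calibration")
})
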