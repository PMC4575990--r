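test_that("single pulse has the carrier at its spectral peak and a calibrated envelope", {
  spec <- pulse_train_spec()   # 220 Hz carrier, sigma 2 ms, 10 kHz, 80 dB
  p <- make_pulse(spec)
  df <- dominant_frequency(p, pad_s = 1)
  expect_lte(abs(df$freq - 220), df$resolution)

  # envelope peak sits on the grid at t = 0 with amplitude A; the
  # carrier's sin passes through 0 there, so |samples| peaks nearby and
  # the analytic envelope at center is A
  a <- db_to_amplitude(80)
  center <- (length(p$samples) + 1) / 2
  expect_equal(p$samples[center], 0, tolerance = 1e-12)  # sin(0) = 0
  # odd symmetry about the center => integral ~ 0
  expect_lt(abs(sum(p$samples)) / sum(abs(p$samples)), 1e-10)
  expect_equal(p$samples[center + 3], -p$samples[center - 3])
  # sample quarter-period after center reaches ~A * envelope
  q <- round(p$sample_rate / (4 * 220))
  t_q <- q / p$sample_rate
  expect_equal(p$samples[center + q],
               a * exp(-t_q^2 / (2 * (0.002)^2)) *
                 sin(2 * pi * 220 * t_q), tolerance = 1e-12)
})

test_that("dB calibration scales amplitude and energy by the closed-form rule", {
  p80 <- make_pulse(pulse_train_spec(level_db = 80))
  p86 <- make_pulse(pulse_train_spec(level_db = 86))
  ratio <- max(abs(p86$samples)) / max(abs(p80$samples))
  expect_equal(ratio, 10^(6 / 20), tolerance = 1e-12)
  energy_ratio <- sum(p86$samples^2) / sum(p80$samples^2)
  expect_equal(energy_ratio, 10^(6 / 10), tolerance = 1e-12)  # ~3.98x
  # same law for sine and noise (RMS-calibrated)
  s_hi <- make_sine(sine_spec(level_db = 90))
  s_lo <- make_sine(sine_spec(level_db = 70))
  expect_equal(max(s_hi$samples) / max(s_lo$samples), 10, tolerance = 1e-9)
  n_hi <- make_noise(noise_spec(level_db = 90, seed = 4))
  n_lo <- make_noise(noise_spec(level_db = 70, seed = 4))
  expect_equal(sqrt(mean(n_hi$samples^2) / mean(n_lo$samples^2)), 10,
               tolerance = 1e-9)
})

test_that("pulse trains place envelope peaks at exact IPI spacing", {
  spec <- pulse_train_spec(ipi = 35, n_pulses = 40)
  tr <- make_pulse_train(spec)
  # locate envelope maxima: local peaks of |hilbert-free| envelope proxy
  # (analytic check: peaks of the planted Gaussian envelopes)
  env <- abs(tr$samples)
  fs <- spec$sample_rate
  first_peak <- which.max(env[1:round(0.012 * fs)])
  last_start <- length(env) - round(0.012 * fs)
  last_peak <- last_start + which.max(env[(last_start + 1):length(env)])
  span_s <- (last_peak - first_peak) / fs
  expect_equal(span_s, 39 * 0.035, tolerance = 2 / fs)
  # n_pulses = 1 degenerates to a single pulse
  one <- make_pulse_train(pulse_train_spec(n_pulses = 1))
  expect_identical(one$samples, make_pulse(pulse_train_spec())$samples)
})

test_that("pulse-train autocorrelation has its secondary peak at the IPI lag", {
  spec <- pulse_train_spec(ipi = 35, n_pulses = 40)
  tr <- make_pulse_train(spec)
  fs <- spec$sample_rate
  ac <- stats::acf(tr$samples, lag.max = round(0.06 * fs), plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  # exclude the zero-lag main lobe (~ pulse support)
  search <- (round(0.015 * fs)):(round(0.06 * fs))
  lag_s <- (search[which.max(ac[search + 1])]) / fs
  expect_equal(lag_s, 0.035, tolerance = 2 / fs)
})

test_that("sine and noise stimuli match their specs", {
  s <- make_sine(sine_spec(freq = 140, duration = 1.4, sample_rate = 10000))
  expect_length(s$samples, 14000)
  df <- dominant_frequency(s, pad_s = 1)
  expect_lte(abs(df$freq - 140), df$resolution)

  n1 <- make_noise(noise_spec(seed = 11))
  n2 <- make_noise(noise_spec(seed = 11))
  expect_identical(n1$samples, n2$samples)

  # spectral flatness: octave-band power ratio < 2 on a long sample
  n <- make_noise(noise_spec(duration = 10, seed = 5))
  spec <- Mod(stats::fft(n$samples))^2
  freqs <- (seq_along(spec) - 1) * n$sample_rate / length(spec)
  bands <- cbind(c(62.5, 125, 250, 500, 1000, 2000),
                 c(125, 250, 500, 1000, 2000, 4000))
  pw <- apply(bands, 1, function(b)
    mean(spec[freqs >= b[1] & freqs < b[2]]))
  expect_lt(max(pw) / min(pw), 2)
})

test_that("invalid stimulus specs are rejected with explanatory errors", {
  expect_error(pulse_train_spec(sample_rate = 500), "too low")
  expect_error(pulse_train_spec(ipi = 10, envelope_sigma = 2), "overlap")
  expect_error(sine_spec(duration = -1), "positive")
  expect_error(noise_spec(duration = 0), "positive")
  expect_error(make_ramp_protocol(pulse_train_spec(),
                                  levels_db = numeric(0)), "non-empty")
  expect_error(make_ramp_protocol(pulse_train_spec(),
                                  levels_db = c(80, 70)), "non-decreasing")
  expect_error(make_intermittent_protocol(pulse_train_spec(ipi = 95,
                                                           n_pulses = 60),
                                          period_s = 5), "exceeds")
})

test_that("ramp protocol lays out lead silence plus one 30-s block per level", {
  rp <- make_ramp_protocol(pulse_train_spec(),
                           levels_db = seq(60, 90, by = 2.5),
                           block_s = 30, lead_silence_s = 60)
  expect_equal(protocol_duration(rp), 60 + 13 * 30)    # 450 s
  ev <- protocol_events(rp)
  expect_equal(nrow(ev), 13)
  expect_equal(ev$level_db, seq(60, 90, by = 2.5))
  # block boundaries share the 30-s chaining-index grid
  expect_true(all(ev$onset_s %% 30 == 0))
  one <- make_ramp_protocol(pulse_train_spec(), levels_db = 80)
  expect_equal(nrow(protocol_events(one)), 1)
})

test_that("intermittent protocol delivers equal pulse counts at every IPI", {
  ip15 <- make_intermittent_protocol(pulse_train_spec(ipi = 15))
  ip95 <- make_intermittent_protocol(pulse_train_spec(ipi = 95))
  ev15 <- protocol_events(ip15); ev95 <- protocol_events(ip95)
  expect_equal(nrow(ev15), 24)                        # 120 s / 5 s
  expect_equal(nrow(ev95), 24)
  # per-window pulse count identical across IPIs: 40 pulses per train
  expect_true(all(ip15$segments$n_pulses[ip15$segments$type == "pulse_train"] == 40))
  expect_true(all(ip95$segments$n_pulses[ip95$segments$type == "pulse_train"] == 40))
  # IPI-95 train still fits its 5-s slot: span 39 * 0.095 + 0.012 s
  expect_lt(39 * 0.095 + 0.012, 5)
  # zero-length song window -> silence-only protocol
  z <- make_intermittent_protocol(pulse_train_spec(), total_s = 0)
  expect_equal(nrow(protocol_events(z)), 0)
})

test_that("protocols survive a JSON round-trip sample-for-sample", {
  ip <- make_intermittent_protocol(pulse_train_spec(ipi = 45), total_s = 20,
                                   lead_s = 2, tail_s = 2)
  path <- tempfile(fileext = ".json")
  write_protocol(ip, path)
  back <- read_protocol(path)
  expect_identical(render_protocol(back)$samples,
                   render_protocol(ip)$samples)
  expect_equal(back$metadata$song_window, c(2, 22))
})
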