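#' Specification of a Gaussian-windowed pulse train
#'
#' Describes synthetic fly pulse song: a train of Gaussian-modulated
#' sinusoidal pulses with a fundamental carrier frequency and a defined
#' inter-pulse interval (IPI, peak-to-peak between envelope maxima).
#' Defaults follow the study design: 220 Hz carrier, 40 pulses, 80 dB,
#' 10 kHz sampling, 2-ms envelope sigma truncated at +/- 3 sigma (so a
#' pulse spans a few carrier cycles, matching D. melanogaster pulse
#' morphology).
#'
#' @param carrier_freq carrier frequency (Hz).
#' @param ipi inter-pulse interval (ms), envelope peak to envelope peak.
#' @param n_pulses number of pulses (>= 1).
#' @param envelope_sigma Gaussian envelope sigma (ms).
#' @param sample_rate sampling rate (samples/s); must be >= 4 x carrier.
#' @param level_db intensity (dB, relative calibration; see
#'   [db_to_amplitude()]).
#' @return an object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(carrier_freq = 220, ipi = 35, n_pulses = 40,
                             envelope_sigma = 2, sample_rate = 10000,
                             level_db = 80) {
  stop_if_not_scalar_pos(carrier_freq, "carrier_freq")
  stop_if_not_scalar_pos(ipi, "ipi")
  stop_if_not_scalar_pos(envelope_sigma, "envelope_sigma")
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  if (!is.numeric(n_pulses) || n_pulses < 1 || n_pulses != round(n_pulses))
    stop("`n_pulses` must be a positive integer", call. = FALSE)
  if (sample_rate < 4 * carrier_freq)
    stop(sprintf(paste0("sample_rate (%g Hz) is too low for a %g Hz carrier; ",
                        "need at least 4 x carrier = %g Hz"),
                 sample_rate, carrier_freq, 4 * carrier_freq), call. = FALSE)
  if (n_pulses > 1 && 6 * envelope_sigma >= ipi)
    stop(sprintf(paste0("pulses would overlap: envelope support 6*sigma = %g ms ",
                        "must be < ipi = %g ms"), 6 * envelope_sigma, ipi),
         call. = FALSE)
  structure(list(carrier_freq = carrier_freq, ipi = ipi,
                 n_pulses = as.integer(n_pulses),
                 envelope_sigma = envelope_sigma,
                 sample_rate = sample_rate, level_db = level_db),
            class = "pulse_train_spec")
}

#' Specification of a sine-song stimulus
#'
#' Defaults follow the imaging stimulus set: 140 Hz, 1.4 s.
#'
#' @param freq tone frequency (Hz).
#' @param duration duration (s).
#' @param level_db intensity (dB).
#' @param sample_rate samples/s.
#' @return an object of class `sine_spec`.
#' @export
sine_spec <- function(freq = 140, duration = 1.4, level_db = 80,
                      sample_rate = 10000) {
  stop_if_not_scalar_pos(freq, "freq")
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  structure(list(freq = freq, duration = duration, level_db = level_db,
                 sample_rate = sample_rate), class = "sine_spec")
}

#' Specification of a white-noise stimulus
#'
#' Gaussian white noise, flat to Nyquist, RMS-calibrated to the dB level,
#' reproducible from `seed`. Default duration 1.4 s as in the imaging
#' stimulus set.
#'
#' @param duration duration (s).
#' @param level_db intensity (dB); amplitude calibration is by RMS.
#' @param sample_rate samples/s.
#' @param seed RNG seed for reproducible samples.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(duration = 1.4, level_db = 80, sample_rate = 10000,
                       seed = 1L) {
  stop_if_not_scalar_pos(duration, "duration")
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  structure(list(duration = duration, level_db = level_db,
                 sample_rate = sample_rate, seed = seed),
            class = "noise_spec")
}

new_waveform <- function(samples, sample_rate, level_db) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 level_db = level_db), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.4g s), level %g dB\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$level_db))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @return duration (s).
#' @export
waveform_duration <- function(w) length(w$samples) / w$sample_rate

#' Synthesize a single Gaussian-windowed pulse
#'
#' s(t) = A * exp(-t^2 / (2 sigma^2)) * sin(2 pi f_c t) on the support
#' t in \[-3 sigma, +3 sigma\], with the envelope peak exactly on the
#' sample grid at t = 0 and A set by the dB calibration.
#'
#' @param spec a [pulse_train_spec()] (only the single-pulse fields are
#'   used).
#' @return a `waveform`.
#' @export
make_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  sigma <- spec$envelope_sigma / 1000
  fs <- spec$sample_rate
  half <- round(3 * sigma * fs)
  t <- (seq_len(2 * half + 1) - (half + 1)) / fs
  a <- db_to_amplitude(spec$level_db)
  s <- a * exp(-t^2 / (2 * sigma^2)) * sin(2 * pi * spec$carrier_freq * t)
  new_waveform(s, fs, spec$level_db)
}

#' Synthesize a pulse train
#'
#' `n_pulses` copies of [make_pulse()] with envelope maxima spaced `ipi`
#' milliseconds apart (peak-to-peak IPI convention), so the first-to-last
#' peak span is (n_pulses - 1) * ipi.
#'
#' @param spec a [pulse_train_spec()].
#' @return a `waveform`.
#' @export
make_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  pulse <- make_pulse(spec)
  fs <- spec$sample_rate
  gap <- round(spec$ipi / 1000 * fs)
  np <- length(pulse$samples)
  n <- (spec$n_pulses - 1L) * gap + np
  s <- numeric(n)
  for (i in seq_len(spec$n_pulses)) {
    idx <- (i - 1L) * gap + seq_len(np)
    s[idx] <- s[idx] + pulse$samples
  }
  new_waveform(s, fs, spec$level_db)
}

#' Synthesize a sine-song stimulus
#'
#' @param spec a [sine_spec()].
#' @return a `waveform` with `round(duration * sample_rate)` samples.
#' @export
make_sine <- function(spec) {
  stopifnot(inherits(spec, "sine_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  a <- db_to_amplitude(spec$level_db)
  new_waveform(a * sin(2 * pi * spec$freq * t), fs, spec$level_db)
}

#' Synthesize a white-noise stimulus
#'
#' Seeded Gaussian samples (flat spectrum to Nyquist), rescaled so the RMS
#' amplitude equals the calibrated amplitude for `level_db`. The same seed
#' always reproduces the same samples; the caller's RNG stream is left
#' untouched.
#'
#' @param spec a [noise_spec()].
#' @return a `waveform`.
#' @export
make_noise <- function(spec) {
  stopifnot(inherits(spec, "noise_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  s <- with_seed(spec$seed, stats::rnorm(n))
  a <- db_to_amplitude(spec$level_db)
  s <- s * a / sqrt(mean(s^2))
  new_waveform(s, fs, spec$level_db)
}

#' Dominant frequency of a waveform
#'
#' Zero-pads to at least `pad_s` seconds (so the FFT bin width is at most
#' 1/pad_s Hz) and returns the frequency of the amplitude-spectrum maximum
#' over (0, Nyquist).
#'
#' @param w a `waveform`.
#' @param pad_s minimum analysis duration after zero-padding (s).
#' @return list with `freq` (Hz) and `resolution` (Hz, one FFT bin).
#' @export
dominant_frequency <- function(w, pad_s = 1) {
  n <- max(length(w$samples), ceiling(pad_s * w$sample_rate))
  spec <- Mod(stats::fft(c(w$samples, numeric(n - length(w$samples)))))
  half <- seq_len(floor(n / 2))          # bins 1..n/2 ~ (0, Nyquist]
  freqs <- (half - 1) * w$sample_rate / n
  keep <- freqs > 0
  list(freq = freqs[keep][which.max(spec[half][keep])],
       resolution = w$sample_rate / n)
}

## ---- protocols ------------------------------------------------------------

new_protocol <- function(segments, sample_rate, metadata = list()) {
  o <- order(segments$start_s)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments) > 1) {
    ends <- segments$start_s + segments$duration_s
    if (any(diff(segments$start_s) <= 0))
      stop("segment start times must be strictly increasing", call. = FALSE)
    if (any(segments$start_s[-1] < ends[-nrow(segments)] - 1e-9))
      stop("protocol segments overlap", call. = FALSE)
  }
  structure(list(segments = segments, sample_rate = sample_rate,
                 metadata = metadata), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d segments, %.4g s total @ %g Hz\n",
              nrow(x$segments), protocol_duration(x), x$sample_rate))
  print(utils::head(x$segments, 10))
  invisible(x)
}

#' Total duration of a protocol in seconds
#' @param protocol a `stimulus_protocol`.
#' @return duration (s), including any trailing silence segment.
#' @export
protocol_duration <- function(protocol) {
  with(protocol$segments, max(start_s + duration_s))
}

segment_row <- function(start_s, duration_s, type, level_db = NA_real_,
                        carrier_freq = NA_real_, ipi = NA_real_,
                        n_pulses = NA_integer_, envelope_sigma = NA_real_,
                        freq = NA_real_, seed = NA_integer_) {
  data.frame(start_s = start_s, duration_s = duration_s, type = type,
             level_db = level_db, carrier_freq = carrier_freq, ipi = ipi,
             n_pulses = n_pulses, envelope_sigma = envelope_sigma,
             freq = freq, seed = seed, stringsAsFactors = FALSE)
}

#' Intensity-ramp playback protocol
#'
#' Lead silence followed by one continuous pulse-train block per
#' intensity level, each lasting `block_s`. Defaults follow the
#' behavioral ramp: 60 s of silence, then continuous pulse song stepped
#' from 60 to 90 dB every 30 s. The exact dB grid of the original ramp is
#' not fully printed (intermediate levels such as 72.5 dB appear), so the
#' default is the 2.5-dB grid 60, 62.5, ..., 90; pass `levels_db` to
#' change it. Block boundaries share the 30-s grid of the chaining index.
#'
#' @param train a [pulse_train_spec()]; its `n_pulses` is ignored (the
#'   train is continuous within each block).
#' @param levels_db non-decreasing intensity levels (dB).
#' @param block_s duration of each level block (s).
#' @param lead_silence_s silence before the first block (s).
#' @return a `stimulus_protocol`.
#' @export
make_ramp_protocol <- function(train, levels_db = seq(60, 90, by = 2.5),
                               block_s = 30, lead_silence_s = 60) {
  stopifnot(inherits(train, "pulse_train_spec"))
  if (length(levels_db) == 0) stop("`levels_db` must be non-empty", call. = FALSE)
  if (is.unsorted(levels_db)) stop("`levels_db` must be non-decreasing", call. = FALSE)
  stop_if_not_scalar_pos(block_s, "block_s")
  n_per_block <- max(1L, floor(block_s * 1000 / train$ipi))
  segs <- list()
  if (lead_silence_s > 0)
    segs[[1]] <- segment_row(0, lead_silence_s, "silence")
  for (i in seq_along(levels_db)) {
    segs[[length(segs) + 1L]] <- segment_row(
      lead_silence_s + (i - 1) * block_s, block_s, "pulse_train",
      level_db = levels_db[i], carrier_freq = train$carrier_freq,
      ipi = train$ipi, n_pulses = n_per_block,
      envelope_sigma = train$envelope_sigma)
  }
  new_protocol(do.call(rbind, segs), train$sample_rate,
               metadata = list(kind = "ramp", levels_db = levels_db,
                               block_s = block_s,
                               lead_silence_s = lead_silence_s))
}

#' Intermittent pulse-train playback protocol
#'
#' A fixed train (default 40 pulses) delivered every `period_s` for
#' `total_s`, flanked by silence, so the number of pulses per song window
#' is identical across IPIs. Defaults follow the IPI-tuning assay: one
#' minute of silence, two minutes of intermittent song (a 40-pulse train
#' every five seconds), two minutes of silence.
#'
#' @param train a [pulse_train_spec()].
#' @param period_s train onset period (s); must be >= the train span.
#' @param total_s duration of the song window (s).
#' @param lead_s leading silence (s).
#' @param tail_s trailing silence (s).
#' @return a `stimulus_protocol`.
#' @export
make_intermittent_protocol <- function(train, period_s = 5, total_s = 120,
                                       lead_s = 60, tail_s = 120) {
  stopifnot(inherits(train, "pulse_train_spec"))
  stop_if_not_scalar_pos(period_s, "period_s")
  if (total_s < 0) stop("`total_s` must be >= 0", call. = FALSE)
  span <- (train$n_pulses - 1) * train$ipi / 1000 +
    6 * train$envelope_sigma / 1000
  if (span > period_s)
    stop(sprintf("train span (%.3f s) exceeds period_s (%g s)", span, period_s),
         call. = FALSE)
  n_trains <- floor(total_s / period_s)
  segs <- list()
  if (lead_s > 0) segs[[1]] <- segment_row(0, lead_s, "silence")
  for (i in seq_len(n_trains)) {
    segs[[length(segs) + 1L]] <- segment_row(
      lead_s + (i - 1) * period_s, span, "pulse_train",
      level_db = train$level_db, carrier_freq = train$carrier_freq,
      ipi = train$ipi, n_pulses = train$n_pulses,
      envelope_sigma = train$envelope_sigma)
  }
  end_song <- lead_s + total_s
  if (tail_s > 0)
    segs[[length(segs) + 1L]] <- segment_row(end_song, tail_s, "silence")
  if (length(segs) == 0) segs[[1]] <- segment_row(0, 0, "silence")
  new_protocol(do.call(rbind, segs), train$sample_rate,
               metadata = list(kind = "intermittent", period_s = period_s,
                               total_s = total_s, lead_s = lead_s,
                               tail_s = tail_s,
                               song_window = c(lead_s, end_song)))
}

segment_waveform <- function(seg, sample_rate) {
  switch(seg$type,
    pulse_train = make_pulse_train(pulse_train_spec(
      carrier_freq = seg$carrier_freq, ipi = seg$ipi,
      n_pulses = seg$n_pulses, envelope_sigma = seg$envelope_sigma,
      sample_rate = sample_rate, level_db = seg$level_db)),
    sine = make_sine(sine_spec(freq = seg$freq, duration = seg$duration_s,
                               level_db = seg$level_db,
                               sample_rate = sample_rate)),
    noise = make_noise(noise_spec(duration = seg$duration_s,
                                  level_db = seg$level_db,
                                  sample_rate = sample_rate,
                                  seed = seg$seed)),
    silence = new_waveform(numeric(round(seg$duration_s * sample_rate)),
                           sample_rate, NA_real_),
    stop(sprintf("unknown segment type '%s'", seg$type), call. = FALSE))
}

#' Render a protocol to a single waveform
#'
#' Each segment's waveform is added at its start time; segments are
#' truncated at their declared duration.
#'
#' @param protocol a `stimulus_protocol`.
#' @return a `waveform` spanning the whole protocol.
#' @export
render_protocol <- function(protocol) {
  fs <- protocol$sample_rate
  n <- ceiling(protocol_duration(protocol) * fs)
  out <- numeric(n)
  for (i in seq_len(nrow(protocol$segments))) {
    seg <- protocol$segments[i, ]
    if (seg$type == "silence") next
    w <- segment_waveform(seg, fs)$samples
    n_seg <- min(length(w), round(seg$duration_s * fs))
    start <- round(seg$start_s * fs)
    idx <- start + seq_len(n_seg)
    idx <- idx[idx <= n]
    out[idx] <- out[idx] + w[seq_along(idx)]
  }
  new_waveform(out, fs, max(protocol$segments$level_db, na.rm = TRUE))
}

#' Stimulus event table of a protocol
#'
#' One row per non-silence segment: onset, kind, IPI and level. This is
#' the event table consumed by the imaging metrics.
#'
#' @param protocol a `stimulus_protocol`.
#' @return data.frame with columns onset_s, kind, ipi, level_db.
#' @export
protocol_events <- function(protocol) {
  seg <- protocol$segments
  seg <- seg[seg$type != "silence", , drop = FALSE]
  data.frame(onset_s = seg$start_s,
             kind = sub("pulse_train", "pulse", seg$type),
             ipi = seg$ipi, level_db = seg$level_db,
             stringsAsFactors = FALSE)
}

#' Write / read a protocol as JSON
#'
#' The JSON carries the full segment table, sample rate and metadata;
#' a read-back protocol renders to an identical sample sequence.
#'
#' @param protocol a `stimulus_protocol`.
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns a `stimulus_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(sample_rate = protocol$sample_rate, metadata = protocol$metadata,
         segments = protocol$segments),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- as.data.frame(x$segments, stringsAsFactors = FALSE)
  num <- c("start_s", "duration_s", "level_db", "carrier_freq", "ipi",
           "envelope_sigma", "freq")
  for (cc in num) seg[[cc]] <- as.numeric(seg[[cc]] %||% NA_real_)
  seg$n_pulses <- as.integer(seg$n_pulses %||% NA_integer_)
  seg$seed <- as.integer(seg$seed %||% NA_integer_)
  new_protocol(seg, as.numeric(x$sample_rate), as.list(x$metadata))
}
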