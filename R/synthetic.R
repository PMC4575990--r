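#' Planted IPI-tuning models
#'
#' Two response shapes emulate the study's neuron classes:
#' `low_pass_hill` — a saturating Hill curve in IPI,
#' r(ipi) = r_max * ipi^n / (K^n + ipi^n), which rises with IPI and
#' saturates above the conspecific ~35 ms (vPN1-like low-pass tuning).
#' The defaults (K = 18 ms, n = 2) put the half-saturation below 35 ms
#' with a gentle slope, so the normalized response is ~0.4 at 15 ms and
#' ~0.8 at 35 ms — attenuated at short IPIs without vanishing, the shape
#' reported for the upstream (vPN1-like) neurons;
#' `band_pass_gaussian` — baseline + r_max * exp(-(ipi - center)^2 /
#' (2 width^2)), peaked at intermediate IPIs with attenuation at both
#' extremes (pC1-like band-pass tuning).
#'
#' @param kind "low_pass_hill" or "band_pass_gaussian".
#' @param r_max peak response (response units).
#' @param K Hill half-saturation IPI (ms); low-pass only.
#' @param n_hill Hill coefficient; low-pass only.
#' @param center,width Gaussian center and width (ms); band-pass only.
#' @param baseline additive floor; band-pass only.
#' @return a `tuning_model`.
#' @export
tuning_model <- function(kind = c("low_pass_hill", "band_pass_gaussian"),
                         r_max = 1, K = 18, n_hill = 2,
                         center = 50, width = 15, baseline = 0.05) {
  kind <- match.arg(kind)
  stop_if_not_scalar_pos(r_max, "r_max")
  stop_if_not_scalar_pos(K, "K")
  stop_if_not_scalar_pos(width, "width")
  structure(list(kind = kind, r_max = r_max, K = K, n_hill = n_hill,
                 center = center, width = width, baseline = baseline),
            class = "tuning_model")
}

#' Evaluate a tuning model at IPI values
#'
#' @param model a [tuning_model()].
#' @param ipi IPI values (ms).
#' @return response values.
#' @export
eval_tuning <- function(model, ipi) {
  stopifnot(inherits(model, "tuning_model"))
  switch(model$kind,
    low_pass_hill = model$r_max * ipi^model$n_hill /
      (model$K^model$n_hill + ipi^model$n_hill),
    band_pass_gaussian = model$baseline + model$r_max *
      exp(-(ipi - model$center)^2 / (2 * model$width^2)))
}

#' Calcium-indicator impulse kernel
#'
#' Double-exponential GCaMP-like kernel, k(t) = (1 - exp(-t/rise)) *
#' exp(-t/decay) for t >= 0, normalized to unit peak. Defaults
#' (rise 0.08 s, decay 0.6 s) are order-of-magnitude GCaMP6m values;
#' the slow decay low-pass-filters fast stimulus structure, as in the
#' recordings this emulates.
#'
#' @param rise_tau rise time constant (s), 0 < rise_tau < decay_tau.
#' @param decay_tau decay time constant (s).
#' @return a `gcamp_kernel`; evaluate with [eval_kernel()].
#' @export
gcamp_kernel <- function(rise_tau = 0.08, decay_tau = 0.6) {
  if (!(rise_tau > 0 && rise_tau < decay_tau))
    stop("need 0 < rise_tau < decay_tau", call. = FALSE)
  k <- structure(list(rise_tau = rise_tau, decay_tau = decay_tau),
                 class = "gcamp_kernel")
  t_pk <- rise_tau * log(1 + decay_tau / rise_tau)
  k$peak <- (1 - exp(-t_pk / rise_tau)) * exp(-t_pk / decay_tau)
  k
}

#' @rdname gcamp_kernel
#' @param kernel a `gcamp_kernel`.
#' @param t times since event onset (s); values at t < 0 are 0.
#' @export
eval_kernel <- function(kernel, t) {
  stopifnot(inherits(kernel, "gcamp_kernel"))
  out <- ifelse(t >= 0,
                (1 - exp(-t / kernel$rise_tau)) * exp(-t / kernel$decay_tau),
                0)
  out / kernel$peak
}

#' Ground truth for a synthetic imaging subject
#'
#' Bundles everything the generator plants so recovery can be scored:
#' ROI geometry, tuning, kernel, noise level and seed. The planted ROI
#' mask convention is the 1.5-sigma footprint of each Gaussian blob
#' (pixels with spatial profile >= exp(-1.125) of peak), the footprint an
#' intensity-based segmentation is expected to recover.
#'
#' @param dims image size c(H, W) in pixels.
#' @param roi_centers list of c(row, col) blob centers.
#' @param roi_sigma blob spatial sigma (px).
#' @param baseline baseline intensity (a.u.).
#' @param contrast blob peak brightness over baseline (peak pixel =
#'   baseline * (1 + contrast)).
#' @param amp_max peak delta-F/F at the preferred stimulus.
#' @param tuning a [tuning_model()] (per-ROI amplitude = amp_max *
#'   tuning(ipi)/r_max).
#' @param kernel a [gcamp_kernel()].
#' @param noise_sd photon-like noise scale: pixel SD =
#'   noise_sd * sqrt(intensity).
#' @param frame_rate frames/s.
#' @param seed RNG seed for movie noise.
#' @return a `synthetic_ground_truth`.
#' @export
synthetic_ground_truth <- function(dims = c(64, 64),
                                   roi_centers = list(c(20, 20), c(44, 40)),
                                   roi_sigma = 4, baseline = 100,
                                   contrast = 4, amp_max = 1,
                                   tuning = tuning_model("band_pass_gaussian"),
                                   kernel = gcamp_kernel(),
                                   noise_sd = 0.5, frame_rate = 13,
                                   seed = 1L) {
  structure(list(dims = dims, roi_centers = roi_centers,
                 roi_sigma = roi_sigma, baseline = baseline,
                 contrast = contrast, amp_max = amp_max, tuning = tuning,
                 kernel = kernel, noise_sd = noise_sd,
                 frame_rate = frame_rate, seed = seed),
            class = "synthetic_ground_truth")
}

roi_profiles <- function(truth) {
  h <- truth$dims[1]; w <- truth$dims[2]
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  lapply(truth$roi_centers, function(cc)
    exp(-((rows - cc[1])^2 + (cols - cc[2])^2) / (2 * truth$roi_sigma^2)))
}

#' Planted ROI label mask of a ground truth
#'
#' @param truth a [synthetic_ground_truth()].
#' @return integer H x W label matrix (1.5-sigma footprints).
#' @export
truth_masks <- function(truth) {
  profs <- roi_profiles(truth)
  cut <- exp(-1.125)   # profile level at radius 1.5 sigma
  m <- array(0L, truth$dims)
  for (i in seq_along(profs)) m[profs[[i]] >= cut] <- i
  m
}

#' Simulate a calcium movie from planted ground truth
#'
#' Baseline image with Gaussian-blob ROIs (peak `contrast` x baseline
#' above baseline); for each stimulus event every ROI receives a
#' delta-F/F transient of amplitude amp_max * tuning(ipi)/r_max (times a
#' logistic intensity factor if `intensity_ec50` is given), shaped by the
#' GCaMP kernel; pixel noise is Gaussian with SD = noise_sd *
#' sqrt(intensity) (photon-like). Fully reproducible from `truth$seed`.
#'
#' @param truth a [synthetic_ground_truth()].
#' @param events data.frame with `onset_s`, `ipi` and optionally
#'   `level_db`; NULL or empty for a stationary (no-stimulus) movie.
#' @param duration_s movie length (s); defaults to last onset + 8 s
#'   (required when `events` is empty).
#' @param intensity_ec50,intensity_slope optional logistic intensity
#'   dependence applied multiplicatively (half-max at `intensity_ec50`
#'   dB).
#' @return a [movie()].
#' @export
simulate_movie <- function(truth, events, duration_s = NULL,
                           intensity_ec50 = NULL, intensity_slope = 0.5) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  no_events <- is.null(events) || nrow(events) == 0
  if (is.null(duration_s)) {
    if (no_events) stop("`duration_s` required when `events` is empty",
                        call. = FALSE)
    duration_s <- max(events$onset_s) + 8
  }
  fr <- truth$frame_rate
  nt <- ceiling(duration_s * fr)
  t <- (seq_len(nt) - 1) / fr
  profs <- roi_profiles(truth)
  base_img <- array(truth$baseline, truth$dims)
  for (p in profs) base_img <- base_img + truth$baseline * truth$contrast * p
  # per-ROI dF/F time course (all ROIs share the tuning model here)
  dff <- numeric(nt)
  if (no_events) events <- data.frame(onset_s = numeric(0), ipi = numeric(0))
  for (i in seq_len(nrow(events))) {
    amp <- truth$amp_max *
      eval_tuning(truth$tuning, events$ipi[i]) / truth$tuning$r_max
    if (!is.null(intensity_ec50) && !is.null(events$level_db))
      amp <- amp * stats::plogis(intensity_slope *
                                   (events$level_db[i] - intensity_ec50))
    dff <- dff + amp * eval_kernel(truth$kernel, t - events$onset_s[i])
  }
  h <- truth$dims[1]; w <- truth$dims[2]
  frames <- array(0, c(h, w, nt))
  roi_gain <- Reduce(`+`, profs)   # spatial weight of the transient
  noise <- with_seed(truth$seed, stats::rnorm(h * w * nt))
  dim(noise) <- c(h, w, nt)
  for (k in seq_len(nt)) {
    clean <- base_img * (1 + dff[k] * roi_gain)
    frames[, , k] <- clean + truth$noise_sd * sqrt(clean) * noise[, , k]
  }
  frames[frames < 0] <- 0
  movie(frames, fr)
}

#' Simulate a per-subject tuning-response table
#'
#' Per-subject peak responses on an IPI grid: value = gain_s *
#' tuning(ipi) + noise, with multiplicative lognormal subject gains
#' (which is what makes per-fly max normalization necessary downstream)
#' and additive Gaussian noise scaled to r_max.
#'
#' @param model a [tuning_model()].
#' @param ipi_grid IPI conditions (ms).
#' @param n_subjects number of subjects (flies).
#' @param seed RNG seed.
#' @param gain_sd SD of log subject gain.
#' @param noise_sd additive noise SD as a fraction of r_max.
#' @return long data.frame(subject, condition, value).
#' @export
simulate_tuning_table <- function(model, ipi_grid = seq(15, 95, by = 10),
                                  n_subjects = 10, seed = 1L,
                                  gain_sd = 0.2, noise_sd = 0.1) {
  stopifnot(inherits(model, "tuning_model"))
  base <- eval_tuning(model, ipi_grid)
  with_seed(seed, {
    rows <- lapply(seq_len(n_subjects), function(s) {
      gain <- exp(stats::rnorm(1, 0, gain_sd))
      data.frame(subject = s, condition = ipi_grid,
                 value = gain * base +
                   stats::rnorm(length(ipi_grid), 0,
                                noise_sd * model$r_max))
    })
    do.call(rbind, rows)
  })
}

#' Simulate chaining-count series under a playback protocol
#'
#' For each 3-s snapshot the number of flies in a chain is
#' Binomial(group_size, p). During song, logit(p) = slope_db * (dB -
#' ec50) + ipi_weight * (tuning(ipi)/r_max - 1): at the planted EC50 and
#' the preferred IPI, p = 1/2, so summed-CI-versus-dB curves have their
#' half-max at `ec50` by construction. During silence p = `p_silence`,
#' except that after the last song segment chaining decays exponentially
#' back to silence with time constant `decay_tau_s` (chaining persists
#' and gradually decreases after song offset). Fly-fly dependence within
#' a chain is deliberately ignored (independent-fly binomial
#' simplification).
#'
#' @param protocol a `stimulus_protocol` (ramp or intermittent).
#' @param n_groups number of independent groups of flies.
#' @param seed RNG seed.
#' @param tuning a [tuning_model()] for the IPI dependence (band-pass
#'   centered at the conspecific 35 ms by default).
#' @param ec50 planted behavioral intensity threshold (dB).
#' @param slope_db logistic slope (1/dB).
#' @param ipi_weight weight of the IPI tuning term on the logit scale.
#' @param p_silence chain probability during silence.
#' @param decay_tau_s post-song decay time constant (s); NULL disables.
#' @param group_size flies per arena.
#' @param dt_s snapshot interval (s).
#' @return list of [chain_count_series()], one per group.
#' @export
simulate_chaining <- function(protocol, n_groups = 14, seed = 1L,
                              tuning = tuning_model("band_pass_gaussian",
                                                    center = 35, width = 25,
                                                    baseline = 0),
                              ec50 = 70.6, slope_db = 0.35,
                              ipi_weight = 3, p_silence = 0.02,
                              decay_tau_s = 30, group_size = 6L,
                              dt_s = 3) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  total <- protocol_duration(protocol)
  times <- seq(0, total - dt_s, by = dt_s)
  seg <- protocol$segments
  song <- seg[seg$type != "silence", , drop = FALSE]
  song_end <- if (nrow(song)) max(song$start_s + song$duration_s) else -Inf
  # active song segment per snapshot: the last song segment whose block
  # (start to start + max(duration, snapshot grid)) covers the time
  p_t <- numeric(length(times))
  p_end <- p_silence
  for (i in seq_along(times)) {
    tt <- times[i]
    active <- NULL
    if (nrow(song)) {
      cand <- which(song$start_s <= tt + 1e-9 &
                      tt < song$start_s + pmax(song$duration_s,
                                               c(diff(song$start_s), Inf)))
      # within the song window, the governing segment is the latest onset
      if (length(cand) && tt < song_end) active <- song[max(cand), ]
    }
    if (!is.null(active)) {
      lg <- slope_db * (active$level_db - ec50) +
        ipi_weight * (eval_tuning(tuning, active$ipi) / tuning$r_max - 1)
      p_t[i] <- stats::plogis(lg)
      p_end <- p_t[i]
    } else if (!is.null(decay_tau_s) && tt >= song_end) {
      p_t[i] <- p_silence + (p_end - p_silence) *
        exp(-(tt - song_end) / decay_tau_s)
    } else {
      p_t[i] <- p_silence
    }
  }
  with_seed(seed, {
    lapply(seq_len(n_groups), function(g) {
      counts <- stats::rbinom(length(times), group_size, p_t)
      chain_count_series(times, counts, group_size)
    })
  })
}
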