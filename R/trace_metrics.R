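#' Construct a fluorescence trace
#'
#' @param values per-frame intensity (finite numeric).
#' @param frame_rate frames/s.
#' @param roi_id integer ROI label.
#' @return a `trace`.
#' @export
trace <- function(values, frame_rate = 13, roi_id = 1L) {
  if (!all(is.finite(values))) stop("trace has non-finite values",
                                    call. = FALSE)
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  structure(list(values = as.numeric(values), frame_rate = frame_rate,
                 roi_id = as.integer(roi_id)), class = "trace")
}

trace_times <- function(tr) (seq_along(tr$values) - 1) / tr$frame_rate

#' Savitzky-Golay smoothing of a calcium trace
#'
#' Cubic (order-3) Savitzky-Golay local-polynomial smoothing, the
#' standard pre-processing before peak extraction. Length is preserved
#' and edges are handled by the filter's truncated-window polynomial
#' fits, so any cubic input is reproduced to machine precision. The
#' default 11-frame window (~0.85 s at 13 Hz) is shorter than the GCaMP6m
#' decay, preserving transient peaks.
#'
#' @param tr a [trace()] or numeric vector.
#' @param window odd window length in frames, >= 5 (a cubic needs at
#'   least 5 points), < trace length.
#' @return smoothed object of the same type.
#' @export
smooth_trace <- function(tr, window = 11L) {
  v <- if (inherits(tr, "trace")) tr$values else tr
  if (window %% 2 == 0 || window < 5)
    stop("`window` must be odd and >= 5", call. = FALSE)
  if (window >= length(v))
    stop("`window` must be shorter than the trace", call. = FALSE)
  sm <- signal::sgolayfilt(v, p = 3, n = window)
  if (inherits(tr, "trace")) { tr$values <- sm; tr } else sm
}

#' Event-locked peak delta-F/F
#'
#' peak = (F_t - F_b) / F_b, where F_b is the mean over the 1-s window
#' before stimulus onset (\[onset - pre_s, onset)) and F_t the maximum in
#' the 5-s window after onset ((onset, onset + post_s\]; the onset frame
#' itself is excluded). Windows are mapped to the nearest frames; at
#' 13 Hz the defaults give 13 baseline and 65 peak-search frames.
#'
#' @param tr a [trace()].
#' @param onset_s stimulus onset time (s).
#' @param pre_s baseline window length (s).
#' @param post_s peak-search window length (s).
#' @return a `peak_response` list: `peak_dff`, `f_t`, `f_b`, `onset_s`.
#' @export
peak_dff <- function(tr, onset_s, pre_s = 1, post_s = 5) {
  stopifnot(inherits(tr, "trace"))
  t <- trace_times(tr)
  eps <- 1e-9
  pre <- which(t >= onset_s - pre_s - eps & t < onset_s - eps)
  post <- which(t > onset_s + eps & t <= onset_s + post_s + eps)
  if (length(pre) == 0 || onset_s - pre_s < t[1] - eps)
    stop("baseline window clipped by trace start", call. = FALSE)
  if (length(post) == 0 || onset_s + post_s > t[length(t)] + 1 / tr$frame_rate)
    stop("peak window clipped by trace end", call. = FALSE)
  f_b <- mean(tr$values[pre])
  if (f_b <= 0) stop("baseline F_b <= 0: trace is not calibrated",
                     call. = FALSE)
  f_t <- max(tr$values[post])
  structure(list(peak_dff = (f_t - f_b) / f_b, f_t = f_t, f_b = f_b,
                 onset_s = onset_s), class = "peak_response")
}

#' Full delta-F/F time course
#'
#' (F(t) - F_pre) / F_pre for every frame, with F_pre the mean over a
#' baseline window preceding stimulation (as used per run before ROI
#' selection).
#'
#' @param tr a [trace()].
#' @param baseline_window numeric (t0, t1) in seconds; mean F over frames
#'   with t0 <= t < t1 is the baseline.
#' @return a `trace` of delta-F/F values.
#' @export
dff_timecourse <- function(tr, baseline_window) {
  stopifnot(inherits(tr, "trace"), length(baseline_window) == 2)
  t <- trace_times(tr)
  idx <- which(t >= baseline_window[1] - 1e-9 & t < baseline_window[2] - 1e-9)
  if (length(idx) == 0) stop("empty baseline window", call. = FALSE)
  f0 <- mean(tr$values[idx])
  if (f0 <= 0) stop("baseline F <= 0", call. = FALSE)
  tr$values <- (tr$values - f0) / f0
  tr
}

#' Per-event responses of a trace
#'
#' Convenience wrapper: smooths once, then computes [peak_dff()] for
#' every event row. Returns the event table with a `peak_dff` column.
#'
#' @param tr a [trace()].
#' @param events data.frame with at least `onset_s`.
#' @param pre_s,post_s windows, see [peak_dff()].
#' @param smooth_window Savitzky-Golay window (frames); NULL to skip.
#' @return `events` with an added `peak_dff` column.
#' @export
event_responses <- function(tr, events, pre_s = 1, post_s = 5,
                            smooth_window = 11L) {
  if (nrow(events) == 0) stop("empty event table", call. = FALSE)
  if (!is.null(smooth_window)) tr <- smooth_trace(tr, smooth_window)
  events$peak_dff <- vapply(events$onset_s, function(on)
    peak_dff(tr, on, pre_s, post_s)$peak_dff, numeric(1))
  events
}

#' Summarize peak responses across experimental conditions
#'
#' Group means and dispersion for e.g. before / during / after a
#' pharmacological manipulation. Significance testing is delegated to
#' the inferential layer ([wilcoxon_test()]).
#'
#' @param groups named list of numeric response vectors (>= 2 groups).
#' @return data.frame(condition, n, mean, sd, sem).
#' @export
condition_compare <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  data.frame(
    condition = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    sem = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)),
                 numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
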