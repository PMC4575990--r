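#' Imaging pipeline: movies to a normalized tuning curve
#'
#' Runs the full per-subject chain — segmentation (soma or neurite mode),
#' morphological cleanup, trace extraction, most-responding-ROI
#' selection, Savitzky-Golay smoothing, event-locked peak delta-F/F —
#' then pools subjects into a per-fly-max-normalized tuning curve over
#' the event axis.
#'
#' @param movies named list of [movie()] objects, one per subject.
#' @param events data.frame with `onset_s`, `ipi` (and optionally
#'   `level_db`), shared across subjects.
#' @param mode segmentation mode: "soma" or "neurite".
#' @param axis which event column indexes the tuning curve ("ipi" or
#'   "level_db").
#' @param seed k-means seed.
#' @param cleanup_radius opening radius (px).
#' @param smooth_window Savitzky-Golay window (frames).
#' @param pre_s,post_s delta-F/F windows (s).
#' @param normalize per-subject max normalization of the pooled curve.
#' @return list: `tuning` (a `tuning_curve`), `responses` (long
#'   data.frame), `roi_ids`, `masks`, `params`.
#' @export
run_imaging_pipeline <- function(movies, events, mode = c("soma", "neurite"),
                                 axis = "ipi", seed = 1L,
                                 cleanup_radius = 1L, smooth_window = 11L,
                                 pre_s = 1, post_s = 5, normalize = TRUE) {
  mode <- match.arg(mode)
  if (is.null(events) || nrow(events) == 0)
    stop("empty event table", call. = FALSE)
  if (!axis %in% names(events))
    stop(sprintf("events lack an `%s` column", axis), call. = FALSE)
  if (is.null(names(movies)))
    names(movies) <- paste0("subject", seq_along(movies))
  responses <- list()
  masks <- list()
  roi_ids <- integer(0)
  for (nm in names(movies)) {
    mov <- movies[[nm]]
    mask <- if (mode == "soma") segment_soma(mov, seed = seed)
            else segment_neurite(mov, seed = seed, events = events)
    mask <- cleanup_mask(mask, cleanup_radius)
    if (n_rois(mask) == 0)
      stop(sprintf("no ROI found for subject '%s'", nm), call. = FALSE)
    traces <- extract_traces(mov, mask)
    best <- most_responding_roi(traces, events, pre_s, post_s, smooth_window)
    tr <- traces[[paste0("roi", best)]]
    resp <- event_responses(tr, events, pre_s, post_s, smooth_window)
    responses[[nm]] <- data.frame(subject = nm,
                                  condition = resp[[axis]],
                                  value = resp$peak_dff,
                                  stringsAsFactors = FALSE)
    masks[[nm]] <- mask
    roi_ids[nm] <- best
  }
  long <- do.call(rbind, responses)
  # one value per subject x condition: average repeats of a condition
  agg <- stats::aggregate(value ~ subject + condition, long, mean)
  curve <- build_tuning(agg, axis = axis)
  if (normalize) curve <- normalize_per_subject(curve)
  list(tuning = curve, responses = long, roi_ids = roi_ids, masks = masks,
       params = list(mode = mode, axis = axis, seed = seed,
                     cleanup_radius = cleanup_radius,
                     smooth_window = smooth_window, pre_s = pre_s,
                     post_s = post_s, normalize = normalize))
}

#' Behavior pipeline: chain counts to chaining-index summaries
#'
#' Computes per-group chaining indices on the protocol's 30-s grid, the
#' group heat map, and — when the protocol defines a song window —
#' per-group summed CI over that window.
#'
#' @param series_list list of [chain_count_series()], one per group.
#' @param protocol optional `stimulus_protocol` for window alignment;
#'   its metadata supplies the song window (intermittent) or the level
#'   blocks (ramp).
#' @param block_s chaining-index block (s).
#' @return list: `ci` (list of `chaining_result`), `heatmap`
#'   (groups x blocks), `summed` (per-group summed CI over the song
#'   window, if defined), `per_level` (ramp protocols: groups x levels CI
#'   matrix).
#' @export
run_behavior_pipeline <- function(series_list, protocol = NULL,
                                  block_s = 30) {
  if (length(series_list) == 0) stop("no groups", call. = FALSE)
  ci <- lapply(series_list, chaining_index, block_s = block_s)
  hm <- chaining_heatmap(ci)
  out <- list(ci = ci, heatmap = hm)
  if (!is.null(protocol)) {
    md <- protocol$metadata
    if (identical(md$kind, "intermittent")) {
      win <- unlist(md$song_window)
      out$summed <- vapply(ci, summed_ci, numeric(1), window = win)
    }
    if (identical(md$kind, "ramp")) {
      lead <- md$lead_silence_s %||% 0
      levels_db <- unlist(md$levels_db)
      bl <- md$block_s %||% block_s
      per_level <- vapply(seq_along(levels_db), function(i) {
        win <- lead + c((i - 1) * bl, i * bl)
        vapply(ci, summed_ci, numeric(1), window = win)
      }, numeric(length(ci)))
      per_level <- matrix(per_level, nrow = length(ci),
                          dimnames = list(names(ci) %||% NULL,
                                          as.character(levels_db)))
      out$per_level <- per_level
    }
  }
  out
}

#' Correlation report: neural tuning versus behavior
#'
#' Aligns each neural tuning curve with the behavioral curve on their
#' shared conditions, max-normalizes the group means, and reports the
#' Pearson correlation with a permutation p-value per curve. When
#' exactly two neural curves are given, they are compared with Meng's
#' z-test using as r_x the correlation between the two neural curves
#' over their shared conditions and n = the number of shared conditions.
#'
#' @param neural_curves named list of `tuning_curve`s.
#' @param behavior_curve a `tuning_curve` (behavioral tuning).
#' @param n_perm,seed,sided passed to [permutation_corr_test()].
#' @param meng_sided sidedness for Meng's z.
#' @return list: `correlations` (data.frame curve, r, p, n_shared,
#'   exhaustive), `permutations` (list of `permutation_result`), `meng`
#'   (a `meng_result` or NULL).
#' @export
run_correlation_report <- function(neural_curves, behavior_curve,
                                   n_perm = 10000L, seed = 1L,
                                   sided = "greater",
                                   meng_sided = "two.sided") {
  stopifnot(length(neural_curves) >= 1,
            inherits(behavior_curve, "tuning_curve"))
  if (is.null(names(neural_curves)))
    names(neural_curves) <- paste0("curve", seq_along(neural_curves))
  norm_max <- function(v) v / max(v)
  perms <- list()
  rows <- list()
  aligned <- list()
  for (nm in names(neural_curves)) {
    cv <- neural_curves[[nm]]
    shared <- intersect(cv$conditions, behavior_curve$conditions)
    if (length(shared) < 4)
      stop(sprintf("curve '%s' shares < 4 conditions with behavior", nm),
           call. = FALSE)
    x <- norm_max(cv$mean[match(shared, cv$conditions)])
    y <- norm_max(behavior_curve$mean[match(shared,
                                            behavior_curve$conditions)])
    pr <- permutation_corr_test(x, y, n_perm = n_perm, seed = seed,
                                sided = sided)
    perms[[nm]] <- pr
    aligned[[nm]] <- list(shared = shared, x = x, y = y)
    rows[[nm]] <- data.frame(curve = nm, r = pr$r_observed,
                             p = pr$p_value, n_shared = length(shared),
                             exhaustive = pr$exhaustive,
                             stringsAsFactors = FALSE)
  }
  meng <- NULL
  if (length(neural_curves) == 2) {
    a <- aligned[[1]]; b <- aligned[[2]]
    shared_n <- intersect(a$shared, b$shared)
    if (length(shared_n) >= 4) {
      r_x <- pearson_r(
        a$x[match(shared_n, a$shared)],
        b$x[match(shared_n, b$shared)])
      meng <- meng_z(rows[[1]]$r, rows[[2]]$r, r_x, length(shared_n),
                     sided = meng_sided)
    }
  }
  list(correlations = do.call(rbind, c(rows, make.row.names = FALSE)),
       permutations = perms, meng = meng)
}
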