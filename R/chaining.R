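#' Time series of chain counts for one group of flies
#'
#' Counts of flies engaged in chaining, scored as snapshots on a regular
#' grid (every 3 s in the assay), for a group of `group_size` males.
#'
#' @param time_s sample times (s), regular grid.
#' @param counts integer counts, 0..group_size, one per sample.
#' @param group_size flies per arena (default 6).
#' @return a `chain_count_series` (data.frame with attributes `dt`,
#'   `group_size`).
#' @export
chain_count_series <- function(time_s, counts, group_size = 6L) {
  if (length(time_s) != length(counts))
    stop("`time_s` and `counts` must have equal length", call. = FALSE)
  if (length(time_s) < 1) stop("empty series", call. = FALSE)
  if (length(time_s) > 1) {
    dts <- diff(time_s)
    if (any(abs(dts - dts[1]) > 1e-9))
      stop("sampling must be regular (constant interval)", call. = FALSE)
    dt <- dts[1]
  } else dt <- NA_real_
  if (any(counts < 0 | counts > group_size | counts != round(counts)))
    stop(sprintf("counts must be integers in 0..%d", group_size),
         call. = FALSE)
  structure(data.frame(time_s = time_s, count = as.integer(counts)),
            dt = dt, group_size = as.integer(group_size),
            class = c("chain_count_series", "data.frame"))
}

#' Chaining index per block
#'
#' Sums the per-sample chain counts within consecutive blocks (default
#' 30 s). With 3-s sampling and six flies the maximum chaining index per
#' 30-s block is 10 samples x 6 flies = 60. Blocks tile the series from
#' its first sample; a partial trailing block is dropped.
#'
#' @param series a [chain_count_series()].
#' @param block_s block length (s); must be a multiple of the sampling
#'   interval.
#' @return a `chaining_result`: data.frame(block_start_s, ci) with
#'   attributes `block_s`, `dt`, `group_size`, `max_ci`.
#' @export
chaining_index <- function(series, block_s = 30) {
  stopifnot(inherits(series, "chain_count_series"))
  dt <- attr(series, "dt")
  if (is.na(dt)) stop("need at least two samples to infer the interval",
                      call. = FALSE)
  per_block <- block_s / dt
  if (abs(per_block - round(per_block)) > 1e-9)
    stop("`block_s` must be a multiple of the sampling interval",
         call. = FALSE)
  per_block <- round(per_block)
  n_blocks <- length(series$count) %/% per_block
  if (n_blocks == 0) stop("series shorter than one block", call. = FALSE)
  idx <- seq_len(n_blocks * per_block)
  block <- rep(seq_len(n_blocks), each = per_block)
  ci <- as.integer(tapply(series$count[idx], block, sum))
  starts <- series$time_s[1] + (seq_len(n_blocks) - 1) * block_s
  structure(data.frame(block_start_s = starts, ci = ci),
            block_s = block_s, dt = dt,
            group_size = attr(series, "group_size"),
            max_ci = as.integer(per_block * attr(series, "group_size")),
            class = c("chaining_result", "data.frame"))
}

#' Heat-map matrix of chaining across groups
#'
#' One row per group of flies, one column per 3-s sample (counts) or per
#' block (chaining indices), as used to summarize chaining time courses.
#'
#' @param results a list of [chain_count_series()] (with
#'   `per_sample = TRUE`) or of [chaining_index()] results.
#' @param per_sample if TRUE rows are raw per-sample counts; otherwise
#'   per-block chaining indices.
#' @return numeric matrix, groups x time bins.
#' @export
chaining_heatmap <- function(results, per_sample = FALSE) {
  if (length(results) == 0) stop("no groups", call. = FALSE)
  vals <- lapply(results, function(r) {
    if (per_sample) {
      stopifnot(inherits(r, "chain_count_series")); r$count
    } else {
      stopifnot(inherits(r, "chaining_result")); r$ci
    }
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1)
    stop("all groups must have equal-length series", call. = FALSE)
  m <- do.call(rbind, vals)
  rownames(m) <- names(results) %||% paste0("group", seq_along(results))
  m
}

#' Summed chaining index over a time window
#'
#' Sums the chaining index over blocks lying fully inside
#' \[window\[1\], window\[2\]\] — e.g. the song-presentation window of an
#' intermittent protocol. Partial overlap does not count.
#'
#' @param result a [chaining_index()] result.
#' @param window numeric length-2, (t0, t1) in seconds.
#' @return integer summed CI.
#' @export
summed_ci <- function(result, window) {
  stopifnot(inherits(result, "chaining_result"), length(window) == 2)
  block_s <- attr(result, "block_s")
  inside <- result$block_start_s >= window[1] - 1e-9 &
    result$block_start_s + block_s <= window[2] + 1e-9
  sum(result$ci[inside])
}

#' Fraction of time with a chain of at least `threshold` flies
#'
#' The chain-fraction metric: the proportion of 3-s samples at which at
#' least `threshold` flies (default 3) are in a courtship chain, as used
#' to score optogenetically induced chaining.
#'
#' @param series a [chain_count_series()].
#' @param threshold minimum flies in chain (<= group size).
#' @return proportion in \[0, 1\].
#' @export
chain_fraction <- function(series, threshold = 3L) {
  stopifnot(inherits(series, "chain_count_series"))
  if (threshold > attr(series, "group_size"))
    stop("`threshold` exceeds group size", call. = FALSE)
  mean(series$count >= threshold)
}
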