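#' Calcium-imaging movie container
#'
#' A T-frame grayscale movie stored as an H x W x T array with a frame
#' rate (nominal 13 frames/s in the study's confocal recordings).
#' Coordinates are row-major and 1-based (R convention), pixel-center.
#'
#' @param frames numeric array, H x W x T, non-negative finite.
#' @param frame_rate frames per second.
#' @return an object of class `movie`.
#' @export
movie <- function(frames, frame_rate = 13) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("`frames` must be an H x W x T array", call. = FALSE)
  if (dim(frames)[3] < 2) stop("movie needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames))) stop("frames contain non-finite values",
                                    call. = FALSE)
  stop_if_not_scalar_pos(frame_rate, "frame_rate")
  structure(list(frames = frames, frame_rate = frame_rate), class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie> %d x %d px, %d frames @ %g Hz (%.3g s)\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate))
  invisible(x)
}

#' Time-averaged intensity image of a movie
#' @param mov a [movie()].
#' @return H x W matrix of per-pixel mean intensity.
#' @export
mean_image <- function(mov) {
  d <- dim(mov$frames)
  matrix(rowMeans(matrix(mov$frames, d[1] * d[2], d[3])), d[1], d[2])
}

pixel_trace_matrix <- function(mov) {
  d <- dim(mov$frames)
  matrix(mov$frames, d[1] * d[2], d[3])
}

new_roi_mask <- function(labels, method, params = list()) {
  structure(labels, method = method, params = params,
            class = c("roi_mask", class(labels)))
}

label_components <- function(binary) {
  # connected-component labeling; EBImage returns an Image, coerce back
  lab <- EBImage::bwlabel(binary)
  matrix(as.integer(round(as.numeric(lab))), nrow(binary), ncol(binary))
}

relabel_mask <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- array(0L, dim(labels))
  for (i in seq_along(ids)) out[labels == ids[i]] <- i
  out
}

#' Number of ROIs in a mask
#' @param mask a `roi_mask`.
#' @return integer count of labeled regions.
#' @export
n_rois <- function(mask) length(setdiff(unique(as.integer(mask)), 0L))

#' Segment cell bodies from the time-averaged image
#'
#' Soma segmentation: k-means clustering of the per-pixel time-averaged
#' intensities; the brightest cluster becomes foreground and its connected
#' components are labeled as individual ROIs. k defaults to 2
#' (foreground/background); initialization is a seeded multi-start so the
#' mask is reproducible bit-for-bit.
#'
#' @param mov a [movie()].
#' @param k number of intensity clusters (>= 2).
#' @param seed RNG seed for the k-means multi-start.
#' @param n_fg how many of the brightest clusters count as foreground.
#' @return a `roi_mask` (H x W integer label matrix, 0 = background,
#'   labels contiguous 1..K). A constant image yields an empty mask with
#'   a warning.
#' @export
segment_soma <- function(mov, k = 2L, seed = 1L, n_fg = 1L) {
  stopifnot(inherits(mov, "movie"))
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  img <- mean_image(mov)
  if (stats::sd(img) == 0 || length(unique(as.vector(img))) < k) {
    warning("degenerate movie (constant average image); returning empty mask")
    return(new_roi_mask(array(0L, dim(img)), "soma",
                        list(k = k, seed = seed, status = "degenerate")))
  }
  km <- with_seed(seed, stats::kmeans(as.vector(img), centers = k,
                                      nstart = 10, iter.max = 100))
  fg_clusters <- order(km$centers, decreasing = TRUE)[seq_len(n_fg)]
  fg <- matrix(as.integer(km$cluster %in% fg_clusters), nrow(img), ncol(img))
  labels <- relabel_mask(label_components(fg))
  new_roi_mask(labels, "soma", list(k = k, seed = seed, n_fg = n_fg))
}

#' Segment neurites from per-pixel time traces
#'
#' Neurite segmentation: each pixel's T-long trace is z-scored (so
#' response kinetics, not brightness, drive the clustering) and clustered
#' by k-means into `k` clusters (default 3). The cluster whose centroid
#' trace has the largest variance is taken as the responding pixel set —
#' averaging incoherent noise traces cancels to a flat centroid, while a
#' shared transient survives — and its connected components are labeled.
#' If `events` is supplied, centroid variance is evaluated within the
#' response windows only.
#'
#' @param mov a [movie()].
#' @param k number of trace clusters (default 3).
#' @param seed RNG seed for the k-means multi-start.
#' @param events optional data.frame with `onset_s`, used to restrict the
#'   coherence score to stimulus-locked windows.
#' @param response_s window after each onset scored for coherence (s).
#' @return a `roi_mask`. All-identical traces yield an empty mask with a
#'   warning.
#' @export
segment_neurite <- function(mov, k = 3L, seed = 1L, events = NULL,
                            response_s = 5) {
  stopifnot(inherits(mov, "movie"))
  d <- dim(mov$frames)
  if (d[3] < 3) stop("need at least 3 frames", call. = FALSE)
  x <- pixel_trace_matrix(mov)
  mu <- rowMeans(x)
  sdv <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  if (all(sdv == 0)) {
    warning("all pixel traces are constant; returning empty mask")
    return(new_roi_mask(array(0L, d[1:2]), "neurite",
                        list(k = k, seed = seed, status = "degenerate")))
  }
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = 10,
                                      iter.max = 100))
  frames_idx <- seq_len(d[3])
  if (!is.null(events) && nrow(events) > 0) {
    t <- (frames_idx - 1) / mov$frame_rate
    keep <- rep(FALSE, d[3])
    for (on in events$onset_s) keep <- keep | (t >= on & t <= on + response_s)
    if (any(keep)) frames_idx <- which(keep)
  }
  coher <- apply(km$centers[, frames_idx, drop = FALSE], 1, stats::var)
  best <- which.max(coher)
  fg <- matrix(as.integer(km$cluster == best), d[1], d[2])
  labels <- relabel_mask(label_components(fg))
  out <- new_roi_mask(labels, "neurite", list(k = k, seed = seed))
  # full cluster assignment, for inspecting how kinetics groups separate
  attr(out, "clusters") <- matrix(km$cluster, d[1], d[2])
  out
}

#' Morphological cleanup of an ROI mask
#'
#' Erosion followed by dilation (binary opening) applied per ROI with a
#' square structuring element of side `2*radius + 1`, removing speckle
#' and thin bridges. Pieces that disconnect are split into separate ROIs;
#' emptied ROIs are dropped and labels renumbered contiguously (ordered
#' by original label, then component). Opening is idempotent, so
#' `cleanup_mask(cleanup_mask(m))` equals `cleanup_mask(m)`.
#'
#' @param mask a `roi_mask`.
#' @param radius structuring-element radius in pixels (>= 1).
#' @return a cleaned `roi_mask`.
#' @export
cleanup_mask <- function(mask, radius = 1L) {
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "box")
  out <- array(0L, dim(mask))
  nxt <- 0L
  for (id in sort(unique(mask[mask > 0]))) {
    bin <- matrix(as.numeric(mask == id), nrow(mask), ncol(mask))
    opened <- EBImage::opening(bin, brush)
    comp <- label_components(matrix(as.numeric(opened) > 0.5,
                                    nrow(mask), ncol(mask)))
    for (c_id in sort(unique(comp[comp > 0]))) {
      nxt <- nxt + 1L
      out[comp == c_id] <- nxt
    }
  }
  new_roi_mask(out, attr(mask, "method") %||% "unknown",
               c(attr(mask, "params"), list(cleanup_radius = radius)))
}

#' Mean-intensity trace of each ROI
#'
#' trace_k\[t\] = mean over pixels with label k of frame t. Background
#' (label 0) is never included.
#'
#' @param mov a [movie()].
#' @param mask a `roi_mask` matching the frame size.
#' @return named list of `trace` objects (`values`, `frame_rate`,
#'   `roi_id`), one per ROI label.
#' @export
extract_traces <- function(mov, mask) {
  d <- dim(mov$frames)
  if (!all(dim(mask)[1:2] == d[1:2]))
    stop("mask shape does not match movie frames", call. = FALSE)
  x <- pixel_trace_matrix(mov)
  ids <- sort(unique(as.integer(mask[mask > 0])))
  out <- lapply(ids, function(id) {
    px <- which(as.integer(mask) == id)
    structure(list(values = colMeans(x[px, , drop = FALSE]),
                   frame_rate = mov$frame_rate, roi_id = id),
              class = "trace")
  })
  names(out) <- paste0("roi", ids)
  out
}

#' Select the most responsive ROI
#'
#' Returns the ROI whose smoothed trace has the largest mean peak
#' delta-F/F across stimulus events (only the most responding ROI is kept
#' for further analysis). Ties break to the lowest ROI id.
#'
#' @param traces list of `trace` objects (from [extract_traces()]).
#' @param events data.frame with `onset_s`.
#' @param pre_s,post_s baseline / peak windows (s), see [peak_dff()].
#' @param smooth_window Savitzky-Golay window (frames); NULL to skip
#'   smoothing.
#' @return the selected `roi_id` (integer).
#' @export
most_responding_roi <- function(traces, events, pre_s = 1, post_s = 5,
                                smooth_window = 11L) {
  if (length(traces) == 0) stop("no traces", call. = FALSE)
  score <- vapply(traces, function(tr) {
    if (!is.null(smooth_window)) tr <- smooth_trace(tr, smooth_window)
    mean(vapply(events$onset_s,
                function(on) peak_dff(tr, on, pre_s, post_s)$peak_dff,
                numeric(1)))
  }, numeric(1))
  ids <- vapply(traces, `[[`, integer(1), "roi_id")
  best <- which(score == max(score))
  unname(ids[best[which.min(ids[best])]])
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages scaled by `scale` (default 1);
#' the frame rate is not carried by the TIFF and must be supplied on
#' read.
#'
#' @param mov a [movie()].
#' @param path file path.
#' @param frame_rate frames/s for the read-back movie.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   a [movie()].
#' @export
write_movie_tiff <- function(mov, path) {
  d <- dim(mov$frames)
  pages <- lapply(seq_len(d[3]), function(t) mov$frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_rate = 13) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  movie(arr, frame_rate)
}
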