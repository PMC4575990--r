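test_that("soma segmentation recovers planted blobs and is deterministic", {
  truth <- soma_truth(seed = 3)
  mov <- simulate_movie(truth, events = NULL, duration_s = 3)
  m1 <- cleanup_mask(segment_soma(mov, seed = 7))
  expect_equal(n_rois(m1), 2L)
  tm <- truth_masks(truth)
  expect_gte(mask_iou(m1, tm, 1), 0.8)
  expect_gte(mask_iou(m1, tm, 2), 0.8)
  # same movie + seed twice: bit-identical mask
  m2 <- cleanup_mask(segment_soma(mov, seed = 7))
  expect_identical(as.integer(m1), as.integer(m2))
  # labels contiguous positive range
  expect_identical(sort(unique(as.integer(m1[m1 > 0]))),
                   seq_len(n_rois(m1)))
})

test_that("a constant movie yields an empty soma mask with a warning", {
  mov <- movie(array(5, c(16, 16, 4)))
  expect_warning(m <- segment_soma(mov), "degenerate")
  expect_equal(n_rois(m), 0L)
})

test_that("neurite segmentation finds a planted coherent band and separates kinetics", {
  # 32 x 32, 60 frames: a horizontal band shares one transient
  h <- 32; w <- 32; nt <- 60
  set.seed(9)
  kern <- gcamp_kernel()
  t <- (seq_len(nt) - 1) / 13
  sig <- eval_kernel(kern, t - 1.5)
  arr <- array(100 + rnorm(h * w * nt, 0, 1), c(h, w, nt))
  band <- 14:18
  for (r in band) for (k in seq_len(nt))
    arr[r, , k] <- arr[r, , k] + 40 * sig[k]
  mov <- movie(arr, 13)
  mask <- cleanup_mask(segment_neurite(mov, seed = 2))
  planted <- array(FALSE, c(h, w)); planted[band, ] <- TRUE
  covered <- sum(mask[planted] > 0) / sum(planted)
  expect_gte(covered, 0.8)
  # found ROI should not leak far outside the band
  expect_lt(sum(mask[!planted] > 0), 0.05 * h * w)
})

test_that("neurite segmentation on pure i.i.d. noise leaves <= 1% ROI area", {
  set.seed(5)
  arr <- array(100 + rnorm(32 * 32 * 60), c(32, 32, 60))
  mask <- cleanup_mask(segment_neurite(movie(arr, 13), seed = 1))
  expect_lte(sum(mask > 0) / (32 * 32), 0.01)
})

test_that("three planted kinetics groups are separated by the trace clustering", {
  h <- 30; w <- 30; nt <- 90
  set.seed(11)
  t <- (seq_len(nt) - 1) / 13
  kinetics <- rbind(eval_kernel(gcamp_kernel(0.05, 0.3), t - 1),
                    eval_kernel(gcamp_kernel(0.3, 2.0), t - 3),
                    sin(2 * pi * 0.8 * t))
  groups <- matrix(rep(1:3, each = h * w / 3), h, w)  # three column bands
  arr <- array(rnorm(h * w * nt, 0, 0.5), c(h, w, nt))
  for (g in 1:3) {
    px <- which(groups == g, arr.ind = TRUE)
    for (i in seq_len(nrow(px)))
      arr[px[i, 1], px[i, 2], ] <- arr[px[i, 1], px[i, 2], ] +
        100 + 10 * kinetics[g, ]
  }
  mask <- segment_neurite(movie(arr, 13), seed = 4)
  found <- as.vector(attr(mask, "clusters"))
  ari <- mclust::adjustedRandIndex(found, as.vector(groups))
  expect_gte(ari, 0.9)
})

test_that("mask cleanup removes speckle, preserves large regions, and is idempotent", {
  m <- array(0L, c(40, 40))
  # large disk, radius 8
  for (r in 1:40) for (cc in 1:40)
    if ((r - 15)^2 + (cc - 15)^2 <= 64) m[r, cc] <- 1L
  m[1, 1] <- 2L; m[38, 3] <- 2L                # isolated speckles
  mask <- structure(m, class = c("roi_mask", "matrix"), method = "manual")
  cleaned <- cleanup_mask(mask, radius = 1)
  expect_equal(n_rois(cleaned), 1L)            # speckles gone
  area_before <- sum(m == 1L); area_after <- sum(cleaned > 0)
  expect_lt(abs(area_after - area_before) / area_before, 0.05)
  twice <- cleanup_mask(cleaned, radius = 1)
  expect_identical(as.integer(cleaned), as.integer(twice))
})

test_that("traces are per-ROI means, independent across disjoint ROIs", {
  arr <- array(2, c(8, 8, 5))
  arr[1:2, 1:2, ] <- 10
  arr[7:8, 7:8, 3] <- 100
  mask <- array(0L, c(8, 8)); mask[1:2, 1:2] <- 1L; mask[7:8, 7:8] <- 2L
  tr <- extract_traces(movie(arr, 13), mask)
  expect_equal(tr$roi1$values, rep(10, 5))
  # perturbing ROI 2's pixels never touches ROI 1's trace
  expect_equal(tr$roi2$values, c(2, 2, 100, 2, 2))
  # constant movie -> constant trace at the constant
  flat <- movie(array(7, c(8, 8, 4)))
  expect_equal(extract_traces(flat, mask)$roi1$values, rep(7, 4))
  expect_error(extract_traces(movie(arr), array(0L, c(4, 4))), "shape")
})

test_that("the most responsive ROI is selected, ties break to the lowest id", {
  t <- (0:129) / 13
  resp <- function(amp) 100 * (1 + amp * eval_kernel(gcamp_kernel(), t - 3))
  events <- data.frame(onset_s = 3)
  traces <- list(roi1 = trace(resp(0.2), 13, 1L),
                 roi2 = trace(resp(0.8), 13, 2L),
                 roi3 = trace(rep(100, 130), 13, 3L))
  expect_equal(most_responding_roi(traces, events), 2L)
  # flat vs responsive
  expect_equal(most_responding_roi(traces[c(1, 3)], events), 1L)
  # exact tie -> lowest id
  tied <- list(roi4 = trace(resp(0.5), 13, 4L),
               roi2 = trace(resp(0.5), 13, 2L))
  expect_equal(most_responding_roi(tied, events), 2L)
})

test_that("movies round-trip through multi-page TIFF", {
  truth <- soma_truth(seed = 2)
  mov <- simulate_movie(truth, events = NULL, duration_s = 1.2)
  # float TIFF stores [0, 1]; scale down for the round trip
  scaled <- movie(mov$frames / 1000, mov$frame_rate)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(scaled, path)
  back <- read_movie_tiff(path, frame_rate = 13)
  expect_equal(dim(back$frames), dim(scaled$frames))
  expect_lt(max(abs(back$frames - scaled$frames)), 1e-6)
})
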