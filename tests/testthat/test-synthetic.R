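test_that("tuning models have the planted shapes", {
  lp <- tuning_model("low_pass_hill", K = 25, n_hill = 4)
  v <- eval_tuning(lp, default_ipi_grid)
  expect_true(all(diff(v) > 0))                  # monotone rise
  expect_gt(eval_tuning(lp, 95) / lp$r_max, 0.9) # saturates high
  expect_equal(eval_tuning(lp, 25), lp$r_max / 2)  # half-max at K
  bp <- tuning_model("band_pass_gaussian", center = 50, width = 15,
                     baseline = 0.05)
  vb <- eval_tuning(bp, default_ipi_grid)
  expect_equal(default_ipi_grid[which.max(vb)], 45)  # nearest grid point
  expect_lt(vb[1], max(vb)); expect_lt(vb[length(vb)], max(vb))
})

test_that("the calcium kernel rises then decays with unit peak", {
  k <- gcamp_kernel(0.08, 0.6)
  t <- seq(0, 5, by = 0.01)
  v <- eval_kernel(k, t)
  expect_equal(max(v), 1, tolerance = 1e-4)
  expect_equal(eval_kernel(k, -1), 0)
  pk <- t[which.max(v)]
  expect_gt(v[length(v)], 0); expect_lt(v[length(v)], 0.01)
  expect_true(all(diff(v[t < pk - 0.01]) > 0))
  expect_error(gcamp_kernel(0.6, 0.08), "rise_tau < decay_tau")
})

test_that("noise-free movies reproduce the planted transient through the pipeline", {
  truth <- synthetic_ground_truth(roi_centers = list(c(20, 20)),
                                  noise_sd = 0, amp_max = 0.8,
                                  tuning = tuning_model("band_pass_gaussian",
                                                        center = 50,
                                                        width = 15,
                                                        baseline = 0))
  ev <- data.frame(onset_s = 3, ipi = 50)     # at the tuning peak
  mov <- simulate_movie(truth, ev, duration_s = 10)
  tm <- truth_masks(truth)
  tr <- extract_traces(mov, tm)$roi1
  got <- peak_dff(tr, 3)$peak_dff
  # closed-form expectation: ROI-mean dF/F weighted by pixel brightness,
  # times the kernel maximum on the 13 Hz frame grid
  d <- dim(mov$frames)
  rows <- matrix(rep(1:64, 64), 64, 64); cols <- matrix(rep(1:64, each = 64), 64, 64)
  p <- exp(-((rows - 20)^2 + (cols - 20)^2) / (2 * 16))
  b <- 100 * (1 + 4 * p)
  w_mean <- sum((b * p)[tm == 1]) / sum(b[tm == 1])
  tgrid <- (seq_len(d[3]) - 1) / 13
  k_max <- max(eval_kernel(truth$kernel, tgrid - 3))
  expected <- 0.8 * w_mean * k_max
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("doubling the noise scale doubles the residual SD of extracted traces", {
  resid_sd <- function(nsd) {
    truth <- synthetic_ground_truth(noise_sd = nsd, seed = 12)
    mov <- simulate_movie(truth, NULL, duration_s = 6)
    tr <- extract_traces(mov, truth_masks(truth))$roi1
    sd(tr$values)
  }
  expect_equal(resid_sd(1.0) / resid_sd(0.5), 2, tolerance = 0.15)
})

test_that("movie generation is bit-identical under a fixed seed", {
  truth <- soma_truth(seed = 99)
  ev <- ipi_event_table(c(35, 55), gap_s = 6)
  m1 <- simulate_movie(truth, ev)
  m2 <- simulate_movie(truth, ev)
  expect_identical(m1$frames, m2$frames)
})

test_that("tuning tables recover the planted band-pass center", {
  m <- tuning_model("band_pass_gaussian", r_max = 1, center = 50,
                    width = 15, baseline = 0.05)
  # argmax lands in the 35-65 ms cells
  tab <- simulate_tuning_table(m, n_subjects = 12, seed = 5)
  cv <- build_tuning(tab)
  expect_true(cv$conditions[which.max(cv$mean)] %in% c(35, 45, 55, 65))
  # single subject, zero noise: table equals the model exactly
  exact <- simulate_tuning_table(m, n_subjects = 1, seed = 1,
                                 gain_sd = 0, noise_sd = 0)
  expect_equal(exact$value, eval_tuning(m, exact$condition))
  # Gaussian-fit center recovery within 10 ms (n = 12, 10% noise)
  centers <- sapply(1:20, function(s) {
    tab <- simulate_tuning_table(m, n_subjects = 12, seed = 100 + s,
                                 noise_sd = 0.1)
    cv <- build_tuning(tab)
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - c0)^2 / (2 * w^2)),
      data = data.frame(x = cv$conditions, y = cv$mean),
      start = list(b = 0, a = 1, c0 = 45, w = 20)),
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else coef(fit)[["c0"]]
  })
  expect_lte(median(abs(centers - 50), na.rm = TRUE), 10)
})

test_that("saturated chaining simulations hit the CI ceiling", {
  rp <- make_ramp_protocol(pulse_train_spec(), levels_db = c(110, 110),
                           block_s = 30, lead_silence_s = 0)
  gs <- simulate_chaining(rp, n_groups = 2, seed = 1, ec50 = 70.6,
                          slope_db = 1, ipi_weight = 0, p_silence = 0)
  for (g in gs) expect_true(all(chaining_index(g)$ci == 60))
})

test_that("ramp chaining recovers the planted behavioral EC50 within 2 dB", {
  rp <- make_ramp_protocol(pulse_train_spec())
  lv <- seq(60, 90, by = 2.5)
  errs <- sapply(1:20, function(s) {
    gs <- simulate_chaining(rp, n_groups = 14, seed = s)
    bh <- run_behavior_pipeline(gs, rp)
    fit <- fit_sigmoid(lv, colMeans(bh$per_level))
    abs(fit$ec50 - 70.6)
  })
  expect_lte(median(errs), 2)
})

test_that("IPI sweeps place the summed-CI peak at the conspecific 35 ms", {
  ipis <- c(15, 20, 25, 35, 45, 55, 65, 75, 85, 95)
  hits <- sapply(1:20, function(s) {
    sums <- sapply(ipis, function(ipi) {
      ip <- make_intermittent_protocol(pulse_train_spec(ipi = ipi))
      gs <- simulate_chaining(ip, n_groups = 15, seed = s * 1000 + ipi)
      mean(run_behavior_pipeline(gs, ip)$summed)
    })
    ipis[which.max(sums)] == 35
  })
  expect_gte(mean(hits), 0.8)
})

test_that("chaining decays gradually after song offset", {
  ip <- make_intermittent_protocol(pulse_train_spec(level_db = 90))
  gs <- simulate_chaining(ip, n_groups = 20, seed = 2, decay_tau_s = 30)
  hm <- chaining_heatmap(lapply(gs, chaining_index))
  blocks <- colMeans(hm)
  # song window spans blocks 3..6 (60-180 s); tail blocks decline
  expect_gt(mean(blocks[3:6]), mean(blocks[7:8]))
  expect_gt(mean(blocks[7:8]), mean(blocks[1:2]))
  expect_gt(blocks[7], blocks[8])
})
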