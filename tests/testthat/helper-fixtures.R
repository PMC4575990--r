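# Shared fixture builders. Everything is generated in code; seeds are fixed
# inside the builders so every test sees the same data.

default_ipi_grid <- seq(15, 95, by = 10)

# events: one stimulus per IPI, spaced so the 1 s + 5 s dF/F windows fit
ipi_event_table <- function(ipis = default_ipi_grid, gap_s = 8,
                            lead_s = 2, level_db = 80) {
  data.frame(onset_s = lead_s + (seq_along(ipis) - 1) * gap_s,
             ipi = ipis, level_db = level_db)
}

# small two-blob soma movie with a band-pass tuned transient
soma_truth <- function(seed = 1L, noise_sd = 0.5,
                       tuning = tuning_model("band_pass_gaussian")) {
  synthetic_ground_truth(dims = c(64, 64),
                         roi_centers = list(c(20, 20), c(44, 40)),
                         roi_sigma = 4, baseline = 100, contrast = 4,
                         amp_max = 1, tuning = tuning,
                         noise_sd = noise_sd, seed = seed)
}

# IoU between one planted label and the best-overlapping found label
mask_iou <- function(found, truth, truth_id) {
  t <- truth == truth_id
  labs <- table(found[t & found > 0])
  if (!length(labs)) return(0)
  l <- as.integer(names(which.max(labs)))
  m <- found == l
  sum(t & m) / sum(t | m)
}

# independent permutation enumerator (list of integer vectors), used as an
# oracle against the package's vectorized enumeration
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in combinat_perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

# brute-force one-sided rank-sum p: enumerate all C(n1+n2, n1) group
# assignments of the pooled ranks (independent of stats::wilcox.test)
rank_sum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2, function(idx) sum(ranks[idx]))
  mean(stats >= obs)   # one-sided: a tends larger
}

# bootstrap-over-subjects SEM of a ratio-of-means transfer function
bootstrap_transfer_sem <- function(num_tab, den_tab, n_boot = 500,
                                   seed = 1L) {
  cn <- build_tuning(num_tab); cd <- build_tuning(den_tab)
  set.seed(seed)
  reps <- replicate(n_boot, {
    ni <- sample(nrow(cn$per_subject), replace = TRUE)
    di <- sample(nrow(cd$per_subject), replace = TRUE)
    colMeans(cn$per_subject[ni, , drop = FALSE]) /
      colMeans(cd$per_subject[di, , drop = FALSE])
  })
  apply(reps, 1, sd)
}
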