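#' Pearson product-moment correlation
#'
#' Thin guard around `stats::cor` for the tuning-curve correlations:
#' requires n >= 3 and non-degenerate variance in both inputs.
#'
#' @param x,y equal-length numeric vectors (condition means).
#' @return correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  stats::cor(x, y)
}

all_permutations <- function(n) {
  # n! x n matrix of all permutations of 1:n (lexicographic), n <= 9
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1] <- i
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

perm_corrs <- function(x, y, perms) {
  # r for x vs y[perm] across rows of `perms`, vectorized
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  y_mat <- matrix(yc[t(perms)], ncol = n, byrow = TRUE)
  as.vector(y_mat %*% xc) / denom
}

#' Permutation test for a tuning-curve correlation
#'
#' Tests the Pearson correlation between two condition-mean series
#' (e.g. normalized neural and behavioral IPI tuning) against the null
#' distribution obtained by randomly permuting the condition labels of
#' one series. When n! <= `exhaustive_limit` (default 5e5, i.e. n <= 9)
#' the null is enumerated exhaustively and the p-value is exact and
#' seed-independent; otherwise a seeded Monte-Carlo sample of
#' `n_perm` permutations is drawn and the add-one-corrected p-value
#' (1 + hits) / (1 + n_perm) is reported. `replace = TRUE` switches to
#' resampling labels with replacement (a bootstrap-style null) instead
#' of permutation.
#'
#' @param x,y equal-length condition means (already aligned on their
#'   shared condition axis).
#' @param n_perm Monte-Carlo permutations (ignored on the exhaustive
#'   path).
#' @param seed RNG seed; required for the Monte-Carlo path.
#' @param sided "greater" (positive correlation, default), "less", or
#'   "two.sided".
#' @param exhaustive force (TRUE/FALSE) or auto-select (NULL) exhaustive
#'   enumeration.
#' @param exhaustive_limit largest n! enumerated.
#' @param replace resample labels with replacement instead of permuting.
#' @return a `permutation_result`: r_observed, p_value, n_perm,
#'   exhaustive, seed, sided, null_mean, null_sd.
#' @export
permutation_corr_test <- function(x, y, n_perm = 10000L, seed = NULL,
                                  sided = c("greater", "less", "two.sided"),
                                  exhaustive = NULL,
                                  exhaustive_limit = 5e5,
                                  replace = FALSE) {
  sided <- match.arg(sided)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) warning("n < 4: permutation p-values are extremely granular")
  r_obs <- pearson_r(x, y)
  if (is.null(exhaustive)) exhaustive <- !replace && factorial(n) <= exhaustive_limit
  eps <- 1e-12
  if (exhaustive) {
    if (replace) stop("exhaustive enumeration is a permutation null; use replace = FALSE",
                      call. = FALSE)
    perms <- all_permutations(n)
    r_null <- perm_corrs(x, y, perms)
    n_used <- nrow(perms)
    hits <- switch(sided,
                   greater = sum(r_null >= r_obs - eps),
                   less = sum(r_null <= r_obs + eps),
                   two.sided = sum(abs(r_null) >= abs(r_obs) - eps))
    p <- hits / n_used
  } else {
    if (is.null(seed)) stop("Monte-Carlo path requires a `seed`",
                            call. = FALSE)
    r_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- if (replace) sample.int(n, n, replace = TRUE)
               else sample.int(n, n)
        yy <- y[idx]
        if (stats::sd(yy) == 0) return(0)
        stats::cor(x, yy)
      }, numeric(1))
    })
    n_used <- n_perm
    hits <- switch(sided,
                   greater = sum(r_null >= r_obs - eps),
                   less = sum(r_null <= r_obs + eps),
                   two.sided = sum(abs(r_null) >= abs(r_obs) - eps))
    p <- (1 + hits) / (1 + n_perm)
  }
  structure(list(r_observed = r_obs, p_value = p, n_perm = n_used,
                 exhaustive = exhaustive, seed = seed, sided = sided,
                 replace = replace,
                 null_mean = mean(r_null), null_sd = stats::sd(r_null)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> r = %.4f, p = %.5g (%s, %s, %d perms)\n",
              x$r_observed, x$p_value, x$sided,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

#' Meng's z-test for comparing two dependent correlations
#'
#' Meng-Rosenthal-Rubin test of whether two correlations r1 and r2 that
#' share a variable (here: two neural tuning curves each correlated with
#' the same behavioral curve) differ. With z1, z2 the Fisher transforms,
#' rbar2 = (r1^2 + r2^2)/2, f = min(1, (1 - r_x) / (2 (1 - rbar2))) and
#' h = (1 - f * rbar2) / (1 - rbar2):
#' z = (z1 - z2) * sqrt((n - 3) / (2 (1 - r_x) h)).
#'
#' @param r1,r2 correlations of each predictor with the shared variable,
#'   in (-1, 1).
#' @param r_x correlation between the two predictors, in (-1, 1).
#' @param n sample size (>= 4).
#' @param sided "two.sided" (default), or "greater" for the one-sided
#'   alternative r1 > r2.
#' @return a `meng_result`: z, p_value, r1, r2, r_x, n, sided.
#' @export
meng_z <- function(r1, r2, r_x, n, sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("r1, r2 must be strictly inside (-1, 1)", call. = FALSE)
  if (r_x >= 1 || r_x <= -1)
    stop("r_x must be strictly inside (-1, 1)", call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r_x) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_x) * h))
  p <- switch(sided,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(-z))
  structure(list(z = z, p_value = p, r1 = r1, r2 = r2, r_x = r_x, n = n,
                 sided = sided), class = "meng_result")
}

#' @export
print.meng_result <- function(x, ...) {
  cat(sprintf("<meng_result> z = %.4f, p = %.5g (%s; r1 = %.3f, r2 = %.3f, r_x = %.3f, n = %d)\n",
              x$z, x$p_value, x$sided, x$r1, x$r2, x$r_x, x$n))
  invisible(x)
}

#' Wilcoxon rank-sum / signed-rank tests
#'
#' Delegates to `stats::wilcox.test`: exact enumeration for small
#' untied samples, normal approximation with tie correction otherwise.
#' For the signed-rank mode, zero differences are dropped (the standard
#' convention); if every pair is tied the statistic is undefined and
#' p = 1 is returned by convention.
#'
#' @param a,b numeric samples; independent for `rank_sum`, paired for
#'   `signed_rank`.
#' @param mode "rank_sum" (two independent samples) or "signed_rank"
#'   (paired).
#' @param sided "two.sided", "greater" (a tends larger), or "less".
#' @return list(statistic, p_value, mode, sided, method).
#' @export
wilcoxon_test <- function(a, b, mode = c("rank_sum", "signed_rank"),
                          sided = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode); sided <- match.arg(sided)
  if (mode == "signed_rank") {
    if (length(a) != length(b))
      stop("signed-rank mode needs paired samples", call. = FALSE)
    if (all(a == b))
      return(list(statistic = NA_real_, p_value = 1, mode = mode,
                  sided = sided,
                  method = "all differences zero; p = 1 by convention"))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    a, b, paired = (mode == "signed_rank"), alternative = sided))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mode = mode, sided = sided, method = ht$method)
}
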