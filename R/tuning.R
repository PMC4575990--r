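#' Build a tuning curve from a long response table
#'
#' Pivots per-subject responses (peak delta-F/F or chaining indices) to a
#' subjects x conditions matrix and computes the group mean and SEM
#' (sample SD / sqrt(n), n = subjects with data) per condition, the form
#' plotted as mean +/- SEM tuning curves over IPI or intensity.
#'
#' @param df data.frame in long format.
#' @param subject,condition,value column names.
#' @param axis label for the condition axis (e.g. "ipi_ms" or "level_db").
#' @return a `tuning_curve`: list(axis, conditions, per_subject (matrix),
#'   mean, sem, n, normalized).
#' @export
build_tuning <- function(df, subject = "subject", condition = "condition",
                         value = "value", axis = "ipi_ms") {
  stopifnot(all(c(subject, condition, value) %in% names(df)))
  conds <- sort(unique(df[[condition]]))
  subs <- unique(df[[subject]])
  m <- matrix(NA_real_, length(subs), length(conds),
              dimnames = list(as.character(subs), as.character(conds)))
  for (i in seq_len(nrow(df))) {
    m[as.character(df[[subject]][i]), as.character(df[[condition]][i])] <-
      df[[value]][i]
  }
  new_tuning_curve(axis, conds, m, normalized = FALSE)
}

new_tuning_curve <- function(axis, conditions, per_subject,
                             normalized = FALSE) {
  n <- colSums(!is.na(per_subject))
  if (any(n == 0)) stop("every condition needs at least one subject",
                        call. = FALSE)
  mu <- colMeans(per_subject, na.rm = TRUE)
  sem <- apply(per_subject, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  })
  structure(list(axis = axis, conditions = conditions,
                 per_subject = per_subject, mean = unname(mu),
                 sem = unname(sem), n = unname(n),
                 normalized = normalized),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %d subjects x %d %s conditions%s\n",
              nrow(x$per_subject), length(x$conditions), x$axis,
              if (x$normalized) " (normalized)" else ""))
  print(data.frame(condition = x$conditions, mean = x$mean, sem = x$sem,
                   n = x$n))
  invisible(x)
}

#' Per-subject max normalization of a tuning curve
#'
#' Divides each subject's row by that subject's maximum response, then
#' recomputes the group mean and SEM on the normalized rows (each fly's
#' response across IPIs divided by its maximum response, then averaged).
#' Subjects whose responses are all zero (or negative throughout) cannot
#' be normalized and are excluded with a warning. Idempotent.
#'
#' @param curve a `tuning_curve`.
#' @return a normalized `tuning_curve`.
#' @export
normalize_per_subject <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  m <- curve$per_subject
  mx <- apply(m, 1, max, na.rm = TRUE)
  bad <- !is.finite(mx) | mx <= 0
  if (any(bad)) {
    warning(sprintf("%d subject(s) with non-positive maximum excluded from normalization",
                    sum(bad)))
    m <- m[!bad, , drop = FALSE]
    mx <- mx[!bad]
  }
  if (nrow(m) == 0) stop("no subject has a positive maximum", call. = FALSE)
  new_tuning_curve(curve$axis, curve$conditions, m / mx, normalized = TRUE)
}

#' Four-parameter logistic (sigmoid) intensity-response fit
#'
#' Least-squares fit of R(I) = floor + (ceiling - floor) /
#' (1 + exp(-slope * (I - ec50))) in dB, the half-maximal sigmoid fit
#' used to estimate activation thresholds. EC50 is the half-maximal
#' point by construction. Fitting is Levenberg-Marquardt with a
#' multi-start over EC50 starting values at the data quantiles and both
#' slope signs; the best (lowest-RSS) converged fit is kept.
#'
#' Degenerate data are flagged, never silently fit: a flat response
#' (range below `flat_tol` of the absolute scale) or an EC50 outside the
#' intensity span +/- one span sets `flagged = TRUE` with a message.
#'
#' @param intensities intensity levels (dB), >= 4 distinct values.
#' @param responses numeric responses (same length), or a `tuning_curve`
#'   over intensity (its mean is used).
#' @param flat_tol relative response range below which the data are
#'   declared flat.
#' @return a `sigmoid_fit`: list(ec50, slope, floor, ceiling, rss,
#'   converged, flagged, message, fitted).
#' @export
fit_sigmoid <- function(intensities, responses, flat_tol = 1e-6) {
  if (inherits(responses, "tuning_curve")) responses <- responses$mean
  x <- as.numeric(intensities); y <- as.numeric(responses)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct intensity levels", call. = FALSE)
  rng <- diff(range(y))
  scale <- max(abs(y), 1e-12)
  if (rng <= flat_tol * scale) {
    return(structure(list(ec50 = NA_real_, slope = NA_real_,
                          floor = mean(y), ceiling = mean(y), rss = 0,
                          converged = FALSE, flagged = TRUE,
                          message = "flat responses (ceiling ~ floor); no sigmoid",
                          fitted = rep(mean(y), length(y))),
                     class = "sigmoid_fit"))
  }
  span <- diff(range(x))
  starts <- expand.grid(
    ec50 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    slope = c(4 / span, -4 / span, 12 / span))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fl + (ce - fl) / (1 + exp(-s * (x - e))),
        start = list(fl = min(y), ce = max(y),
                     s = starts$slope[i], e = starts$ec50[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(ec50 = NA_real_, slope = NA_real_,
                          floor = NA_real_, ceiling = NA_real_,
                          rss = NA_real_, converged = FALSE, flagged = TRUE,
                          message = "no start converged", fitted = NULL),
                     class = "sigmoid_fit"))
  }
  p <- stats::coef(best$fit)
  # canonical orientation: ceiling >= floor (flip slope sign if needed)
  fl <- unname(p["fl"]); ce <- unname(p["ce"])
  s <- unname(p["s"]); e <- unname(p["e"])
  if (fl > ce) { tmp <- fl; fl <- ce; ce <- tmp; s <- -s }
  flagged <- FALSE; msg <- ""
  if (e < min(x) - span || e > max(x) + span) {
    flagged <- TRUE
    msg <- "EC50 outside data span +/- one span; extrapolated fit"
  }
  structure(list(ec50 = e, slope = s, floor = fl, ceiling = ce,
                 rss = best$rss, converged = TRUE, flagged = flagged,
                 message = msg, fitted = stats::fitted(best$fit)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$flagged) cat("<sigmoid_fit> FLAGGED:", x$message, "\n")
  cat(sprintf("<sigmoid_fit> EC50 = %.3f dB, slope = %.4f /dB, floor = %.4g, ceiling = %.4g, rss = %.4g\n",
              x$ec50, x$slope, x$floor, x$ceiling, x$rss))
  invisible(x)
}

#' Neuron-to-neuron transfer function with propagated SEM
#'
#' Element-wise ratio of two tuning curves over a shared condition axis
#' (e.g. downstream pC1-like responses divided by upstream vPN1-like
#' responses), with first-order error propagation of the SEMs assuming
#' independent numerator and denominator samples:
#' sem_i = |ratio_i| * sqrt((sem_num/mu_num)^2 + (sem_den/mu_den)^2).
#' Conditions whose denominator mean is at or below `eps` are dropped
#' with a warning (the ratio is undefined there).
#'
#' @param numerator,denominator `tuning_curve`s on identical condition
#'   axes.
#' @param eps smallest admissible denominator mean.
#' @return a `transfer_function`: list(axis, conditions, ratio, sem).
#' @export
transfer_function <- function(numerator, denominator, eps = 1e-9) {
  stopifnot(inherits(numerator, "tuning_curve"),
            inherits(denominator, "tuning_curve"))
  if (!identical(numerator$conditions, denominator$conditions))
    stop("tuning curves must share the same condition axis", call. = FALSE)
  keep <- denominator$mean > eps
  if (!all(keep))
    warning(sprintf("%d condition(s) dropped: denominator mean ~ 0",
                    sum(!keep)))
  if (!any(keep)) stop("no condition with positive denominator",
                       call. = FALSE)
  mu_n <- numerator$mean[keep]; mu_d <- denominator$mean[keep]
  se_n <- numerator$sem[keep]; se_d <- denominator$sem[keep]
  ratio <- mu_n / mu_d
  sem <- abs(ratio) * sqrt((se_n / mu_n)^2 + (se_d / mu_d)^2)
  structure(list(axis = numerator$axis,
                 conditions = numerator$conditions[keep],
                 ratio = ratio, sem = sem),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> over %s\n", x$axis))
  print(data.frame(condition = x$conditions, ratio = x$ratio, sem = x$sem))
  invisible(x)
}
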