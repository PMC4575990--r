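#' Run code with a temporarily fixed RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded components never perturb the global stream.
#'
#' @param seed integer seed, or NULL to run without touching the RNG.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert a sound level in dB to a linear amplitude
#'
#' Calibration is relative: amplitude 1.0 corresponds to `ref_db`
#' (default 80 dB SPL). The absolute SPL-to-particle-velocity mapping of a
#' physical playback rig is a measurement, not a computation, and is out of
#' scope; all stimuli share this single relative scale so that
#' amplitude(L1)/amplitude(L2) = 10^((L1 - L2)/20) holds exactly.
#'
#' @param level_db sound level (dB).
#' @param ref_db level assigned amplitude `ref_amplitude` (default 80).
#' @param ref_amplitude amplitude at `ref_db` (default 1).
#' @return linear amplitude (dimensionless).
#' @export
db_to_amplitude <- function(level_db, ref_db = 80, ref_amplitude = 1) {
  ref_amplitude * 10^((level_db - ref_db) / 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
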