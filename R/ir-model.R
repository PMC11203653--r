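#' Inversion-recovery signal model
#'
#' Evaluates the three-parameter inversion-recovery signal
#' \eqn{y(TI) = A - B \exp(-TI/T_1)}, the model underlying MOLLI-style T1
#' mapping. `A` scales the fully recovered signal; `B` measures the quality
#' of the inversion (`B/A = 2` for a perfect inversion); `t1` is the
#' longitudinal relaxation time in milliseconds. Magnitude reconstruction
#' discards the sign, so with `magnitude = TRUE` the absolute value is
#' returned.
#'
#' @param ti Inversion time(s) in ms (non-negative, vectorised).
#' @param A Signal scaling factor.
#' @param B Inversion amplitude; for an ideal 180-degree inversion
#'   `B = 2 * A`.
#' @param t1 Longitudinal relaxation time in ms; must be positive.
#' @param magnitude If `TRUE`, return `|A - B exp(-ti/t1)|`.
#' @return Numeric vector of signal values, one per `ti`.
#' @examples
#' ir_signal(c(90, 240, 756, 923, 1440, 2106, 2790), A = 1000, B = 1950,
#'           t1 = 1400)
#' ir_signal(1200, A = 1000, B = 2000, t1 = 1200, magnitude = TRUE)
#' @export
ir_signal <- function(ti, A, B, t1, magnitude = FALSE) {
  if (any(!is.finite(t1)) || any(t1 <= 0)) {
    stop("invalid parameter: 't1' must be positive and finite", call. = FALSE)
  }
  if (any(ti < 0)) {
    stop("invalid parameter: 'ti' must be non-negative", call. = FALSE)
  }
  y <- A - B * exp(-ti / t1)
  if (magnitude) abs(y) else y
}

#' Polarity-restoration candidates for a magnitude signal
#'
#' Magnitude images lose the sign of the inversion-recovery signal below the
#' null point. Because the signed signal crosses zero at most once (it is
#' monotone in TI), the sign pattern must be "first k samples negative"; this
#' returns all `n + 1` monotone restorations, where candidate `k` negates
#' the first `k` samples of the magnitude signal (samples assumed ordered by
#' increasing TI).
#'
#' @param signal Non-negative magnitude samples, ordered by increasing TI.
#' @param ti_ms Optional inversion times (ms); only used to check that
#'   lengths agree.
#' @return A list of `length(signal) + 1` numeric vectors; element `k + 1`
#'   is the candidate with the first `k` samples negated (`k = 0, ..., n`).
#' @export
restore_polarity <- function(signal, ti_ms = NULL) {
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    stop("invalid input: 'signal' must be finite numeric", call. = FALSE)
  }
  if (any(signal < 0)) {
    stop("invalid input: magnitude 'signal' must be non-negative",
         call. = FALSE)
  }
  if (!is.null(ti_ms) && length(ti_ms) != length(signal)) {
    stop("'ti_ms' and 'signal' lengths differ", call. = FALSE)
  }
  n <- length(signal)
  lapply(0:n, function(k) {
    y <- signal
    if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
    y
  })
}
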