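#' Fit the three-parameter inversion-recovery model to one voxel
#'
#' Nonlinear least-squares fit of \eqn{y = A - B \exp(-TI/T_1)} by a
#' Levenberg-Marquardt algorithm with analytic Jacobian. For magnitude data
#' the fit is repeated over every monotone polarity-restoration candidate
#' (see [restore_polarity()]) and the candidate with the smallest residual
#' sum of squares is kept.
#'
#' The apparent T1 of a Look-Locker readout underestimates true T1; the
#' conventional correction is \eqn{T_1 = T_1^\ast (B/A - 1)}. Values are
#' reported uncorrected by default (the model is fitted and reported with
#' `t1` directly in the exponent); set `ll_correction = TRUE` to also report
#' the corrected value.
#'
#' @param signal Numeric vector of samples, one per inversion time.
#'   Non-negative when `magnitude = TRUE`.
#' @param ti_ms Inversion times in ms. Sorted internally together with
#'   `signal`; at least 4 samples are required (3 parameters + 1 df).
#' @param magnitude Is `signal` a magnitude (unsigned) measurement?
#'   Default `TRUE`, as for typical MOLLI reconstructions.
#' @param t1_range Allowed T1 interval in ms; estimates at either bound are
#'   flagged invalid.
#' @param tol Relative parameter tolerance for convergence.
#' @param maxit Maximum Levenberg-Marquardt iterations per start.
#' @param ll_correction Also report the Look-Locker-corrected
#'   `t1 * (B/A - 1)`.
#' @return An object of class `"ir_fit"`: a list with `coefficients`
#'   (named `A`, `B`, `t1_ms`), `polarity_index` (number of leading samples
#'   sign-flipped), `rss`, `converged`, `valid`, `signal`, `ti_ms`,
#'   `magnitude` and, if requested, `t1_ll_ms`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()`, `simulate()`, `vcov()` and `deviance()`.
#' @examples
#' ti <- c(90, 240, 756, 923, 1440, 2106, 2790)
#' y <- ir_signal(ti, A = 1000, B = 1950, t1 = 1400, magnitude = TRUE)
#' fit <- ir_fit(y, ti)
#' coef(fit)
#' @seealso [fit_t1_map()] for whole-image fitting.
#' @export
ir_fit <- function(signal, ti_ms, magnitude = TRUE,
                   t1_range = c(1, 10000), tol = 1e-9, maxit = 200,
                   ll_correction = FALSE) {
  if (length(signal) != length(ti_ms)) {
    stop("'signal' and 'ti_ms' lengths differ", call. = FALSE)
  }
  if (length(signal) < 4) {
    stop("insufficient data: at least 4 samples are required", call. = FALSE)
  }
  if (any(!is.finite(signal)) || any(!is.finite(ti_ms))) {
    stop("invalid input: non-finite values in 'signal' or 'ti_ms'",
         call. = FALSE)
  }
  if (magnitude && any(signal < 0)) {
    stop("invalid input: magnitude 'signal' must be non-negative",
         call. = FALSE)
  }
  stopifnot(length(t1_range) == 2, t1_range[1] > 0, t1_range[2] > t1_range[1])
  ord <- order(ti_ms)
  ti <- as.numeric(ti_ms[ord])
  y <- as.numeric(signal[ord])
  res <- .cpp_fit_stack(matrix(y, ncol = 1), ti, magnitude,
                        t1_range[1], t1_range[2], tol, as.integer(maxit))
  out <- structure(
    list(
      coefficients = c(A = res$A[1], B = res$B[1], t1_ms = res$t1[1]),
      polarity_index = res$polarity[1],
      rss = res$rss[1],
      converged = res$converged[1],
      valid = .fit_is_valid(res$A[1], res$B[1], res$t1[1], res$converged[1],
                            t1_range),
      signal = y,
      ti_ms = ti,
      magnitude = magnitude,
      t1_range = t1_range,
      iterations = res$iter[1]
    ),
    class = "ir_fit"
  )
  if (ll_correction) {
    out$t1_ll_ms <- unname(res$t1[1] * (res$B[1] / res$A[1] - 1))
  }
  out
}

# A fit is usable when the optimizer converged, T1 sits strictly inside its
# bounds, and B is not degenerate (a constant signal fits exactly with B ~ 0
# and unidentifiable T1).
.fit_is_valid <- function(A, B, t1, converged, t1_range, rss = 0,
                          rss_max = Inf) {
  isTRUE(converged) &&
    is.finite(t1) &&
    t1 > t1_range[1] * (1 + 1e-6) + 1e-9 &&
    t1 < t1_range[2] * (1 - 1e-6) &&
    abs(B) > 1e-8 * max(abs(A), 1) &&
    rss <= rss_max
}

#' @export
print.ir_fit <- function(x, ...) {
  cat("Inversion-recovery fit: y = A - B * exp(-TI/T1)\n")
  cat(sprintf("  A = %.4g, B = %.4g, T1 = %.6g ms\n",
              x$coefficients[["A"]], x$coefficients[["B"]],
              x$coefficients[["t1_ms"]]))
  if (!is.null(x$t1_ll_ms)) {
    cat(sprintf("  Look-Locker corrected T1 = %.6g ms\n", x$t1_ll_ms))
  }
  cat(sprintf("  %d samples (%s), polarity index %d, rss = %.4g\n",
              length(x$signal), if (x$magnitude) "magnitude" else "signed",
              x$polarity_index, x$rss))
  if (!x$valid) cat("  [flagged invalid]\n")
  invisible(x)
}

#' @export
coef.ir_fit <- function(object, ...) object$coefficients

#' @export
deviance.ir_fit <- function(object, ...) object$rss

#' @export
df.residual.ir_fit <- function(object, ...) length(object$signal) - 3L

#' Predicted inversion-recovery signal
#'
#' @param object An [ir_fit()] object.
#' @param ti_ms Inversion times at which to predict; defaults to the times
#'   used in the fit.
#' @param magnitude Return the magnitude of the predicted signal; defaults
#'   to the fit's own convention.
#' @param ... Unused.
#' @return Numeric vector of model predictions.
#' @export
predict.ir_fit <- function(object, ti_ms = NULL, magnitude = NULL, ...) {
  if (is.null(ti_ms)) ti_ms <- object$ti_ms
  if (is.null(magnitude)) magnitude <- object$magnitude
  p <- object$coefficients
  ir_signal(ti_ms, p[["A"]], p[["B"]], p[["t1_ms"]], magnitude = magnitude)
}

#' @export
fitted.ir_fit <- function(object, ...) predict(object)

#' @export
residuals.ir_fit <- function(object, ...) {
  # Residuals on the fitting scale: the best polarity candidate vs the
  # signed model.
  y <- object$signal
  if (object$magnitude && object$polarity_index > 0) {
    k <- seq_len(object$polarity_index)
    y[k] <- -y[k]
  }
  p <- object$coefficients
  y - ir_signal(object$ti_ms, p[["A"]], p[["B"]], p[["t1_ms"]])
}

#' Approximate covariance of the fitted parameters
#'
#' Gauss-Newton approximation `sigma^2 (J'J)^{-1}` evaluated at the
#' estimate, with `sigma^2 = rss / (n - 3)`.
#'
#' @param object An [ir_fit()] object.
#' @param ... Unused.
#' @return A 3x3 matrix with rows/columns `A`, `B`, `t1_ms`.
#' @export
vcov.ir_fit <- function(object, ...) {
  p <- object$coefficients
  e <- exp(-object$ti_ms / p[["t1_ms"]])
  J <- cbind(A = 1, B = -e,
             t1_ms = -p[["B"]] * e * object$ti_ms / p[["t1_ms"]]^2)
  n <- length(object$signal)
  s2 <- object$rss / max(n - 3, 1)
  s2 * solve(crossprod(J))
}

#' @export
summary.ir_fit <- function(object, ...) {
  se <- tryCatch(sqrt(diag(vcov(object))), error = function(e) rep(NA_real_, 3))
  structure(
    list(fit = object,
         table = cbind(Estimate = object$coefficients, `Std. Error` = se)),
    class = "summary.ir_fit"
  )
}

#' @export
print.summary.ir_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameters:\n")
  print(x$table, digits = 5)
  invisible(x)
}

#' Plot an inversion-recovery fit
#'
#' Observed samples (polarity-restored when fitted from magnitude data)
#' with the fitted recovery curve.
#'
#' @param x An [ir_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ir_fit <- function(x, ...) {
  y <- x$signal
  if (x$magnitude && x$polarity_index > 0) {
    k <- seq_len(x$polarity_index)
    y[k] <- -y[k]
  }
  ti_grid <- seq(0, max(x$ti_ms) * 1.05, length.out = 200)
  p <- x$coefficients
  curve_y <- ir_signal(ti_grid, p[["A"]], p[["B"]], p[["t1_ms"]])
  graphics::plot(x$ti_ms, y, xlab = "Inversion time (ms)",
                 ylab = "Signal", ylim = range(c(y, curve_y)), ...)
  graphics::lines(ti_grid, curve_y, col = "firebrick")
  graphics::abline(h = 0, lty = 3, col = "grey50")
  graphics::mtext(sprintf("T1 = %.0f ms", p[["t1_ms"]]), side = 3,
                  adj = 1, cex = 0.8)
  invisible(x)
}

#' Simulate replicate signals from a fitted recovery curve
#'
#' Draws noisy replicates of the fitted model at the fit's inversion times,
#' using Rician or Gaussian noise.
#'
#' @param object An [ir_fit()] object.
#' @param nsim Number of replicate signals.
#' @param seed Optional RNG seed (restores the previous RNG state on exit).
#' @param sigma Noise standard deviation (per channel for Rician noise).
#'   Defaults to the residual standard deviation of the fit.
#' @param noise_model `"rician"`, `"gaussian"` or `"none"`.
#' @param ... Unused.
#' @return A matrix with `length(ti_ms)` rows and `nsim` columns.
#' @export
simulate.ir_fit <- function(object, nsim = 1, seed = NULL,
                            sigma = NULL, noise_model = "rician", ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  if (is.null(sigma)) {
    sigma <- sqrt(object$rss / max(length(object$signal) - 3, 1))
  }
  p <- object$coefficients
  s <- ir_signal(object$ti_ms, p[["A"]], p[["B"]], p[["t1_ms"]])
  out <- replicate(nsim, .add_noise(s, sigma, noise_model))
  matrix(out, nrow = length(s), ncol = nsim,
         dimnames = list(paste0("ti_", object$ti_ms), NULL))
}

# Magnitude-MRI noise: Rician is |s + n1 + i n2| with Gaussian channels.
.add_noise <- function(s, sigma, model = c("rician", "gaussian", "none")) {
  model <- match.arg(model)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (model == "none" || sigma == 0) {
    return(if (model == "rician") abs(s) else s)
  }
  n <- length(s)
  switch(model,
    rician = sqrt((s + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2),
    gaussian = s + stats::rnorm(n, 0, sigma)
  )
}
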