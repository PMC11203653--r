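#' Inversion-recovery image series
#'
#' Container for a stack of 2-D images acquired at increasing inversion
#' times, the input to [fit_t1_map()]. Frames are stored as a 3-D array
#' `[x, y, ti]` and are re-ordered by ascending TI on construction.
#'
#' @param frames A 3-D numeric array `[nx, ny, n_ti]`, or a list of equally
#'   sized matrices (one per TI).
#' @param ti_ms Inversion times in ms, one per frame; must be distinct and
#'   positive, and at least 4 are required.
#' @param magnitude Are the frames magnitude (unsigned) images? Magnitude
#'   frames must be non-negative.
#' @param pixel_spacing_mm In-plane pixel spacing in mm, length 1 or 2.
#' @return An object of class `"inversion_series"` with elements `frames`
#'   (3-D array, TI-ascending), `ti_ms`, `magnitude`, `pixel_spacing_mm`.
#' @examples
#' ti <- c(90, 240, 756, 923, 1440, 2106, 2790)
#' frames <- vapply(ti, function(t) {
#'   matrix(ir_signal(t, 1000, 1950, 1400, magnitude = TRUE), 4, 4)
#' }, matrix(0, 4, 4))
#' s <- inversion_series(frames, ti)
#' @export
inversion_series <- function(frames, ti_ms, magnitude = TRUE,
                             pixel_spacing_mm = c(1.48, 1.48)) {
  if (is.list(frames)) {
    dims <- dim(frames[[1]])
    if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1)))) {
      stop("all frames must have the same dimensions", call. = FALSE)
    }
    frames <- array(unlist(frames), dim = c(dims, length(frames)))
  }
  if (length(dim(frames)) != 3) {
    stop("'frames' must be a 3-D array [x, y, ti]", call. = FALSE)
  }
  n_ti <- dim(frames)[3]
  if (length(ti_ms) != n_ti) {
    stop("number of frames and inversion times differ", call. = FALSE)
  }
  if (n_ti < 4) {
    stop("insufficient data: at least 4 inversion times are required",
         call. = FALSE)
  }
  if (anyDuplicated(ti_ms)) {
    dup <- unique(ti_ms[duplicated(ti_ms)])
    stop("duplicate inversion times: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(ti_ms <= 0)) stop("inversion times must be positive", call. = FALSE)
  if (magnitude && any(frames < 0)) {
    stop("magnitude frames must be non-negative", call. = FALSE)
  }
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  stopifnot(length(pixel_spacing_mm) == 2, all(pixel_spacing_mm > 0))
  ord <- order(ti_ms)
  structure(
    list(frames = frames[, , ord, drop = FALSE],
         ti_ms = as.numeric(ti_ms[ord]),
         magnitude = magnitude,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm)),
    class = "inversion_series"
  )
}

#' @export
print.inversion_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Inversion-recovery series: %d x %d pixels, %d TIs (%s)\n",
              d[1], d[2], d[3], if (x$magnitude) "magnitude" else "signed"))
  cat("  TI (ms):", paste(x$ti_ms, collapse = ", "), "\n")
  cat(sprintf("  pixel spacing: %.3g x %.3g mm\n",
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

#' @export
dim.inversion_series <- function(x) dim(x$frames)

#' Voxelwise T1 map from an inversion-recovery series
#'
#' Applies the three-parameter fit of [ir_fit()] to every in-mask voxel of
#' the series and assembles parameter maps. Out-of-mask voxels and voxels
#' whose fit fails validity checks (non-convergence, T1 at a bound,
#' degenerate amplitude, or residual sum of squares above `rss_max`) are
#' marked `NA` in the T1 map, never silently zero; their diagnostics remain
#' available in the component maps.
#'
#' @param series An [inversion_series()].
#' @param mask Optional logical matrix matching the frame shape; only
#'   in-mask voxels are fitted. `NULL` fits every voxel.
#' @param rss_max Validity threshold on the per-voxel residual sum of
#'   squares (default `Inf`, no RSS-based flagging).
#' @inheritParams ir_fit
#' @return An object of class `"t1_map"`: a list of matrices `t1` (ms, `NA`
#'   where invalid), `A`, `B`, `rss`, `polarity`, plus logical matrices
#'   `converged`, `valid`, `fitted_mask`, and provenance (`ti_ms`,
#'   `pixel_spacing_mm`, options). If `ll_correction = TRUE`, also `t1_ll`.
#' @examples
#' ti <- c(90, 240, 756, 923, 1440, 2106, 2790)
#' frames <- vapply(ti, function(t) {
#'   matrix(ir_signal(t, 1000, 1950, 1400, magnitude = TRUE), 4, 4)
#' }, matrix(0, 4, 4))
#' m <- fit_t1_map(inversion_series(frames, ti))
#' range(m$t1)
#' @export
fit_t1_map <- function(series, mask = NULL, t1_range = c(1, 10000),
                       tol = 1e-9, maxit = 200, rss_max = Inf,
                       ll_correction = FALSE) {
  stopifnot(inherits(series, "inversion_series"))
  d <- dim(series$frames)
  nx <- d[1]; ny <- d[2]; n_ti <- d[3]
  if (is.null(mask)) {
    mask <- matrix(TRUE, nx, ny)
  }
  if (!is.logical(mask) || !identical(dim(mask), c(nx, ny))) {
    stop("'mask' must be a logical matrix matching the frame shape",
         call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) == 0) stop("empty mask: no voxels to fit", call. = FALSE)
  # signals as columns: one column per in-mask voxel
  Y <- matrix(series$frames, nrow = nx * ny, ncol = n_ti)[idx, , drop = FALSE]
  res <- .cpp_fit_stack(t(Y), series$ti_ms, series$magnitude,
                        t1_range[1], t1_range[2], tol, as.integer(maxit))
  blank <- matrix(NA_real_, nx, ny)
  out <- list(t1 = blank, A = blank, B = blank, rss = blank,
              polarity = matrix(NA_integer_, nx, ny),
              converged = matrix(FALSE, nx, ny),
              valid = matrix(FALSE, nx, ny),
              fitted_mask = mask,
              ti_ms = series$ti_ms,
              pixel_spacing_mm = series$pixel_spacing_mm,
              options = list(magnitude = series$magnitude,
                             t1_range = t1_range, tol = tol, maxit = maxit,
                             rss_max = rss_max,
                             ll_correction = ll_correction))
  out$A[idx] <- res$A
  out$B[idx] <- res$B
  out$rss[idx] <- res$rss
  out$polarity[idx] <- res$polarity
  out$converged[idx] <- res$converged
  valid <- res$converged &
    res$t1 > t1_range[1] * (1 + 1e-6) + 1e-9 &
    res$t1 < t1_range[2] * (1 - 1e-6) &
    abs(res$B) > 1e-8 * pmax(abs(res$A), 1) &
    res$rss <= rss_max
  out$valid[idx] <- valid
  t1 <- res$t1
  t1[!valid] <- NA_real_
  out$t1[idx] <- t1
  if (ll_correction) {
    out$t1_ll <- blank
    out$t1_ll[idx] <- t1 * (res$B / res$A - 1)
  }
  class(out) <- "t1_map"
  out
}

#' @export
print.t1_map <- function(x, ...) {
  d <- dim(x$t1)
  nfit <- sum(x$fitted_mask)
  nval <- sum(x$valid)
  cat(sprintf("T1 map: %d x %d pixels, %d fitted voxels (%d valid)\n",
              d[1], d[2], nfit, nval))
  if (nval > 0) {
    q <- stats::quantile(x$t1[x$valid], c(0.05, 0.5, 0.95))
    cat(sprintf("  T1 (ms): 5%% %.0f | median %.0f | 95%% %.0f\n",
                q[1], q[2], q[3]))
  }
  invisible(x)
}

#' @export
as.matrix.t1_map <- function(x, ...) x$t1

#' Display a T1 map
#'
#' @param x A [fit_t1_map()] object.
#' @param zlim T1 display range in ms; defaults to the valid-voxel range.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.t1_map <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) {
    zlim <- if (any(x$valid)) range(x$t1[x$valid]) else c(0, 1)
  }
  graphics::image(seq_len(nrow(x$t1)), seq_len(ncol(x$t1)), x$t1,
                  zlim = zlim, col = grDevices::hcl.colors(64, "Spectral",
                                                           rev = TRUE),
                  xlab = "x (pixels)", ylab = "y (pixels)",
                  useRaster = TRUE, ...)
  invisible(x)
}
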