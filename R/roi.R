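#' Labeled region masks with pixel geometry
#'
#' Bundles named boolean masks (calf muscle compartments AM, LM, DM, SM,
#' GM; arteries AT, PT, PE; optionally a `leg` outline) with the pixel
#' spacing needed to turn voxel counts into areas.
#'
#' @param labels Named list of logical matrices, all the same shape.
#'   Compartment labels must be drawn from AM/LM/DM/SM/GM, artery labels
#'   from AT/PT/PE; other names (e.g. `leg`) are carried as auxiliary
#'   outlines.
#' @param pixel_spacing_mm Pixel spacing in mm, length 1 or 2.
#' @param side `"left"`, `"right"` or `"bilateral"`.
#' @return An object of class `"region_set"`.
#' @export
region_set <- function(labels, pixel_spacing_mm = 1.48,
                       side = c("bilateral", "left", "right")) {
  side <- match.arg(side)
  stopifnot(is.list(labels), length(labels) >= 1, !is.null(names(labels)))
  dims <- dim(labels[[1]])
  for (nm in names(labels)) {
    m <- labels[[nm]]
    if (!is.logical(m) || !identical(dim(m), dims)) {
      stop("label '", nm, "' is not a logical matrix of matching shape",
           call. = FALSE)
    }
  }
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  stopifnot(all(pixel_spacing_mm > 0))
  structure(list(labels = labels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 side = side),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  counts <- vapply(x$labels, sum, numeric(1))
  cat(sprintf("Region set (%s side), %d labels:\n", x$side, length(counts)))
  for (nm in names(counts)) cat(sprintf("  %-4s %6d voxels\n", nm, counts[nm]))
  invisible(x)
}

#' Union of a region set's compartment and artery masks
#'
#' Convenience mask covering every labeled tissue voxel (auxiliary outlines
#' such as `leg` excluded); useful as a fitting mask.
#'
#' @param regions A [region_set()].
#' @return A logical matrix.
#' @export
region_union <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  nms <- intersect(names(regions$labels), .phantom_region_names())
  Reduce(`|`, regions$labels[nms])
}

#' Per-compartment T1 metrics
#'
#' Summarises a T1 map over one region of interest: the peak (maximum) T1,
#' the mean T1 over all voxels, the minimum T1, and the cross-sectional
#' area. Invalid voxels (`NA` in the map) are excluded from all metrics and
#' from the voxel count.
#'
#' @param map A [fit_t1_map()] object, or a plain numeric matrix of T1
#'   values with `NA` marking invalid voxels.
#' @param mask Logical matrix selecting the region.
#' @param pixel_spacing_mm Pixel spacing; taken from `map` when it is a
#'   `t1_map`.
#' @return An object of class `"compartment_metrics"`: a list with
#'   `peak_t1_ms`, `mean_t1_ms`, `min_t1_ms`, `csa_mm2`, `n_voxels`.
#' @export
compartment_metrics <- function(map, mask, pixel_spacing_mm = NULL) {
  if (inherits(map, "t1_map")) {
    if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- map$pixel_spacing_mm
    map <- map$t1
  }
  if (is.null(pixel_spacing_mm)) pixel_spacing_mm <- c(1, 1)
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(map))) {
    stop("'mask' must be a logical matrix matching the map", call. = FALSE)
  }
  if (!any(mask)) stop("empty region: mask selects no voxels", call. = FALSE)
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop("empty region: no valid voxels inside mask", call. = FALSE)
  }
  structure(
    list(peak_t1_ms = max(vals),
         mean_t1_ms = mean(vals),
         min_t1_ms = min(vals),
         csa_mm2 = length(vals) * prod(pixel_spacing_mm),
         n_voxels = length(vals)),
    class = "compartment_metrics"
  )
}

#' @export
print.compartment_metrics <- function(x, ...) {
  cat(sprintf(
    "T1 metrics: peak %.1f | mean %.1f | min %.1f ms; CSA %.0f mm2 (%d voxels)\n",
    x$peak_t1_ms, x$mean_t1_ms, x$min_t1_ms, x$csa_mm2, x$n_voxels))
  invisible(x)
}

#' Average peak T1 over the five calf muscle compartments
#'
#' Arithmetic mean of the per-compartment peak T1 values of AM, LM, DM, SM
#' and GM; all five must be present.
#'
#' @param metrics Named list of [compartment_metrics()] (or of numeric peak
#'   values) covering exactly the five muscle compartments.
#' @return The averaged peak T1 in ms.
#' @export
average_peak_t1 <- function(metrics) {
  need <- .muscle_names()
  if (!all(need %in% names(metrics))) {
    stop("incomplete set: need all of ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  peaks <- vapply(metrics[need], function(m) {
    if (inherits(m, "compartment_metrics")) m$peak_t1_ms else as.numeric(m)
  }, numeric(1))
  mean(peaks)
}

#' Averaged peak blood-pool T1 over the calf arteries
#'
#' Computes the peak (maximum) T1 within each available artery mask (AT,
#' PT, PE) and averages the per-artery peaks. Arteries whose mask is empty
#' or contains no valid voxel are skipped with a warning.
#'
#' @param map A [fit_t1_map()] object or T1 matrix.
#' @param regions A [region_set()] containing at least one artery label.
#' @return The averaged peak blood T1 in ms, with attributes `n_arteries`
#'   (number contributing) and `per_artery` (named peaks).
#' @export
blood_pool_t1 <- function(map, regions) {
  stopifnot(inherits(regions, "region_set"))
  t1 <- if (inherits(map, "t1_map")) map$t1 else map
  arteries <- intersect(.artery_names(), names(regions$labels))
  if (length(arteries) == 0) {
    stop("empty region: no artery labels in the region set", call. = FALSE)
  }
  peaks <- c()
  for (nm in arteries) {
    vals <- t1[regions$labels[[nm]]]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) {
      warning("artery '", nm, "' has no valid voxels; skipped",
              call. = FALSE)
      next
    }
    peaks[nm] <- max(vals)
  }
  if (length(peaks) == 0) {
    stop("empty region: no artery contains valid voxels", call. = FALSE)
  }
  structure(mean(peaks), n_arteries = length(peaks), per_artery = peaks)
}

#' Bilateral average of two compartment-metric sets
#'
#' Element-wise arithmetic mean of the left- and right-side metrics of the
#' same compartment, as used for bilateral-average reporting.
#'
#' @param left,right [compartment_metrics()] objects for the same
#'   compartment on the two sides.
#' @return A `"compartment_metrics"` object of averaged values
#'   (`n_voxels` is the mean voxel count and may be fractional).
#' @export
bilateral_average <- function(left, right) {
  stopifnot(inherits(left, "compartment_metrics"),
            inherits(right, "compartment_metrics"))
  cl <- attr(left, "compartment"); cr <- attr(right, "compartment")
  if (!is.null(cl) && !is.null(cr) && !identical(cl, cr)) {
    stop("label error: sides belong to different compartments (", cl,
         " vs ", cr, ")", call. = FALSE)
  }
  out <- Map(function(a, b) (a + b) / 2, unclass(left), unclass(right))
  structure(out, class = "compartment_metrics", compartment = cl)
}

#' Compartment metrics table for one fitted subject
#'
#' Runs [compartment_metrics()] over the five muscle compartments of a map
#' and returns the fixed-schema long table used by the cohort pipeline.
#'
#' @param map A [fit_t1_map()] object.
#' @param regions A [region_set()] with the muscle labels.
#' @param subject,group Identifiers copied into the table.
#' @return A `data.frame` with columns `subject`, `group`, `compartment`,
#'   `peak_t1_ms`, `mean_t1_ms`, `min_t1_ms`, `csa_mm2`.
#' @export
muscle_metrics_table <- function(map, regions, subject = "s1",
                                 group = "control") {
  stopifnot(inherits(regions, "region_set"))
  rows <- lapply(.muscle_names(), function(nm) {
    m <- compartment_metrics(map, regions$labels[[nm]])
    data.frame(subject = subject, group = group, compartment = nm,
               peak_t1_ms = m$peak_t1_ms, mean_t1_ms = m$mean_t1_ms,
               min_t1_ms = m$min_t1_ms, csa_mm2 = m$csa_mm2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
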