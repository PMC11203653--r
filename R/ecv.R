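#' Extracellular volume fraction from pre/post-contrast T1
#'
#' Computes the extracellular volume fraction of a muscle compartment from
#' its peak T1 before and after gadolinium contrast, the averaged peak
#' arterial blood T1 at the same two time points, and the hematocrit:
#' \deqn{ECV = (1 - hct) \frac{1/T1_{m,post} - 1/T1_{m,pre}}
#'                            {1/T1_{b,post} - 1/T1_{b,pre}}}
#' Hematocrit given in percent (values above 1) is converted to a fraction
#' with a message. Results outside \[0, 1\] are returned but flagged
#' implausible via a warning and the `"implausible"` attribute; they are
#' never clamped.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param t1m_pre_ms,t1m_post_ms Compartment (peak) T1 in ms, pre and post
#'   contrast; post must be below pre.
#' @param t1b_pre_ms,t1b_post_ms Averaged peak blood-pool T1 in ms, pre and
#'   post contrast.
#' @param hematocrit Hematocrit as a fraction in (0, 1), or in percent.
#' @return ECV as a fraction (multiply by 100 for percent), with attribute
#'   `"implausible"` (logical vector) when any value falls outside \[0, 1\].
#' @examples
#' compute_ecv(1900, 600, 1700, 400, hematocrit = 0.40)
#' @export
compute_ecv <- function(t1m_pre_ms, t1m_post_ms, t1b_pre_ms, t1b_post_ms,
                        hematocrit) {
  n <- max(length(t1m_pre_ms), length(t1m_post_ms), length(t1b_pre_ms),
           length(t1b_post_ms), length(hematocrit))
  t1m_pre_ms <- rep_len(t1m_pre_ms, n)
  t1m_post_ms <- rep_len(t1m_post_ms, n)
  t1b_pre_ms <- rep_len(t1b_pre_ms, n)
  t1b_post_ms <- rep_len(t1b_post_ms, n)
  hematocrit <- rep_len(hematocrit, n)
  if (any(!is.finite(c(t1m_pre_ms, t1m_post_ms, t1b_pre_ms, t1b_post_ms,
                       hematocrit)))) {
    stop("invalid input: non-finite ECV inputs", call. = FALSE)
  }
  if (any(c(t1m_pre_ms, t1m_post_ms, t1b_pre_ms, t1b_post_ms) <= 0)) {
    stop("invalid parameter: all T1 values must be positive", call. = FALSE)
  }
  pct <- hematocrit > 1
  if (any(pct)) {
    message("hematocrit > 1 interpreted as percent and divided by 100 (",
            sum(pct), " value", if (sum(pct) > 1) "s", ")")
    hematocrit[pct] <- hematocrit[pct] / 100
  }
  if (any(hematocrit <= 0 | hematocrit >= 1)) {
    stop("invalid parameter: hematocrit must lie in (0, 1)", call. = FALSE)
  }
  if (any(t1b_post_ms == t1b_pre_ms)) {
    stop("division by zero: pre- and post-contrast blood T1 are equal",
         call. = FALSE)
  }
  if (any(t1m_post_ms > t1m_pre_ms)) {
    warning("post-contrast muscle T1 above pre-contrast; ",
            "contrast should shorten T1", call. = FALSE)
  }
  ecv <- (1 - hematocrit) *
    (1 / t1m_post_ms - 1 / t1m_pre_ms) /
    (1 / t1b_post_ms - 1 / t1b_pre_ms)
  bad <- ecv < 0 | ecv > 1
  if (any(bad)) {
    warning(sum(bad), " ECV value(s) outside [0, 1]; flagged implausible, ",
            "not clamped", call. = FALSE)
    attr(ecv, "implausible") <- bad
  }
  ecv
}

#' Per-subject, per-compartment ECV for a cohort
#'
#' Joins pre/post compartment peak T1 tables with per-subject blood-pool T1
#' and hematocrit and applies [compute_ecv()]. Subjects missing any input
#' (either contrast state of a compartment, either blood value, or
#' hematocrit) are excluded and counted.
#'
#' @param metrics_pre,metrics_post Long tables as produced by
#'   [muscle_metrics_table()] (columns `subject`, `group`, `compartment`,
#'   `peak_t1_ms`, ...), for the native and post-contrast maps.
#' @param subjects A `data.frame` with one row per subject: columns
#'   `subject`, `hematocrit` (fraction or percent), `t1b_pre_ms`,
#'   `t1b_post_ms`.
#' @param use_mean Use the mean instead of the peak compartment T1
#'   (sensitivity analysis; the primary definition is the peak).
#' @return A `data.frame` with columns `subject`, `group`, `compartment`,
#'   `ecv_pct`, carrying attributes `n_excluded` and `excluded_subjects`.
#' @export
cohort_ecv <- function(metrics_pre, metrics_post, subjects,
                       use_mean = FALSE) {
  need <- c("subject", "hematocrit", "t1b_pre_ms", "t1b_post_ms")
  if (!all(need %in% names(subjects))) {
    stop("'subjects' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  col <- if (use_mean) "mean_t1_ms" else "peak_t1_ms"
  all_subj <- unique(c(metrics_pre$subject, metrics_post$subject,
                       subjects$subject))
  rows <- list()
  excluded <- character(0)
  for (s in all_subj) {
    pre <- metrics_pre[metrics_pre$subject == s, ]
    post <- metrics_post[metrics_post$subject == s, ]
    info <- subjects[subjects$subject == s, ]
    complete <- nrow(info) == 1 &&
      all(.muscle_names() %in% pre$compartment) &&
      all(.muscle_names() %in% post$compartment) &&
      all(is.finite(c(info$hematocrit, info$t1b_pre_ms, info$t1b_post_ms)))
    if (!complete) {
      excluded <- c(excluded, s)
      next
    }
    for (cmp in .muscle_names()) {
      ecv <- compute_ecv(pre[[col]][pre$compartment == cmp],
                         post[[col]][post$compartment == cmp],
                         info$t1b_pre_ms, info$t1b_post_ms,
                         info$hematocrit)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, group = pre$group[1], compartment = cmp,
        ecv_pct = 100 * as.numeric(ecv), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(subject = character(0), group = character(0),
               compartment = character(0), ecv_pct = numeric(0))
  }
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_subjects") <- excluded
  out
}
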