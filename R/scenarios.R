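#' Metrics across class admixtures
#'
#' A classifier with fixed recall and specificity is evaluated on sets of
#' varying prevalence by modelling the data as a two-component mixture with
#' positive-class weight `alpha`. At each grid point the normalized
#' confusion matrix `tp = alpha * rec`, `fn = alpha * (1 - rec)`,
#' `tn = (1 - alpha) * spec`, `fp = (1 - alpha) * (1 - spec)` is evaluated
#' with the full metric suite. Recall and specificity are invariant along
#' the curve by construction; accuracy, the predictive values, F1, MCC and
#' the threat score all move with the admixture, which is what makes a
#' single reported prevalence insufficient to judge a model.
#'
#' The default grid excludes the endpoints 0 and 1, where one class is
#' absent and several metrics degenerate to `NA`; pass them explicitly if
#' degenerate rows are wanted.
#'
#' @param rec,spec Recall and specificity, each in `[0, 1]`.
#' @param alpha_grid Mixture parameters in `[0, 1]`.
#' @return A data frame of class `prevalence_curve` with column `alpha`
#'   followed by the eight metric columns ([metric_names]); attributes
#'   `rec` and `spec` carry the inputs.
#'
#' @examples
#' curve <- prevalence_sweep(rec = 0.997, spec = 0.99,
#'                           alpha_grid = c(0.005, 0.5))
#' curve$PREC # precision collapses at low prevalence
#'
#' @export
prevalence_sweep <- function(rec, spec,
                             alpha_grid = seq(0.01, 0.99, by = 0.01)) {
  if (rec < 0 || rec > 1 || spec < 0 || spec > 1) {
    stop("rec and spec must lie in [0, 1]", call. = FALSE)
  }
  if (length(alpha_grid) == 0L || any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha_grid values must lie in [0, 1]", call. = FALSE)
  }
  rows <- t(vapply(alpha_grid, function(a) {
    cm <- confusion_matrix(tp = a * rec, fn = a * (1 - rec),
                           tn = (1 - a) * spec, fp = (1 - a) * (1 - spec),
                           strict = FALSE)
    unclass(all_metrics(cm))
  }, numeric(8)))
  out <- data.frame(alpha = alpha_grid, rows)
  colnames(out) <- c("alpha", metric_names)
  attr(out, "rec") <- rec
  attr(out, "spec") <- spec
  class(out) <- c("prevalence_curve", "data.frame")
  out
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf("Prevalence sweep: rec = %g, spec = %g, %d grid points\n",
              attr(x, "rec"), attr(x, "spec"), nrow(x)))
  NextMethod()
}

#' Degenerate biased-classifier baseline
#'
#' The confusion matrix of the classifier that assigns every sample to one
#' class. Under class imbalance this baseline exposes what headline metrics
#' hide: biased-positive always has recall 1, biased-negative always has
#' specificity 1, and the prevalence-sensitive metrics make the degeneracy
#' visible (the MCC is undefined because a full row of the matrix is zero).
#'
#' @param pos_total,neg_total Class totals (non-negative).
#' @param direction `"positive"` or `"negative"`.
#' @param basis Evaluation basis for the result.
#' @return A [confusion_matrix()].
#'
#' @examples
#' all_metrics(biased_classifier(6000, 21695, "positive"))
#'
#' @export
biased_classifier <- function(pos_total, neg_total,
                              direction = c("positive", "negative"),
                              basis = "per-frame") {
  direction <- match.arg(direction)
  if (pos_total < 0 || neg_total < 0) {
    stop("class totals must be non-negative", call. = FALSE)
  }
  if (direction == "positive") {
    confusion_matrix(tp = pos_total, tn = 0, fp = neg_total, fn = 0,
                     basis = basis)
  } else {
    confusion_matrix(tp = 0, tn = neg_total, fp = 0, fn = pos_total,
                     basis = basis)
  }
}

#' Pool per-class or per-fold evaluations
#'
#' Element-wise sum of confusion matrices that were reported separately,
#' e.g. a positives-only and a negatives-only test of the same model. All
#' parts must share the evaluation basis. Stated class totals, when any
#' part carries them, are summed as well (parts without an explicit total
#' contribute their row sums), so a part evaluated against an explicitly
#' stated class total keeps that convention after pooling.
#'
#' Pooling assumes the parts may simply be added -- the micro-average view.
#' Whether that assumption is defensible for separately reported per-class
#' tests is precisely what the biased baselines of [biased_classifier()]
#' probe.
#'
#' @param parts A list of [confusion_matrix()] objects.
#' @return A [confusion_matrix()].
#'
#' @examples
#' pos_part <- confusion_matrix(5663, 0, 251, 337)
#' neg_part <- confusion_matrix(0, 20691, 1004, 0)
#' mcc(combine_evaluations(list(pos_part, neg_part))) # 0.84
#'
#' @export
combine_evaluations <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L || !all(vapply(parts, is_cm,
                                                            logical(1)))) {
    stop("parts must be a non-empty list of confusion_matrix objects",
         call. = FALSE)
  }
  bases <- vapply(parts, function(p) p$basis, character(1))
  if (length(unique(bases)) != 1L) {
    stop("evaluation basis mismatch: ", paste(unique(bases), collapse = ", "),
         call. = FALSE)
  }
  sum_of <- function(f) sum(vapply(parts, f, numeric(1)))
  any_override <- any(vapply(parts, function(p) {
    !is.null(p$pos_total) || !is.null(p$neg_total)
  }, logical(1)))
  confusion_matrix(
    tp = sum_of(function(p) p$tp), tn = sum_of(function(p) p$tn),
    fp = sum_of(function(p) p$fp), fn = sum_of(function(p) p$fn),
    basis = bases[[1L]],
    pos_total = if (any_override) sum_of(positives),
    neg_total = if (any_override) sum_of(negatives),
    strict = FALSE
  )
}

#' Expand event-level detections to frame counts
#'
#' Screening-video studies often report detection at the event (lesion)
#' level while the classifier runs per frame. Under stated assumptions --
#' every event spans a fixed window of `fps * event_window_s` frames that
#' is either detected or missed whole, and a fixed fraction of each
#' video's frames are false positives -- the event tallies expand to a
#' frame-level confusion matrix:
#'
#' * `w = round(fps * event_window_s)` (or `w = 1` with `per_event = TRUE`),
#' * `tp = (n_events - n_missed) * w`, `fn = n_missed * w`,
#' * `fp = round(fp_fraction_per_video * frames_per_video) * n_videos`,
#' * `tn` = all remaining frames, so the total is conserved at
#'   `n_videos * frames_per_video`.
#'
#' The positive-class total is stated as `n_events * w` (the frames
#' belonging to events), matching how such studies print their class
#' sizes.
#'
#' @param n_videos Number of videos screened.
#' @param frames_per_video Frames per video.
#' @param fps Frame rate (frames/second).
#' @param event_window_s Assumed detectable window around an event, in
#'   seconds.
#' @param fp_fraction_per_video Fraction of each video's frames that are
#'   false positives, in `[0, 1]`.
#' @param n_events Number of true events across all videos.
#' @param n_missed Number of events missed (`<= n_events`).
#' @param per_event Count whole events instead of frames (`w = 1`); the
#'   negative class is still every remaining frame.
#'
#' @return A [confusion_matrix()] on the `"per-frame"` (or `"per-polyp"`)
#'   basis.
#'
#' @examples
#' cm <- expand_events_to_frames(n_videos = 338, frames_per_video = 50000,
#'                               fps = 25, event_window_s = 10,
#'                               fp_fraction_per_video = 0.01,
#'                               n_events = 338, n_missed = 1)
#' ppv(cm) # about 0.33 despite recall near 1
#'
#' @export
expand_events_to_frames <- function(n_videos, frames_per_video, fps,
                                    event_window_s, fp_fraction_per_video,
                                    n_events, n_missed = 0,
                                    per_event = FALSE) {
  vals <- c(n_videos, frames_per_video, fps, event_window_s,
            fp_fraction_per_video, n_events, n_missed)
  if (anyNA(vals) || any(vals < 0)) {
    stop("all expansion assumptions must be non-negative numbers",
         call. = FALSE)
  }
  if (n_missed > n_events) {
    stop("n_missed cannot exceed n_events", call. = FALSE)
  }
  if (fp_fraction_per_video > 1) {
    stop("fp_fraction_per_video must lie in [0, 1]", call. = FALSE)
  }
  w <- if (per_event) 1 else round_metric(fps * event_window_s, 0L)
  total <- n_videos * frames_per_video
  tp <- (n_events - n_missed) * w
  fn <- n_missed * w
  fp <- round_metric(fp_fraction_per_video * frames_per_video, 0L) * n_videos
  tn <- total - tp - fn - fp
  if (tn < 0) {
    stop("expansion assumptions exceed the total number of frames ",
         "(derived tn < 0)", call. = FALSE)
  }
  confusion_matrix(tp, tn, fp, fn,
                   basis = if (per_event) "per-polyp" else "per-frame",
                   pos_total = n_events * w,
                   neg_total = total - n_events * w)
}
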