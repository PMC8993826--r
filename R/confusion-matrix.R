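#' Evaluation bases
#'
#' The unit at which a study counts its predictions. Per-finding evaluation
#' counts detected instances rather than samples, so positive instances may
#' outnumber images and counts need not be integers.
#'
#' @export
cm_bases <- c("per-frame", "per-finding", "per-polyp", "per-patient")

#' Construct a confusion matrix
#'
#' The atom of all computation: the four counts of a 2x2 confusion matrix,
#' together with the evaluation basis and (optionally) explicitly stated
#' class totals.
#'
#' Class totals default to the row sums `tp + fn` (positives) and `tn + fp`
#' (negatives). Published studies with a per-finding flavour of evaluation,
#' or with an unbounded negative class, sometimes state class totals that
#' disagree with the counts (e.g. a table listing zero negatives next to a
#' non-zero false-positive count). Supplying `pos_total`/`neg_total`
#' reproduces that convention: accuracy, recall, specificity and the mixture
#' parameter are then computed against the stated totals, while the
#' predictive values, F1, MCC and threat score always work on the four
#' entries themselves.
#'
#' @param tp,tn,fp,fn Non-negative counts of true positives, true negatives,
#'   false positives and false negatives. Must be whole numbers unless
#'   `basis = "per-finding"` or `strict = FALSE`.
#' @param basis Evaluation basis, one of [cm_bases].
#' @param pos_total,neg_total Optional explicitly stated class totals
#'   overriding `tp + fn` and `tn + fp`.
#' @param strict If `TRUE` (default), counts outside the per-finding basis
#'   must be whole numbers. Set to `FALSE` for normalized (real-valued)
#'   matrices such as the grid points of a prevalence sweep.
#'
#' @return An object of class `confusion_matrix`.
#'
#' @examples
#' cm <- confusion_matrix(tp = 65, tn = 33, fp = 7, fn = 1)
#' all_metrics(cm)
#'
#' @export
confusion_matrix <- function(tp, tn, fp, fn,
                             basis = "per-frame",
                             pos_total = NULL, neg_total = NULL,
                             strict = TRUE) {
  basis <- match.arg(basis, cm_bases)
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (!is.numeric(counts) || length(counts) != 4L || anyNA(counts) ||
      any(!is.finite(counts))) {
    stop("tp, tn, fp, fn must be single finite numbers", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("confusion-matrix counts must be non-negative", call. = FALSE)
  }
  if (strict && basis != "per-finding" &&
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("counts must be whole numbers outside the per-finding basis ",
         "(use strict = FALSE for normalized matrices)", call. = FALSE)
  }
  for (tot in list(pos_total, neg_total)) {
    if (!is.null(tot) &&
        (!is.numeric(tot) || length(tot) != 1L || is.na(tot) || tot < 0)) {
      stop("class totals must be single non-negative numbers", call. = FALSE)
    }
  }
  structure(
    list(tp = unname(tp), tn = unname(tn), fp = unname(fp), fn = unname(fn),
         basis = basis, pos_total = pos_total, neg_total = neg_total),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%s)\n", x$basis))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2,
              dimnames = list(predicted = c("pos", "neg"),
                              truth = c("pos", "neg")))
  print(m)
  pt <- positives(x); nt <- negatives(x)
  if (!is.null(x$pos_total) || !is.null(x$neg_total)) {
    cat(sprintf("stated totals: pos = %s, neg = %s\n",
                format(pt), format(nt)))
  }
  invisible(x)
}

is_cm <- function(x) inherits(x, "confusion_matrix")

#' Class totals of a confusion matrix
#'
#' `positives()` returns the positive-class total (the stated `pos_total`
#' if present, otherwise `tp + fn`); `negatives()` the analogue for the
#' negative class; `grand_total()` their sum.
#'
#' @param cm A [confusion_matrix()].
#' @return A single number.
#' @export
positives <- function(cm) {
  stopifnot(is_cm(cm))
  if (!is.null(cm$pos_total)) cm$pos_total else cm$tp + cm$fn
}

#' @rdname positives
#' @export
negatives <- function(cm) {
  stopifnot(is_cm(cm))
  if (!is.null(cm$neg_total)) cm$neg_total else cm$tn + cm$fp
}

#' @rdname positives
#' @export
grand_total <- function(cm) positives(cm) + negatives(cm)

#' Mixture parameter (prevalence) of an evaluation set
#'
#' The fraction of all samples that belong to the positive class,
#' `N_P / (N_P + N_N)`. The composition of the evaluation set drives the
#' prevalence-dependent metrics (PPV, NPV, accuracy, F1); recall and
#' specificity are invariant to it.
#'
#' @param cm A [confusion_matrix()].
#' @return A number in `[0, 1]`, or `NA` when the set is empty.
#'
#' @examples
#' mixture_parameter(confusion_matrix(97, 55, 12, 46)) # 143 / 210
#'
#' @export
mixture_parameter <- function(cm) {
  gt <- grand_total(cm)
  if (gt == 0) return(NA_real_)
  positives(cm) / gt
}
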