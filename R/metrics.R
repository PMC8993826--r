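#' @keywords internal
"_PACKAGE"

#' Canonical metric names
#'
#' The serialization order and spelling used everywhere in the package:
#' `ACC`, `PREC`, `REC`, `F1`, `SPEC`, `MCC`, `NPV`, `TS`. `PREC` is the
#' positive-class precision (PPV).
#'
#' @export
metric_names <- c("ACC", "PREC", "REC", "F1", "SPEC", "MCC", "NPV", "TS")

div_or_na <- function(num, den) {
  out <- rep(NA_real_, length(den))
  ok <- !is.na(den) & den != 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Binary classification metrics
#'
#' Each metric maps a [confusion_matrix()] to a single value and returns
#' `NA` exactly when its defining denominator is zero, never an error and
#' never `NaN`. All metrics are bounded to `[0, 1]` except the MCC, which
#' is bounded to `[-1, 1]`.
#'
#' * `accuracy()`: `(tp + tn) / (pos + neg)` -- fraction of all samples
#'   classified correctly.
#' * `recall()` (sensitivity, TPR): `tp / pos` -- fraction of positive
#'   samples found.
#' * `specificity()`: `tn / neg` -- the negative-class recall.
#' * `ppv()` (positive precision): `tp / (tp + fp)`.
#' * `npv()` (negative precision): `tn / (tn + fn)`.
#' * `f1_score()`: harmonic mean of precision and recall,
#'   `2 tp / (2 tp + fp + fn)`. Not symmetric between the classes.
#' * `mcc()`: Matthews correlation coefficient,
#'   `(tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; `NA` when any
#'   factor of the denominator vanishes. High only when all four entries
#'   are good, which makes it robust under class imbalance.
#' * `threat_score()` (critical success index): `tp / (tp + fn + fp)`;
#'   ignores true negatives, suited to rare-event detection.
#'
#' `pos` and `neg` are the class totals of the matrix (stated totals when
#' present, row sums otherwise; see [confusion_matrix()]).
#'
#' The MCC denominator is evaluated as the exponential of the half-sum of
#' logarithms of its four factors, so products of counts on the order of
#' 10^7 (and far beyond) cannot overflow.
#'
#' @param cm A [confusion_matrix()].
#' @return A single number, or `NA` where undefined.
#'
#' @examples
#' cm <- confusion_matrix(tp = 3723, tn = 4735, fp = 262, fn = 930)
#' accuracy(cm)     # 0.876...
#' npv(cm)          # 0.836...
#' mcc(cm)          # 0.759...
#' threat_score(cm) # 0.757...
#'
#' @name metrics
NULL

#' @rdname metrics
#' @export
accuracy <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tp + cm$tn, grand_total(cm))
}

#' @rdname metrics
#' @export
recall <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tp, positives(cm))
}

#' @rdname metrics
#' @export
specificity <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tn, negatives(cm))
}

#' @rdname metrics
#' @export
ppv <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tp, cm$tp + cm$fp)
}

#' @rdname metrics
#' @export
npv <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tn, cm$tn + cm$fn)
}

#' @rdname metrics
#' @export
f1_score <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
}

#' @rdname metrics
#' @export
mcc <- function(cm) {
  stopifnot(is_cm(cm))
  mcc_counts(cm$tp, cm$tn, cm$fp, cm$fn)
}

mcc_counts <- function(tp, tn, fp, fn) {
  s <- cbind(tp + fp, tp + fn, tn + fp, tn + fn)
  out <- rep(NA_real_, nrow(s))
  ok <- rowSums(s == 0) == 0
  if (any(ok)) {
    num <- tp[ok] * tn[ok] - fp[ok] * fn[ok]
    out[ok] <- num / exp(0.5 * rowSums(log(s[ok, , drop = FALSE])))
  }
  out
}

#' @rdname metrics
#' @export
threat_score <- function(cm) {
  stopifnot(is_cm(cm))
  div_or_na(cm$tp, cm$tp + cm$fn + cm$fp)
}

#' Compute all eight metrics at once
#'
#' Evaluates every metric of the suite (see [metrics]) on one confusion
#' matrix. Degenerate inputs yield `NA` entries, never errors.
#'
#' @param cm A [confusion_matrix()].
#' @return A named numeric vector of class `metric_set` with entries
#'   [metric_names].
#'
#' @examples
#' all_metrics(confusion_matrix(65, 33, 7, 1))
#'
#' @export
all_metrics <- function(cm) {
  stopifnot(is_cm(cm))
  out <- c(ACC = accuracy(cm), PREC = ppv(cm), REC = recall(cm),
           F1 = f1_score(cm), SPEC = specificity(cm), MCC = mcc(cm),
           NPV = npv(cm), TS = threat_score(cm))
  structure(out, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  v <- unclass(x)
  cat(paste(names(v),
            ifelse(is.na(v), "NA", formatC(v, digits = digits, format = "f")),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
format.metric_set <- function(x, ...) format(unclass(x), ...)

# Vectorized metric suite over parallel count vectors, with the default
# (row-sum) class totals. Used by the solver and the property checks.
metrics_counts <- function(tp, tn, fp, fn) {
  pos <- tp + fn
  neg <- tn + fp
  cbind(
    ACC  = div_or_na(tp + tn, pos + neg),
    PREC = div_or_na(tp, tp + fp),
    REC  = div_or_na(tp, pos),
    F1   = div_or_na(2 * tp, 2 * tp + fp + fn),
    SPEC = div_or_na(tn, neg),
    MCC  = mcc_counts(tp, tn, fp, fn),
    NPV  = div_or_na(tn, tn + fn),
    TS   = div_or_na(tp, tp + fn + fp)
  )
}

#' Round metric values half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.845 at two
#' decimals is 0.85 and -0.005 is -0.01), the convention of printed
#' metric tables. `NA` passes through. A guard of about 1.5e-8 absorbs
#' binary floating-point representation error of decimal inputs.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param decimals Non-negative integer number of decimal places.
#' @return Numeric vector of the same length.
#'
#' @examples
#' round_metric(c(0.9848, 0.5735, 0.845), 2) # 0.98 0.57 0.85
#'
#' @export
round_metric <- function(x, decimals = 2L) {
  if (length(decimals) != 1L || is.na(decimals) || decimals < 0) {
    stop("decimals must be a single non-negative integer", call. = FALSE)
  }
  s <- 10^decimals
  y <- abs(x) * s
  out <- sign(x) * floor(y + 0.5 + sqrt(.Machine$double.eps)) / s
  out[is.na(x)] <- NA_real_
  if (inherits(x, "metric_set")) class(out) <- "metric_set"
  out
}
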