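#' Create a study record
#'
#' One row of a reported-results table: identifiers, class totals where
#' known, the metrics the study reported (at a stated rounding precision),
#' and, when the study printed them, the confusion-matrix counts.
#'
#' @param study_id Study identifier (text).
#' @param set_label Label of the evaluation set within the study, e.g.
#'   `"T2.R1"` (table 2, row 1 of the source study).
#' @param basis Evaluation basis ([cm_bases]) or `NA` when unstated.
#' @param total,pos_total,neg_total Stated totals; `NA` when unknown.
#' @param reported Named numeric vector of reported metric values. Names
#'   must be among [metric_names]; a value of `NA` means the study printed
#'   the metric as undefined ("NA"); metrics absent from the vector were
#'   not reported at all.
#' @param reported_decimals Decimal places at which the reported metrics
#'   were printed (default 2).
#' @param cm Optional [confusion_matrix()] when the study printed counts.
#' @param notes Character vector of free-text annotations.
#'
#' @return An object of class `study_record`.
#'
#' @examples
#' rec <- study_record("2", "T2.R1", basis = "per-frame",
#'                     pos_total = 143, neg_total = 67,
#'                     reported = c(PREC = 0.89, REC = 0.68))
#' solve_record(rec)
#'
#' @export
study_record <- function(study_id, set_label, basis = NA_character_,
                         total = NA_real_, pos_total = NA_real_,
                         neg_total = NA_real_, reported = numeric(),
                         reported_decimals = 2L, cm = NULL,
                         notes = character()) {
  if (!is.na(basis)) basis <- match.arg(basis, cm_bases)
  if (length(reported)) {
    if (is.null(names(reported)) || !all(names(reported) %in% metric_names)) {
      stop("reported metric names must be among: ",
           paste(metric_names, collapse = ", "), call. = FALSE)
    }
    bounds_lo <- ifelse(names(reported) == "MCC", -1, 0)
    bad <- !is.na(reported) & (reported < bounds_lo | reported > 1)
    if (any(bad)) {
      stop("reported metric out of bounds: ",
           paste(sprintf("%s = %g", names(reported)[bad], reported[bad]),
                 collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cm) && !is_cm(cm)) stop("cm must be a confusion_matrix",
                                       call. = FALSE)
  if (is.null(cm) && length(reported) == 0L) {
    stop("a study record needs a confusion matrix or at least one ",
         "reported metric", call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id),
         set_label = as.character(set_label), basis = basis,
         total = total, pos_total = pos_total, neg_total = neg_total,
         reported = reported, reported_decimals = as.integer(reported_decimals),
         cm = cm, notes = notes),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("Study record %s / %s (%s)\n", x$study_id, x$set_label,
              ifelse(is.na(x$basis), "basis unstated", x$basis)))
  cat(sprintf("  totals: total = %s, pos = %s, neg = %s\n",
              format(x$total), format(x$pos_total), format(x$neg_total)))
  if (length(x$reported)) {
    cat("  reported (", x$reported_decimals, " dp): ",
        paste(names(x$reported),
              ifelse(is.na(x$reported), "NA", format(x$reported)),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$cm)) {
    cat(sprintf("  counts: tp = %s, tn = %s, fp = %s, fn = %s\n",
                format(x$cm$tp), format(x$cm$tn), format(x$cm$fp),
                format(x$cm$fn)))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

record_pos <- function(record) {
  if (!is.na(record$pos_total)) record$pos_total
  else if (!is.null(record$cm)) positives(record$cm)
  else NA_real_
}

record_neg <- function(record) {
  if (!is.na(record$neg_total)) record$neg_total
  else if (!is.null(record$cm)) negatives(record$cm)
  else NA_real_
}

#' Derive confusion-matrix counts from recall and precision
#'
#' Reconstructs integer counts from a study that reported recall and
#' precision together with the class totals: `tp = round(rec * pos)`,
#' `fn = pos - tp`, `fp = round(tp / prec - tp)`, `tn = neg - fp`. Rounding
#' is half away from zero and is applied once per derived quantity, `tp`
#' first, so the result matches hand recalculations of published tables.
#'
#' @param pos_total,neg_total Positive / negative class totals (> 0).
#' @param rec,prec Reported recall and precision, each in `(0, 1]`.
#' @param basis Evaluation basis for the result.
#' @param round Derive integer counts (default). With `round = FALSE` the
#'   exact real-valued solution is returned (per-finding basis), which is
#'   occasionally what a published table was computed from.
#'
#' @return A [confusion_matrix()].
#'
#' @examples
#' cm_from_recall_precision(143, 67, rec = 0.68, prec = 0.89)
#'
#' @export
cm_from_recall_precision <- function(pos_total, neg_total, rec, prec,
                                     basis = "per-frame", round = TRUE) {
  if (pos_total <= 0 || neg_total <= 0) {
    stop("class totals must be positive", call. = FALSE)
  }
  if (rec <= 0 || rec > 1 || prec <= 0 || prec > 1) {
    stop("rec and prec must lie in (0, 1]", call. = FALSE)
  }
  rnd <- if (round) function(x) round_metric(x, 0L) else identity
  tp <- rnd(rec * pos_total)
  fn <- pos_total - tp
  fp <- rnd(tp / prec - tp)
  tn <- neg_total - fp
  if (fp > neg_total || tn < 0 || fn < 0) {
    stop(sprintf(paste0("infeasible report: derived counts (tp = %s, fp = %s)",
                        " exceed the class totals"),
                 format(tp), format(fp)),
         call. = FALSE)
  }
  confusion_matrix(tp, tn, fp, fn,
                   basis = if (round) basis else "per-finding",
                   strict = round)
}

feasible_set <- function(solutions, status) {
  structure(list(solutions = solutions, status = status),
            class = "feasible_set")
}

#' @export
print.feasible_set <- function(x, max = 5, ...) {
  cat(sprintf("Feasible set: %d solution(s), status '%s'\n",
              length(x$solutions), x$status))
  for (cm in utils::head(x$solutions, max)) {
    cat(sprintf("  tp = %s, tn = %s, fp = %s, fn = %s\n",
                format(cm$tp), format(cm$tn), format(cm$fp), format(cm$fn)))
  }
  if (length(x$solutions) > max) {
    cat("  ... and", length(x$solutions) - max, "more\n")
  }
  invisible(x)
}

# Conservative integer range for tp (or tn) implied by one reported ratio
# value / total at d decimals; widened by 1 on each side, the exact
# rounding check downstream does the final filtering.
ratio_range <- function(value, total, decimals, upper) {
  h <- 0.5 * 10^-decimals
  lo <- max(0L, floor((value - h) * total) - 1L)
  hi <- min(upper, ceiling((value + h) * total) + 1L)
  if (lo > hi) integer() else seq.int(lo, hi)
}

#' Enumerate confusion matrices compatible with a reported record
#'
#' Searches integer counts `tp` in `[0, pos]` and `fp` in `[0, neg]`
#' (with `fn`, `tn` fixed by the class totals) for all matrices whose
#' recomputed metrics, rounded half away from zero to the record's stated
#' precision, reproduce every reported value. A metric reported as "NA"
#' must be undefined in the candidate too. The ranges are pruned using the
#' intervals implied by reported recall (for `tp`) and specificity (for
#' `fp`); pruning is conservative and is followed by the exact rounding
#' check, so the result is identical to an exhaustive search.
#'
#' An empty feasible set is not an error: it signals an internally
#' inconsistent published report.
#'
#' @param record A [study_record()] with known class totals and at least
#'   one reported metric (or an embedded confusion matrix).
#' @param use_cm If the record carries printed counts, return them as the
#'   unique solution (default). With `use_cm = FALSE` the counts are
#'   ignored and the reported metrics are solved as stated, which is how
#'   printed counts can themselves be cross-checked.
#'
#' @return A `feasible_set`: a list of [confusion_matrix()] solutions
#'   sorted by `(tp, fp)`, and a status of `"unique"`, `"multiple"` or
#'   `"empty"`.
#'
#' @examples
#' rec <- study_record("2", "T2.R1", pos_total = 143, neg_total = 67,
#'                     reported = c(PREC = 0.89, REC = 0.68))
#' solve_record(rec)
#'
#' @export
solve_record <- function(record, use_cm = TRUE) {
  stopifnot(inherits(record, "study_record"))
  if (use_cm && !is.null(record$cm)) {
    return(feasible_set(list(record$cm), "unique"))
  }
  pos <- record_pos(record)
  neg <- record_neg(record)
  if (is.na(pos) || is.na(neg)) {
    stop("class totals unknown: the search space is unbounded", call. = FALSE)
  }
  reported <- record$reported
  if (length(reported) == 0L) {
    stop("no reported metrics to solve against", call. = FALSE)
  }
  d <- record$reported_decimals

  tp_cand <- seq.int(0L, pos)
  if ("REC" %in% names(reported) && !is.na(reported[["REC"]])) {
    tp_cand <- ratio_range(reported[["REC"]], pos, d, pos)
  }
  fp_cand <- seq.int(0L, neg)
  if ("SPEC" %in% names(reported) && !is.na(reported[["SPEC"]])) {
    tn_cand <- ratio_range(reported[["SPEC"]], neg, d, neg)
    fp_cand <- sort(neg - tn_cand)
  }
  if (length(tp_cand) == 0L || length(fp_cand) == 0L) {
    return(feasible_set(list(), "empty"))
  }

  grid <- expand.grid(fp = fp_cand, tp = tp_cand, KEEP.OUT.ATTRS = FALSE)
  tp <- grid$tp; fp <- grid$fp
  tn <- neg - fp; fn <- pos - tp
  m <- metrics_counts(tp, tn, fp, fn)
  ok <- rep(TRUE, nrow(m))
  for (name in names(reported)) {
    v <- reported[[name]]
    col <- m[, name]
    ok <- ok & if (is.na(v)) is.na(col) else {
      !is.na(col) & abs(round_metric(col, d) - v) < 1e-8
    }
  }
  idx <- which(ok)
  idx <- idx[order(tp[idx], fp[idx])]
  basis <- if (is.na(record$basis)) "per-frame" else record$basis
  sols <- lapply(idx, function(i) {
    confusion_matrix(tp[i], tn[i], fp[i], fn[i], basis = basis)
  })
  status <- if (length(sols) == 0L) "empty"
            else if (length(sols) == 1L) "unique"
            else "multiple"
  feasible_set(sols, status)
}

#' Audit a reported study record
#'
#' Recomputes the full metric suite for a record from its feasible
#' confusion matrices and flags every metric as `CONFIRMED` (reported and
#' matching the recomputation within one unit of the stated precision),
#' `DISCREPANT` (reported but not matching) or `MISSING` (not reported;
#' the recomputed value fills the gap).
#'
#' When several matrices are feasible, the first under `(tp, fp)` ordering
#' is used and the multiplicity is noted; no averaging or fabrication of a
#' unique answer. When no matrix reproduces all reported values at the
#' stated precision (an internally inconsistent report) but recall and
#' precision are both reported, the audit falls back to the closed-form
#' derivation of [cm_from_recall_precision()] and notes the inconsistency;
#' without that fallback the audit fails with an error of class
#' `cmaudit_infeasible`.
#'
#' @param record A [study_record()].
#' @param use_cm Passed on to [solve_record()].
#'
#' @return An object of class `audit_report`: the record, the feasible
#'   set, the confusion matrix used, the recomputed `metric_set`, the
#'   per-metric flags, and notes.
#'
#' @examples
#' rec <- study_record("2", "T2.R1", pos_total = 143, neg_total = 67,
#'                     reported = c(ACC = 0.71, PREC = 0.89, REC = 0.68),
#'                     cm = NULL)
#' audit_record(rec)
#'
#' @export
audit_record <- function(record, use_cm = TRUE) {
  stopifnot(inherits(record, "study_record"))
  notes <- character()
  fs <- solve_record(record, use_cm = use_cm)
  if (fs$status == "empty") {
    rep_names <- names(record$reported)
    can_fall_back <- all(c("REC", "PREC") %in% rep_names) &&
      !anyNA(record$reported[c("REC", "PREC")]) &&
      !is.na(record_pos(record)) && !is.na(record_neg(record))
    if (!can_fall_back) {
      stop(structure(
        class = c("cmaudit_infeasible", "error", "condition"),
        list(message = paste0(
               "no confusion matrix reproduces the reported metrics of ",
               record$study_id, "/", record$set_label,
               " at the stated precision"),
             call = sys.call())))
    }
    cm_used <- cm_from_recall_precision(
      record_pos(record), record_neg(record),
      rec = record$reported[["REC"]], prec = record$reported[["PREC"]],
      basis = if (is.na(record$basis)) "per-frame" else record$basis)
    notes <- c(notes, paste(
      "no confusion matrix reproduces all reported values at the stated",
      "precision; counts derived from recall and precision alone"))
  } else {
    cm_used <- fs$solutions[[1L]]
    if (fs$status == "multiple") {
      notes <- c(notes, sprintf(
        "%d feasible matrices; first under (tp, fp) ordering used",
        length(fs$solutions)))
    }
  }
  recomputed <- all_metrics(cm_used)
  tol <- 10^(-record$reported_decimals) + 1e-12
  flags <- vapply(metric_names, function(name) {
    if (!name %in% names(record$reported)) return("MISSING")
    v <- record$reported[[name]]
    r <- recomputed[[name]]
    agree <- (is.na(v) && is.na(r)) ||
      (!is.na(v) && !is.na(r) && abs(v - r) <= tol)
    if (agree) "CONFIRMED" else "DISCREPANT"
  }, character(1))
  structure(
    list(record = record, feasible = fs, cm = cm_used,
         recomputed = recomputed, flags = flags, notes = notes),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("Audit of %s / %s (feasible: %s)\n",
              x$record$study_id, x$record$set_label, x$feasible$status))
  rep_val <- vapply(metric_names, function(n) {
    if (n %in% names(x$record$reported)) {
      v <- x$record$reported[[n]]
      if (is.na(v)) "NA" else format(v)
    } else "-"
  }, character(1))
  rec_val <- ifelse(is.na(x$recomputed), "NA",
                    formatC(unclass(x$recomputed), digits = 4, format = "f"))
  out <- data.frame(metric = metric_names, reported = rep_val,
                    recomputed = rec_val, flag = unname(x$flags))
  print(out, row.names = FALSE)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
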