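rows_to_matrix <- function(rows) {
  if (length(rows) == 0L) stop("no rows to aggregate", call. = FALSE)
  if (is.matrix(rows) || is.data.frame(rows)) {
    m <- as.matrix(rows)
  } else if (is.list(rows)) {
    m <- do.call(rbind, lapply(rows, unclass))
  } else {
    stop("rows must be a list of metric sets or a matrix/data frame",
         call. = FALSE)
  }
  if (nrow(m) == 0L) stop("no rows to aggregate", call. = FALSE)
  if (is.null(colnames(m)) || !all(metric_names %in% colnames(m))) {
    stop("aggregation rows need the metric columns ",
         paste(metric_names, collapse = ", "), call. = FALSE)
  }
  m[, metric_names, drop = FALSE]
}

#' Aggregate per-class or per-fold metric rows
#'
#' `average_metrics()` is the unweighted (macro) per-metric mean;
#' `weighted_average_metrics()` weights each row, conventionally by its
#' positive-class count. Undefined (`NA`) entries are excluded metric by
#' metric, with the weights renormalized over the remaining rows; a metric
#' undefined in every row stays `NA`.
#'
#' By default the row values are first rounded half away from zero to
#' `decimals` places, which is how summary rows of printed tables are
#' produced from the printed per-row values; pass `decimals = NULL` to
#' aggregate at full precision.
#'
#' Macro and weighted aggregation answer different questions from pooling
#' counts ([combine_evaluations()]): they summarize rows as reported,
#' without assuming the underlying sets may be merged.
#'
#' @param rows A list of `metric_set` vectors (or a matrix / data frame
#'   with the columns [metric_names]).
#' @param weights Non-negative numeric vector, one weight per row, with a
#'   positive sum.
#' @param decimals Decimal places at which row values enter the
#'   aggregation (default 2, the precision of printed tables), or `NULL`
#'   for full precision.
#'
#' @return A `metric_set`.
#'
#' @examples
#' r1 <- all_metrics(confusion_matrix(11, 29, 6, 2))
#' r2 <- all_metrics(confusion_matrix(29, 11, 2, 6))
#' average_metrics(list(r1, r2))
#' weighted_average_metrics(list(r1, r2), weights = c(13, 35))
#'
#' @export
average_metrics <- function(rows, decimals = 2L) {
  m <- rows_to_matrix(rows)
  weighted_average_metrics(m, weights = rep(1, nrow(m)), decimals = decimals)
}

#' @rdname average_metrics
#' @export
weighted_average_metrics <- function(rows, weights, decimals = 2L) {
  m <- rows_to_matrix(rows)
  if (length(weights) != nrow(m) || anyNA(weights) || any(weights < 0)) {
    stop("weights must be non-negative, one per row", call. = FALSE)
  }
  if (sum(weights) == 0) {
    stop("total weight must be positive", call. = FALSE)
  }
  if (!is.null(decimals)) m <- round_metric(m, decimals)
  out <- vapply(metric_names, function(name) {
    v <- m[, name]
    ok <- !is.na(v)
    if (!any(ok) || sum(weights[ok]) == 0) return(NA_real_)
    sum(weights[ok] * v[ok]) / sum(weights[ok])
  }, numeric(1))
  structure(out, class = "metric_set")
}
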