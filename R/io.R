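record_schema <- c("study", "set", "basis", "total", "pos", "neg",
                   "tp", "tn", "fp", "fn",
                   "acc", "prec", "rec", "f1", "spec", "mcc", "npv", "ts")
metric_columns <- c("acc", "prec", "rec", "f1", "spec", "mcc", "npv", "ts")

parse_count <- function(x, row, col) {
  if (is.na(x) || !nzchar(x)) return(NA_real_)
  v <- suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  if (is.na(v) || v < 0) {
    stop(sprintf("row %d, column %s: invalid count '%s'", row, col, x),
         call. = FALSE)
  }
  v
}

# "" -> not reported (NULL); "NA" -> reported as undefined; else a number
# inside the metric's bounds.
parse_metric <- function(x, row, col) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  if (identical(x, "NA")) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  lo <- if (col == "mcc") -1 else 0
  if (is.na(v)) {
    stop(sprintf("row %d, column %s: invalid value '%s'", row, col, x),
         call. = FALSE)
  }
  if (v < lo || v > 1) {
    stop(sprintf("row %d, column %s: value %s out of bounds [%d, 1]",
                 row, col, x, lo), call. = FALSE)
  }
  v
}

row_to_record <- function(vals, row, reported_decimals) {
  counts <- vapply(c("tp", "tn", "fp", "fn"), function(col) {
    parse_count(vals[[col]], row, col)
  }, numeric(1))
  total <- parse_count(vals[["total"]], row, "total")
  pos <- parse_count(vals[["pos"]], row, "pos")
  neg <- parse_count(vals[["neg"]], row, "neg")
  basis <- vals[["basis"]]
  basis <- if (is.na(basis) || !nzchar(basis)) NA_character_ else {
    if (!basis %in% cm_bases) {
      stop(sprintf("row %d, column basis: unknown basis '%s'", row, basis),
           call. = FALSE)
    }
    basis
  }
  reported <- numeric()
  for (col in metric_columns) {
    v <- parse_metric(vals[[col]], row, col)
    if (!is.null(v)) {
      reported[toupper(sub("^f1$", "F1", col))] <- v
    }
  }
  cm <- NULL
  if (!anyNA(counts)) {
    cm <- confusion_matrix(
      counts[["tp"]], counts[["tn"]], counts[["fp"]], counts[["fn"]],
      basis = if (is.na(basis)) "per-frame" else basis,
      pos_total = if (!is.na(pos)) pos,
      neg_total = if (!is.na(neg)) neg)
  }
  note <- vals[["note"]]
  study_record(
    study_id = vals[["study"]], set_label = vals[["set"]], basis = basis,
    total = total, pos_total = pos, neg_total = neg,
    reported = reported, reported_decimals = reported_decimals, cm = cm,
    notes = if (!is.null(note) && !is.na(note) && nzchar(note)) note
            else character())
}

#' Read study records from CSV or JSON
#'
#' The CSV schema (header required, UTF-8, comma-separated) is
#' `study,set,basis,total,pos,neg,tp,tn,fp,fn,acc,prec,rec,f1,spec,mcc,npv,ts`;
#' an empty cell means unknown / not reported and the literal string
#' `"NA"` means reported-as-undefined. An optional `note` column carries
#' free-text annotations. The JSON form is an array of objects with the
#' same keys (absent or `null` keys are unknown). Malformed rows are
#' reported with their row number and column.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; by default guessed from the file
#'   extension.
#' @param reported_decimals Precision at which the reported metrics were
#'   printed (default 2).
#' @return A list of [study_record()] objects.
#'
#' @examples
#' path <- system.file("extdata", "table1_reported.csv", package = "cmaudit")
#' length(read_records(path))
#'
#' @export
read_records <- function(path, format = c("auto", "csv", "json"),
                         reported_decimals = 2L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          na.strings = character(), check.names = FALSE,
                          fileEncoding = "UTF-8")
    missing_cols <- setdiff(record_schema, colnames(df))
    if (length(missing_cols)) {
      stop("schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.list(rows)) stop("schema error: expected a JSON array of objects",
                             call. = FALSE)
    rows <- lapply(rows, function(r) {
      out <- lapply(r, function(v) if (is.null(v)) "" else as.character(v))
      for (col in setdiff(c(record_schema, "note"), names(out))) out[[col]] <- ""
      out
    })
  }
  lapply(seq_along(rows), function(i) {
    row_to_record(rows[[i]], row = i, reported_decimals = reported_decimals)
  })
}

format_cell <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) "" else as.character(x)
}

report_row <- function(report) {
  record <- report$record
  cm <- report$cm
  filled <- unclass(report$recomputed)
  metric_cells <- vapply(metric_names, function(n) {
    v <- filled[[n]]
    if (is.na(v)) "NA" else as.character(v)
  }, character(1))
  flag_cells <- unname(report$flags)
  c(study = record$study_id, set = record$set_label,
    basis = format_cell(record$basis),
    total = format_cell(record$total),
    pos = format_cell(record$pos_total), neg = format_cell(record$neg_total),
    tp = as.character(cm$tp), tn = as.character(cm$tn),
    fp = as.character(cm$fp), fn = as.character(cm$fn),
    stats::setNames(metric_cells, metric_columns),
    stats::setNames(flag_cells, paste0("flag_", metric_columns)),
    status = report$feasible$status,
    note = paste(report$notes, collapse = "; "))
}

#' Write audit reports to CSV or markdown
#'
#' Renders audits in the study-record schema of [read_records()] plus one
#' flag column per metric, the feasibility status and notes. Metric cells
#' hold the recomputed (filled-in) values at full precision; undefined
#' values are printed literally as `NA`. The two formats carry identical
#' cell content and the output is deterministic and locale-independent.
#' The CSV is itself a valid record file, so reports can be re-read with
#' [read_records()].
#'
#' @param reports A non-empty list of audits from [audit_record()].
#' @param path Output file, or `""` for standard output.
#' @param format `"csv"` or `"markdown"`.
#' @return Invisibly, the lines written.
#'
#' @export
write_report <- function(reports, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (!is.list(reports) || length(reports) == 0L ||
      !all(vapply(reports, inherits, logical(1), "audit_report"))) {
    stop("reports must be a non-empty list of audit_report objects",
         call. = FALSE)
  }
  rows <- lapply(reports, report_row)
  header <- names(rows[[1L]])
  lines <- if (format == "csv") {
    body <- vapply(rows, function(r) {
      paste(vapply(unname(r), function(cell) {
        if (grepl('[",\n]', cell)) {
          paste0('"', gsub('"', '""', cell), '"')
        } else cell
      }, character(1)), collapse = ",")
    }, character(1))
    c(paste(header, collapse = ","), body)
  } else {
    md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
    c(md_row(header),
      md_row(rep("---", length(header))),
      vapply(rows, function(r) md_row(unname(r)), character(1)))
  }
  con <- if (nzchar(path)) file(path, "w", encoding = "UTF-8") else stdout()
  if (nzchar(path)) on.exit(close(con))
  writeLines(lines, con)
  invisible(lines)
}

#' Packaged fixtures of the reported and recalculated study tables
#'
#' Two machine-readable tables accompany the package: the metrics of five
#' gastroenterology ML studies as originally reported
#' (`"table1_reported"`), and the corresponding recalculated rows with
#' derived confusion-matrix counts, pooled, biased-baseline and summary
#' rows (`"table2_recalculated"`). Cells the source tables print
#' inconsistently are encoded verbatim and annotated in the `note` column
#' (tags `echo:<metric>` for values carried forward from the original
#' report and `unrounded:<metric>` for values computed from unrounded
#' intermediate counts, both irreproducible from the printed integer
#' counts; plus free-text notes on total mismatches and inferred digits)
#' rather than silently corrected.
#'
#' @param table `"table1_reported"` or `"table2_recalculated"`.
#' @param quiet Suppress the per-row messages about annotated
#'   inconsistencies.
#' @return A list of [study_record()] objects; the raw data frame is
#'   available through [fixture_path()] and [read_records()].
#'
#' @examples
#' length(load_fixture("table1_reported"))
#'
#' @export
load_fixture <- function(table = c("table1_reported", "table2_recalculated"),
                         quiet = FALSE) {
  table <- match.arg(table)
  records <- read_records(fixture_path(table))
  if (!quiet) {
    for (rec in records) {
      if (length(rec$notes)) {
        message(sprintf("fixture %s row %s/%s: %s", table, rec$study_id,
                        rec$set_label, paste(rec$notes, collapse = "; ")))
      }
    }
  }
  records
}

#' @rdname load_fixture
#' @export
fixture_path <- function(table = c("table1_reported",
                                   "table2_recalculated")) {
  table <- match.arg(table)
  system.file("extdata", paste0(table, ".csv"), package = "cmaudit",
              mustWork = TRUE)
}

#' Generate synthetic study records
#'
#' Draws records from the mixture model that underlies the prevalence
#' analysis: for each record the positive-class size is
#' `Binomial(size, alpha)`, true positives are `Binomial(pos, rec)` and
#' true negatives `Binomial(neg, spec)`; the reported metrics are the full
#' recomputed suite rounded to `decimals` places. Reproducible given
#' `seed`. Useful as ground truth for solver round-trip checks: the
#' generating matrix must always be in the feasible set of its own rounded
#' report.
#'
#' @param n Number of records.
#' @param alpha Mixture parameter (prevalence) in `[0, 1]`.
#' @param rec,spec True recall and specificity of the simulated classifier.
#' @param size Evaluation-set size per record.
#' @param seed Integer seed (required; the generator is deterministic).
#' @param decimals Rounding precision of the reported metrics.
#' @param keep_cm Attach the generating matrix to each record (default);
#'   with `FALSE` the records carry totals and rounded metrics only.
#' @return A list of [study_record()] objects.
#'
#' @examples
#' recs <- generate_synthetic_records(3, alpha = 0.3, rec = 0.9,
#'                                    spec = 0.95, size = 100, seed = 1)
#' recs[[1]]
#'
#' @export
generate_synthetic_records <- function(n, alpha = 0.5, rec = 0.85,
                                       spec = 0.9, size = 200, seed,
                                       decimals = 2L, keep_cm = TRUE) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (alpha < 0 || alpha > 1 || rec < 0 || rec > 1 || spec < 0 || spec > 1) {
    stop("alpha, rec and spec must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    pos <- stats::rbinom(1L, size, alpha)
    neg <- size - pos
    tp <- stats::rbinom(1L, pos, rec)
    tn <- stats::rbinom(1L, neg, spec)
    cm <- confusion_matrix(tp, tn, neg - tn, pos - tp)
    reported <- round_metric(unclass(all_metrics(cm)), decimals)
    study_record(
      study_id = sprintf("SYN%04d", i), set_label = "R1",
      basis = "per-frame", total = size, pos_total = pos, neg_total = neg,
      reported = reported, reported_decimals = decimals,
      cm = if (keep_cm) cm)
  })
}
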