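# Independent re-implementations used as oracles. These deliberately avoid
# the package's own helpers: metrics are written out formula by formula and
# the exhaustive solver enumerates the full grid without pruning.

oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- as.double(tp); tn <- as.double(tn)
  fp <- as.double(fp); fn <- as.double(fn)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(ACC  = sdiv(tp + tn, tp + tn + fp + fn),
    PREC = sdiv(tp, tp + fp),
    REC  = sdiv(tp, tp + fn),
    F1   = sdiv(2 * tp, 2 * tp + fp + fn),
    SPEC = sdiv(tn, tn + fp),
    MCC  = if (denom == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(denom),
    NPV  = sdiv(tn, tn + fn),
    TS   = sdiv(tp, tp + fn + fp))
}

# Decimal half-away-from-zero, written independently of round_metric.
oracle_round <- function(x, d) {
  ifelse(is.na(x), NA_real_,
         sign(x) * floor(abs(x) * 10^d + 0.5 + 1e-9) / 10^d)
}

# Unpruned exhaustive search over the full (tp, fp) grid.
oracle_solve <- function(pos, neg, reported, d) {
  hits <- list()
  for (tp in 0:pos) {
    for (fp in 0:neg) {
      m <- oracle_metrics(tp, neg - fp, fp, pos - tp)
      ok <- TRUE
      for (name in names(reported)) {
        v <- reported[[name]]
        ok <- ok && if (is.na(v)) is.na(m[[name]]) else {
          !is.na(m[[name]]) && isTRUE(abs(oracle_round(m[[name]], d) - v) < 1e-8)
        }
      }
      if (ok) hits[[length(hits) + 1L]] <- c(tp = tp, fp = fp)
    }
  }
  hits
}

random_cm <- function(max_class = 250) {
  pos <- sample.int(max_class, 1L)
  neg <- sample.int(max_class, 1L)
  tp <- sample.int(pos + 1L, 1L) - 1L
  tn <- sample.int(neg + 1L, 1L) - 1L
  confusion_matrix(tp, tn, neg - tn, pos - tp)
}

fixture_tags <- function(record) {
  note <- paste(record$notes, collapse = " ")
  m <- regmatches(note, gregexpr("(echo|unrounded):[a-z0-9]+", note))[[1]]
  toupper(sub("^[a-z]+:", "", m))
}
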