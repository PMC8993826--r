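# cmaudit

Confusion-matrix metrics, reconstruction and reporting audits for binary
classifiers in medical AI studies.

Clinical machine-learning papers typically report a few headline metrics
(accuracy, sensitivity, sometimes precision) at two decimal places. Every
standard binary-classification metric, however, is a deterministic function
of the four confusion-matrix counts TP, TN, FP, FN — so a partial report
plus the class totals often determines the counts nearly uniquely, and with
them every metric the authors *didn't* report. cmaudit is a library and
command-line tool for readers, reviewers and authors who want to:

* compute the full metric suite — accuracy (ACC), recall/sensitivity (REC),
  specificity (SPEC), precision as PPV and NPV, F1, Matthews correlation
  coefficient (MCC) and threat score / critical success index (TS) — with
  explicit `NA` semantics where a denominator vanishes;
* reconstruct confusion-matrix counts from reported metrics
  (`cm_from_recall_precision()` closed form, `solve_record()` exhaustive
  integer search at the stated rounding precision);
* audit a published record: confirm, contradict or fill in each metric
  (`audit_record()`, flags `CONFIRMED` / `DISCREPANT` / `MISSING`);
* probe scenarios: metrics across class admixtures
  (`prevalence_sweep()` over the mixture
  `p(x, α) = α p_P(x) + (1 − α) p_N(x)`), degenerate biased baselines
  (`biased_classifier()`), pooling of separately reported per-class tests
  (`combine_evaluations()`), and event-to-frame expansion of screening
  studies (`expand_events_to_frames()`);
* aggregate per-class rows as macro (`average_metrics()`) or weighted
  (`weighted_average_metrics()`) summaries.

The package ships machine-readable fixtures of the reported and
recalculated metric tables of five published gastroenterology studies
(`load_fixture()`), encoded verbatim with annotations where the source
tables disagree with their own printed counts.

## Worked example

A gastric-cancer detector was evaluated on 4653 cancer and 4997 normal
images; the study reported accuracy 0.88, sensitivity 0.80, specificity
0.95 and PPV 0.93, and printed its confusion matrix. The full suite from
the printed counts:

```r
library(cmaudit)
cm <- confusion_matrix(tp = 3723, tn = 4735, fp = 262, fn = 930)
all_metrics(cm)
#> ACC 0.8765  PREC 0.9343  REC 0.8001  F1 0.8620  SPEC 0.9476  MCC 0.7588  NPV 0.8358  TS 0.7575
```

The reported numbers check out, but the omitted ones change the story: the
NPV (0.84) is well below the PPV (0.93) — the model misses cancers far more
often than it raises false alarms — and the MCC (0.76) and TS (0.76) sit
below every reported metric. Had the counts *not* been printed, the same
conclusion follows from the reported metrics alone:

```r
rec <- study_record("5", "T1", pos_total = 4653, neg_total = 4997,
                    reported = c(ACC = 0.88, PREC = 0.93,
                                 REC = 0.80, SPEC = 0.95))
audit_record(rec)
#> Audit of 5 / T1 (feasible: multiple)
#>  metric reported recomputed      flag
#>     ACC     0.88     0.8750 CONFIRMED
#>    PREC     0.93     0.9349 CONFIRMED
#>     REC      0.8     0.7963 CONFIRMED
#>      F1        -     0.8600   MISSING
#>    SPEC     0.95     0.9484 CONFIRMED
#>     MCC        -     0.7563   MISSING
#>     NPV        -     0.8333   MISSING
#>      TS        -     0.7544   MISSING
#> notes: 501 feasible matrices; first under (tp, fp) ordering used
```

Every matrix compatible with the four reported values yields an MCC within
a point of 0.76 — the audit recovers the unreported picture without access
to the data.

From the shell, the same computations:

```sh
Rscript inst/cli/cmaudit.R compute --tp 3723 --tn 4735 --fp 262 --fn 930
Rscript inst/cli/cmaudit.R audit --input inst/extdata/table1_reported.csv
Rscript inst/cli/cmaudit.R sweep --rec 0.997 --spec 0.99 --points 99
```

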