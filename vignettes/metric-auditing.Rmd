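---
title: "Auditing binary-classification metrics in medical AI studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing binary-classification metrics in medical AI studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaudit)
```

## The problem

Clinical machine-learning studies routinely summarize a binary classifier
with a handful of headline numbers -- an accuracy, a sensitivity, sometimes
a precision -- chosen and rounded by the authors. Because every standard
metric is a deterministic function of the four confusion-matrix counts
(TP, TN, FP, FN), a reported subset of metrics plus the class totals often
pins those counts down almost completely. That makes published evaluations
*auditable*: one can reconstruct the counts, recompute the full metric
suite, fill in what was omitted (typically the negative-predictive value,
the Matthews correlation coefficient and the threat score), and flag
reported values that are inconsistent with the study's own numbers.

cmaudit implements that audit loop end to end: exact metric definitions
with explicit undefined-value semantics, an exhaustive integer solver for
the counts, prevalence and bias scenario analysis, per-class aggregation,
and fixtures holding the reported and recalculated tables of five
gastroenterology studies.

## The metric suite and its undefined values

All eight metrics are computed from a `confusion_matrix(tp, tn, fp, fn)`:

* ACC = (TP+TN)/(P+N), REC = TP/P, SPEC = TN/N,
* PREC (= PPV) = TP/(TP+FP), NPV = TN/(TN+FN),
* F1 = 2TP/(2TP+FP+FN),
* MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
* TS (critical success index) = TP/(TP+FN+FP),

where P and N are the class totals. A metric whose defining denominator is
zero is returned as `NA` -- never an error, never silent `NaN`. For the MCC
we return `NA` whenever any of the four denominator factors vanishes; some
literatures define MCC = 0 there, but the tables we reproduce print "NA",
and a correlation between a constant and anything is genuinely undefined.
The MCC denominator is evaluated as `exp(0.5 * sum(log(...)))`, so products
of screening-scale counts (10^7 per factor, 10^28 overall) cannot overflow.

### Stated class totals

`confusion_matrix()` accepts optional `pos_total` / `neg_total` overrides.
They exist because published tables sometimes state class totals that
disagree with the entry sums: detection studies with an unbounded negative
class print NEG = 0 next to a non-zero FP count (every frame or pixel not
containing a lesion is in principle a true negative, so "the" negative
total is a modelling choice), and per-finding evaluations can have more
positive instances than samples. When totals are stated, ACC, REC, SPEC and
the mixture parameter use them; PREC, NPV, F1, MCC and TS always work on
the four entries. With no overrides the totals are the row sums and
everything reduces to the textbook formulas. This single convention
reproduces every prevalence-dependent cell of the recalculated tables,
including the specificity printed as NA when the stated negative class is
empty.

### Rounding

Printed tables round half away from zero; `round_metric()` implements that
convention (0.845 -> 0.85 at two decimals, -0.005 -> -0.01) with a ~1.5e-8
guard for binary representation of decimal inputs. The same convention
defines the solver's feasibility test, which keeps the two exactly
consistent.

## Reconstructing counts from reported metrics

Given class totals and reported recall and precision,
`cm_from_recall_precision()` applies the closed form
`tp = round(rec * pos)`, `fn = pos - tp`, `fp = round(tp/prec - tp)`,
`tn = neg - fp`, rounding once per quantity with `tp` first -- the order a
careful reader reproduces a table with. Derived counts outside the class
totals raise an infeasible-report error.

`solve_record()` generalizes this to any subset of the eight metrics: it
enumerates integer `tp` in `[0, pos]` and `fp` in `[0, neg]` and keeps the
candidates whose recomputed metrics, rounded to the record's stated
precision, equal every reported value (a metric reported as "NA" must be
undefined in the candidate). A value `v` printed at `d` decimals is thereby
treated as the half-open interval `[v - h, v + h)` with `h = 0.5 * 10^-d`,
which is exactly the preimage of half-away-from-zero rounding -- so the
matrix that generated a report is always in the feasible set of that
report, a property the tests exercise on thousands of random matrices.
Reported recall and specificity prune the `tp` and `fp` ranges (the pruning
is conservative, by design one candidate wider than the implied interval,
and the exact check runs afterwards, so the result is identical to the
unpruned exhaustive search -- also asserted in the tests). An empty
feasible set is a *finding*, not an error: the published report is
internally inconsistent.

`audit_record()` then recomputes all eight metrics from the first feasible
matrix under `(tp, fp)` ordering (multiplicity is reported, never averaged
away) and flags each metric `CONFIRMED`, `DISCREPANT` or `MISSING`. For an
internally inconsistent report with recall and precision available, the
audit falls back to the closed form above and says so in its notes; that
choice mirrors how the source recalculations were evidently produced, and
it keeps the audit informative exactly where it is most needed.

## Scenario analysis

**Prevalence sweeps.** Writing the data distribution as the mixture
`p(x, alpha) = alpha * p_P(x) + (1 - alpha) * p_N(x)`, recall and
specificity are properties of the classifier alone, while accuracy, PPV,
NPV, F1 and TS depend on the mixture parameter `alpha` (the prevalence).
`prevalence_sweep()` evaluates the suite on the normalized real-valued
matrix at each grid point. PPV rises and NPV falls strictly in `alpha`;
at a screening-style prevalence of 0.005, a classifier with recall 0.997
and specificity 0.99 has a PPV of only 0.33.

```{r sweep}
curve <- prevalence_sweep(rec = 0.997, spec = 0.99,
                          alpha_grid = c(0.005, 0.5))
round_metric(curve$PREC, 2)
```

**Biased baselines and pooling.** `biased_classifier()` builds the
degenerate all-positive / all-negative matrices, the cheapest way to see
what a headline metric hides under imbalance. `combine_evaluations()` sums
per-class (or per-fold) matrices that a study reported separately; stated
totals are summed alongside, so pooled rows keep the stated-total
convention of their parts.

**Event-to-frame expansion.** Detection studies reporting at the event
(lesion) level can be re-expressed per frame under explicit assumptions:
every event occupies a window of `round(fps * window_s)` frames detected or
missed whole, and a fixed fraction of each video's frames are false
positives. `expand_events_to_frames()` performs the expansion, conserving
the total frame count `n_videos * frames_per_video`. The positive-class
total is stated as `n_events * w`, the convention of the tables this
mirrors. In the screening chain shipped in the fixtures (338 videos of
50,000 frames -- the video count is a parameter, inferred from the printed
total of 16,900,000 frames, never hard-coded), the source table prints
TP = 84,500 while also printing FN = 250 against a positive class of
84,500; those cells double-count the missed event's frames. We keep the
counts self-consistent (TP = 84,250 = 337 detected windows of 250 frames)
and reproduce every printed *metric* of the row, plus TN, FP and FN
exactly.

## Aggregation

`average_metrics()` (macro) and `weighted_average_metrics()` summarize
rows as reported; pooled (micro) aggregation is what
`combine_evaluations()` does, and no third scheme is offered. The source
table's weighted row is reproduced with weights equal to each row's
positive-class count -- the weights are not stated there and are documented
as inferred. Both functions round the rows to two decimals before
aggregating by default, because that is demonstrably how the printed
summary rows were built (their AVG NPV cell reads 0.79 where full-precision
arithmetic gives 0.795); `decimals = NULL` aggregates at full precision.
`NA` entries drop out metric by metric with weights renormalized.

## The packaged tables and their blemishes

`load_fixture()` returns the reported table (15 records) and the
recalculated table (20 records) as study records. The fixtures are
deliberately verbatim: rows whose stated totals disagree with their entry
sums, a garbled false-positive cell (encoded as 1255 − 251 = 1004 from the
pooled row's arithmetic), and six metric cells that cannot be reproduced
from their own printed counts are all annotated in a `note` column (tags
`echo:<metric>` for values carried forward from the reported table and
`unrounded:<metric>` for values computed from unrounded intermediate
counts) rather than corrected. The regression test asserts agreement
within ±0.01 -- the slack of two-decimal printing -- on every un-annotated
cell, and asserts that the annotated cells genuinely deviate. Auditing
tables should start by admitting where the audited table disagrees with
itself.

## Synthetic records

`generate_synthetic_records()` draws records from the same mixture model:
`pos ~ Binomial(size, alpha)`, `tp ~ Binomial(pos, rec)`,
`tn ~ Binomial(neg, spec)`, with the reported metrics being the rounded
recomputed suite. Defaults (`alpha = 0.5`, `rec = 0.85`, `spec = 0.9`,
`size = 200`) describe a moderately sized, balanced validation set with a
clinically plausible operating point -- comparable to the smaller studies
in the fixtures. The generator emulates sampling noise in the class split
and in both error rates; it does not emulate within-video correlation of
frames, label noise, or data-dependent threshold tuning, so solver and
audit tests built on it demonstrate arithmetic correctness, not robustness
of any real model.

## Numerical and scale choices

Solver work is vectorized over the pruned `(tp, fp)` grid; with all eight
metrics reported at two decimals the grid is a few dozen candidates, and
class totals up to 500 solve in milliseconds. The test suite runs the
round-trip property on 60 matrices at 2 and 3 decimals plus 1,000 matrices
in the acceptance pass, oracle-equivalence on 25 random instances, and
bounds on 10,000 random matrices; the whole suite completes in about a
minute and a half on one core. Boundary ties in feasibility are resolved by
the rounding convention itself (half away from zero, hence low-inclusive
intervals); degenerate inputs (empty classes, all-zero matrices) flow
through as `NA` everywhere.

## Limitations

* Reconstruction needs class totals; records without them (several
  in-text rows of the reported table) can be stored and rendered but not
  solved.
* The audit assumes metrics were rounded half away from zero at the stated
  precision; a source that truncated instead would need a different
  interval convention.
* AUROC/AUPRC are out of scope -- they are not functions of a single
  confusion matrix -- as are multi-class, detection and segmentation
  evaluations.
* A feasible set of size one proves uniqueness only at the stated
  precision; more precise reporting could still distinguish matrices the
  solver cannot.
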