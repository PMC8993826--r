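test_that("recall-precision closed form reproduces recalculated counts", {
  cases <- list(
    # pos, neg, rec, prec -> tp, tn, fp, fn
    list(143, 67, 0.68, 0.89, c(97, 55, 12, 46)),
    list(100, 100, 1.0, 1.0, c(100, 100, 0, 0)),
    list(13, 35, 0.85, 0.65, c(11, 29, 6, 2)),
    list(35, 13, 0.83, 0.94, c(29, 11, 2, 6))
  )
  for (case in cases) {
    cm <- cm_from_recall_precision(case[[1]], case[[2]], case[[3]], case[[4]])
    expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), case[[5]])
  }
})

test_that("closed form rejects reports whose counts cannot exist", {
  expect_error(cm_from_recall_precision(100, 5, rec = 1, prec = 0.5),
               "infeasible")
  expect_error(cm_from_recall_precision(0, 10, rec = 0.5, prec = 0.5),
               "positive")
  expect_error(cm_from_recall_precision(10, 10, rec = 1.2, prec = 0.5),
               "\\(0, 1\\]")
})

test_that("records with printed counts solve to themselves", {
  cm <- confusion_matrix(65, 33, 7, 1)
  rec <- study_record("3", "T1", cm = cm)
  fs <- solve_record(rec)
  expect_identical(fs$status, "unique")
  expect_identical(fs$solutions[[1]], cm)
})

test_that("solver equals the unpruned exhaustive search", {
  # the published row: precision and recall pin the counts down
  rec <- study_record("2", "T2.R1", pos_total = 143, neg_total = 67,
                      reported = c(PREC = 0.89, REC = 0.68))
  fs <- solve_record(rec)
  tps <- vapply(fs$solutions, function(s) s$tp, numeric(1))
  fps <- vapply(fs$solutions, function(s) s$fp, numeric(1))
  expect_true(any(tps == 97 & fps == 12))
  oracle <- oracle_solve(143, 67, c(PREC = 0.89, REC = 0.68), 2)
  expect_equal(length(fs$solutions), length(oracle))
  expect_equal(cbind(tps, fps),
               cbind(tps = vapply(oracle, `[[`, numeric(1), "tp"),
                     fps = vapply(oracle, `[[`, numeric(1), "fp")))

  # adding the (internally inconsistent) reported accuracy empties the set
  rec2 <- study_record("2", "T2.R1", pos_total = 143, neg_total = 67,
                       reported = c(ACC = 0.71, PREC = 0.89, REC = 0.68))
  expect_identical(solve_record(rec2)$status, "empty")

  # randomized oracle-equivalence sweep on small instances
  withr::with_seed(2024, {
    for (i in 1:20) {
      pos <- sample.int(60, 1); neg <- sample.int(60, 1)
      tp <- sample.int(pos + 1, 1) - 1; tn <- sample.int(neg + 1, 1) - 1
      m <- oracle_metrics(tp, tn, neg - tn, pos - tp)
      picked <- sample(metric_names, sample.int(4, 1))
      reported <- oracle_round(m[picked], 2)
      r <- study_record("sim", as.character(i), pos_total = pos,
                        neg_total = neg, reported = reported)
      fs <- solve_record(r)
      oracle <- oracle_solve(pos, neg, reported, 2)
      got <- vapply(fs$solutions, function(s) paste(s$tp, s$fp), character(1))
      want <- vapply(oracle, function(s) paste(s[["tp"]], s[["fp"]]),
                     character(1))
      expect_equal(sort(got), sort(want))
      expect_true(paste(tp, neg - tn) %in% got)
    }
  })
})

test_that("round-trip: the generating matrix is always feasible", {
  withr::with_seed(77, {
    for (d in c(2L, 3L)) {
      for (i in 1:60) {
        cm <- random_cm()
        reported <- round_metric(unclass(all_metrics(cm)), d)
        r <- study_record("rt", as.character(i),
                          pos_total = positives(cm), neg_total = negatives(cm),
                          reported = reported, reported_decimals = d)
        fs <- solve_record(r)
        hit <- any(vapply(fs$solutions, function(s) {
          s$tp == cm$tp && s$fp == cm$fp
        }, logical(1)))
        expect_true(hit)
      }
    }
  })
})

test_that("adding a reported metric never enlarges the feasible set", {
  withr::with_seed(15, {
    for (i in 1:15) {
      cm <- random_cm(120)
      full <- round_metric(unclass(all_metrics(cm)), 2)
      full <- full[!is.na(full)]
      keys <- function(fs) vapply(fs$solutions,
                                  function(s) paste(s$tp, s$fp), character(1))
      subset_names <- sample(names(full), max(1, length(full) - 3))
      base_rec <- study_record("m", "a", pos_total = positives(cm),
                               neg_total = negatives(cm),
                               reported = full[subset_names])
      larger <- keys(solve_record(base_rec))
      extra <- setdiff(names(full), subset_names)
      if (length(extra) == 0) next
      more_rec <- study_record("m", "b", pos_total = positives(cm),
                               neg_total = negatives(cm),
                               reported = full[c(subset_names, extra[1])])
      smaller <- keys(solve_record(more_rec))
      expect_true(all(smaller %in% larger))
    }
  })
})

test_that("closed form is consistent with the solver at full precision", {
  withr::with_seed(42, {
    for (i in 1:25) {
      cm <- random_cm(200)
      if (cm$tp == 0 || positives(cm) == 0 || negatives(cm) == 0) next
      r <- recall(cm); p <- ppv(cm)
      if (is.na(p) || p == 0) next
      derived <- cm_from_recall_precision(positives(cm), negatives(cm), r, p)
      expect_equal(c(derived$tp, derived$fp), c(cm$tp, cm$fp))
      rec <- study_record("fp", "x", pos_total = positives(cm),
                          neg_total = negatives(cm),
                          reported = round_metric(c(REC = r, PREC = p), 6),
                          reported_decimals = 6L)
      fs <- solve_record(rec)
      expect_true(any(vapply(fs$solutions, function(s) {
        s$tp == derived$tp && s$fp == derived$fp
      }, logical(1))))
    }
  })
})

test_that("solver demands class totals and at least one reported value", {
  expect_error(solve_record(study_record("x", "y",
                                         reported = c(REC = 0.9))),
               "unbounded")
  cm <- confusion_matrix(5, 5, 0, 0)
  expect_error(solve_record(study_record("x", "y", cm = cm), use_cm = FALSE),
               "no reported metrics")
})

test_that("audit flags discrepant, confirmed and missing metrics", {
  # inconsistent published row: accuracy does not match its own prec/rec
  rec <- study_record("2", "T2.R1", pos_total = 143, neg_total = 67,
                      reported = c(ACC = 0.71, PREC = 0.89, REC = 0.68,
                                   F1 = 0.75))
  rep <- audit_record(rec)
  expect_identical(rep$feasible$status, "empty")
  expect_length(rep$notes, 1)
  expect_identical(unname(rep$flags[c("ACC", "PREC", "REC", "F1")]),
                   c("DISCREPANT", "CONFIRMED", "CONFIRMED", "DISCREPANT"))
  expect_identical(unname(rep$flags["NPV"]), "MISSING")
  expect_equal(round_metric(rep$recomputed[["ACC"]], 2), 0.72)
  expect_equal(rep$recomputed[["NPV"]], 0.55, tolerance = 0.011)

  # a self-consistent record confirms everything it reports
  cm <- confusion_matrix(29, 11, 2, 6)
  own <- study_record("2", "T3.R2", pos_total = 35, neg_total = 13,
                      reported = round_metric(unclass(all_metrics(cm)), 2))
  expect_true(all(audit_record(own)$flags == "CONFIRMED"))

  # filled-in MCC for the gastric-cancer study from reported metrics alone
  s5 <- study_record("5", "T1", pos_total = 4653, neg_total = 4997,
                     reported = c(ACC = 0.88, REC = 0.80, SPEC = 0.95,
                                  PREC = 0.93))
  rep5 <- audit_record(s5)
  expect_identical(unname(rep5$flags["MCC"]), "MISSING")
  expect_equal(rep5$recomputed[["MCC"]], 0.76, tolerance = 0.011)
})

test_that("audit without a recall-precision fallback fails loudly", {
  rec <- study_record("x", "y", pos_total = 10, neg_total = 10,
                      reported = c(ACC = 0.431))  # unreachable at 2 dp
  expect_error(audit_record(rec), class = "cmaudit_infeasible")
})
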