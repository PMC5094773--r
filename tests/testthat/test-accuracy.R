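# naive per-record oracle for the confusion counts
oracle_confusion <- function(values, positive, threshold, direction) {
  keep <- !is.na(values)
  v <- values[keep]
  y <- positive[keep]
  tpos <- if (direction == "le") v <= threshold else v >= threshold
  c(tp = sum(tpos & y), fp = sum(tpos & !y),
    tn = sum(!tpos & !y), fn = sum(!tpos & y))
}

test_that("confusion metrics match a brute-force count and handle degeneracy", {
  acc <- confusion_metrics(c(20, 26, 24, 30), c(TRUE, FALSE, TRUE, FALSE), 25, "le")
  expect_equal(acc$sensitivity, 1)
  expect_equal(acc$specificity, 1)
  expect_identical(acc$lr_pos, Inf)

  allneg <- confusion_metrics(c(20, 30), c(FALSE, FALSE), 25, "le")
  expect_true(is.na(allneg$sensitivity))
  expect_false(is.na(allneg$specificity))
  expect_match(allneg$undefined, "sensitivity")

  set.seed(41)
  for (dir in c("le", "ge")) {
    v <- round(rnorm(200, 30, 6))
    v[sample(200, 15)] <- NA
    y <- runif(200) < 0.3
    for (t in c(20, 28, 35)) {
      acc <- confusion_metrics(v, y, t, dir)
      o <- oracle_confusion(v, y, t, dir)
      expect_equal(c(tp = acc$tp, fp = acc$fp, tn = acc$tn, fn = acc$fn), o)
      expect_equal(acc$lr_pos, acc$sensitivity / (1 - acc$specificity))
    }
  }
})

test_that("CL sweeps are monotone and satisfy the Bayes identity on every row", {
  co <- small_default_cohort(13)
  for (tp in c("A", "B", "C")) {
    sw <- sweep_cl(co, tp)
    expect_true(all(diff(sw$sensitivity) >= 0))
    expect_true(all(diff(sw$specificity) <= 0))
    pi <- (sw$tp + sw$fn) / sw$n
    ppv_bayes <- sw$sensitivity * pi /
      (sw$sensitivity * pi + (1 - sw$specificity) * (1 - pi))
    ok <- !is.na(sw$ppv)
    expect_equal(sw$ppv[ok], ppv_bayes[ok])
  }
  # constant denominators when nothing is missing
  full <- make_records(40, cl_a = round(runif(40, 15, 45)),
                       ga_birth = rep(ga_days(c("34+0", "39+0")), 20))
  sw <- sweep_cl(full, "A")
  expect_true(all(sw$n == 40))
})

test_that("delta sweeps use pre-cerclage intervals and the >= predicate", {
  co <- make_records(2, cl_a = c(30, 30), cl_b = c(21, 30),
                     ga_birth = ga_days(c("34+0", "39+0")))
  sw <- sweep_delta(co, "A-B", thresholds = 20)
  expect_equal(sw$sensitivity, 1)   # GROUP2 shortened 30%
  expect_equal(sw$specificity, 1)   # GROUP1 shortened 0%
  # d = 0 makes every non-lengthening record test-positive
  sw0 <- sweep_delta(co, "A-B", thresholds = 0)
  expect_equal(sw0$tp + sw0$fp, 2L)
})

test_that("empty test-negative cells render NPV as 100% when no positives are missed", {
  co <- make_records(4, cl_a = c(20, 25, 30, 35),
                     ga_birth = rep(ga_days(c("34+0", "39+0")), 2))
  sw <- sweep_cl(co, "A", thresholds = 50)
  expect_true(is.na(sw$npv))          # no test-negative records
  expect_equal(sw$npv_pct, 100)       # reporting convention
  expect_equal(sw$s_pct, 100)
})

test_that("ROC construction: corners, AUC, symmetry, and a null measurement", {
  v <- c(10, 12, 14, 30, 32, 35)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_curve(v, y, "le")
  expect_equal(auc(r), 1)
  expect_equal(auc(roc_curve(v, y, "ge")), 1 - auc(r))
  expect_error(roc_curve(v, rep(TRUE, 6)), "positive and one negative")

  set.seed(57)
  v <- rnorm(4000)
  y <- runif(4000) < 0.5
  expect_equal(auc(roc_curve(v, y, "le")), 0.5, tolerance = 0.05)
})

test_that("ROC matches an established implementation on a synthetic cohort", {
  skip_if_not_installed("pROC")
  co <- small_default_cohort(29)
  keep <- !is.na(co$cl_c)
  ours <- auc(roc_curve(co$cl_c[keep], co$risk_group[keep] == "GROUP2", "le"))
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = co$risk_group[keep] == "GROUP2", predictor = co$cl_c[keep],
    direction = ">", quiet = TRUE
  )))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})
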