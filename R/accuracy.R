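#' Diagnostic accuracy of a threshold predicate
#'
#' Builds the 2x2 confusion of a test predicate against the GROUP2 outcome
#' (preterm birth and/or cerclage — always the positive class) and derives
#' sensitivity, specificity, predictive values and the positive likelihood
#' ratio `S / (1 - Sp)` from the unrounded counts. Records with a missing
#' measurement are excluded from the denominator. Metrics whose cell is
#' empty are `NA` with a note in `undefined`; a likelihood ratio at perfect
#' specificity is `Inf`.
#'
#' @param values Per-record measurement (CL in mm or %-change).
#' @param positive Logical per-record GROUP2 indicator.
#' @param threshold Test threshold.
#' @param direction `"le"` (test-positive when `values <= threshold`, the CL
#'   convention) or `"ge"` (`values >= threshold`, the %-change convention).
#' @return A one-row `accuracy_result` tibble: `tp`, `fp`, `tn`, `fn`, `n`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `lr_pos`, `undefined`.
#' @examples
#' confusion_metrics(c(20, 26, 24, 30), c(TRUE, FALSE, TRUE, FALSE), 25, "le")
#' @export
confusion_metrics <- function(values, positive, threshold,
                              direction = c("le", "ge")) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(positive)
  v <- values[keep]
  y <- positive[keep]
  test_pos <- if (direction == "le") v <= threshold else v >= threshold
  tp <- sum(test_pos & y)
  fp <- sum(test_pos & !y)
  fn <- sum(!test_pos & y)
  tn <- sum(!test_pos & !y)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  lr <- if (is.na(sens) || is.na(spec)) {
    NA_real_
  } else if (spec == 1) {
    if (sens > 0) Inf else NA_real_
  } else {
    sens / (1 - spec)
  }
  undefined <- c(
    if (tp + fn == 0) "sensitivity", if (tn + fp == 0) "specificity",
    if (tp + fp == 0) "ppv", if (tn + fn == 0) "npv"
  )
  tibble::new_tibble(tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(v),
    sensitivity = sens, specificity = spec,
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
    lr_pos = lr,
    undefined = paste(undefined, collapse = ";")
  ), class = "accuracy_result")
}

# per-row display conventions: percentages to the nearest integer, LR to one
# decimal; an empty test-negative (or test-positive) cell that misses no
# positives (negatives) is shown as 100% by convention
.render_row <- function(acc) {
  shown_npv <- if (is.na(acc$npv) && acc$fn == 0) 1 else acc$npv
  shown_ppv <- if (is.na(acc$ppv) && acc$fp == 0) 1 else acc$ppv
  dplyr::mutate(
    acc,
    s_pct = round(100 * .data$sensitivity),
    sp_pct = round(100 * .data$specificity),
    ppv_pct = round(100 * shown_ppv),
    npv_pct = round(100 * shown_npv),
    lr_1dp = round(.data$lr_pos, 1)
  )
}

.sweep_one <- function(values, positive, thresholds, direction, label) {
  purrr::map_dfr(thresholds, function(t) {
    acc <- .render_row(confusion_metrics(values, positive, t, direction))
    dplyr::bind_cols(
      tibble::tibble(block = label, threshold = t, direction = direction), acc
    )
  })
}

#' Threshold sweeps for cervical length and interval change
#'
#' `sweep_cl()` computes one accuracy row per CL threshold (predicate
#' `CL <= t`) at a screening timepoint; `sweep_delta()` one row per
#' %-shortening threshold (predicate `delta >= d`) for a screening interval,
#' using pre-cerclage measurements only. Each row's denominator is the set
#' of records with the required measurement(s) observed. Alongside the
#' unrounded metrics, display columns follow the reporting conventions:
#' percentages to the nearest integer, likelihood ratio to one decimal —
#' always computed from the unrounded sensitivity and specificity.
#'
#' @param cohort A cohort tibble; risk groups assigned if absent.
#' @param timepoint `"A"`, `"B"` or `"C"`.
#' @param interval `"A-B"`, `"B-C"` or `"A-C"`.
#' @param thresholds Thresholds to sweep; defaults are the reported sets
#'   (mm: 20, 25, 30, 35, 40, 50 at A/B and 20, 25, 30, 35, 37 at C;
#'   percent: 5, 10, 20, 30, 40).
#' @return A `cl_sweep` tibble, one row per threshold.
#' @export
sweep_cl <- function(cohort, timepoint = c("A", "B", "C"), thresholds = NULL) {
  timepoint <- match.arg(timepoint)
  if (is.null(thresholds)) {
    thresholds <- if (timepoint == "C") c(20, 25, 30, 35, 37)
                  else c(20, 25, 30, 35, 40, 50)
  }
  if (!"risk_group" %in% names(cohort)) cohort <- add_risk_group(cohort)
  cc <- censor_post_cerclage(cohort)
  values <- cc[[paste0("cl_", tolower(timepoint))]]
  out <- .sweep_one(values, cohort$risk_group == "GROUP2", thresholds, "le",
                    timepoint)
  tibble::new_tibble(out, class = "cl_sweep")
}

#' @rdname sweep_cl
#' @export
sweep_delta <- function(cohort, interval = c("A-B", "B-C", "A-C"),
                        thresholds = c(5, 10, 20, 30, 40)) {
  interval <- match.arg(interval)
  if (!"risk_group" %in% names(cohort)) cohort <- add_risk_group(cohort)
  cohort <- add_deltas(cohort)
  col <- paste0("delta_", tolower(gsub("-", "", interval)))
  out <- .sweep_one(cohort[[col]], cohort$risk_group == "GROUP2", thresholds,
                    "ge", interval)
  tibble::new_tibble(out, class = "cl_sweep")
}

#' ROC curve over all observed thresholds
#'
#' Constructs the receiver-operating-characteristic points of a measurement
#' against the GROUP2 outcome over every distinct observed value, plus the
#' two degenerate corner points, and the area under the curve by the
#' trapezoid rule. `direction = "le"` treats small values as test-positive
#' (the CL convention); `"ge"` the opposite (the %-change convention).
#'
#' @inheritParams confusion_metrics
#' @return A `cl_roc` tibble of `(threshold, fpr, tpr)` ordered by `fpr`,
#'   with the AUC in `attr(, "auc")`.
#' @export
roc_curve <- function(values, positive, direction = c("le", "ge")) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(positive)
  v <- values[keep]
  y <- positive[keep]
  if (!any(y) || all(y)) {
    stop("ROC needs at least one positive and one negative record",
         call. = FALSE)
  }
  thr <- sort(unique(v))
  pts <- purrr::map_dfr(thr, function(t) {
    acc <- confusion_metrics(v, y, t, direction)
    tibble::tibble(threshold = t, fpr = 1 - acc$specificity,
                   tpr = acc$sensitivity)
  })
  pts <- dplyr::bind_rows(
    tibble::tibble(threshold = NA_real_, fpr = 0, tpr = 0),
    pts,
    tibble::tibble(threshold = NA_real_, fpr = 1, tpr = 1)
  )
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  out <- tibble::new_tibble(pts, class = "cl_roc")
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @param roc A `cl_roc` object.
#' @export
auc <- function(roc) {
  attr(roc, "auc")
}
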