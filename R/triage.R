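#' Triage model specification
#'
#' The sequential screening triage model is a fixed set of thresholds applied
#' at up to three second-trimester visits (A: 13+0-15+6, B: 16+0-18+6,
#' C: 20+0-22+6 weeks). At each visit a woman is classified `HIGH_RISK`
#' (intervene and stop surveillance), `DISCHARGE` (safely stop surveillance)
#' or `CONTINUE` (rescan at the next visit). The defaults are the published
#' rule set:
#'
#' * **A**: high if CL < 19 mm; discharge if CL >= 42 mm.
#' * **B**: high if CL < 23 mm or shortening since A >= 21%;
#'   else discharge if CL >= 38 mm or shortening since A < 6%.
#' * **C** (terminal): high if (CL at A < 28 mm and shortening >= 5%) or
#'   CL at C <= 24 mm or (CL at A >= 24 mm and CL at B < 26 mm);
#'   else discharge.
#'
#' High rules are evaluated before discharge rules (safety-first: a record
#' satisfying both is called high). The interval for the step-C ">= 5%
#' shortening" clause defaults to A-C; the step-B discharge rule defaults to
#' the disjunction as published, with `b_low_rule = "and"` available as the
#' conservative conjunctive variant.
#'
#' @param a_high_lt,a_low_ge Step-A thresholds, mm.
#' @param b_high_cl_lt,b_high_delta_ge,b_low_cl_ge,b_low_delta_lt Step-B
#'   thresholds, mm and percent.
#' @param c_rule1_a_lt,c_rule1_delta_ge,c_rule2_c_le,c_rule3_a_ge,c_rule3_b_lt
#'   Step-C thresholds, mm and percent.
#' @param c_rule1_delta_interval Interval for the step-C shortening clause,
#'   `"A-C"` (default) or `"B-C"`.
#' @param b_low_rule `"or"` (published form) or `"and"`.
#' @return A `triage_model` object.
#' @examples
#' fig3 <- triage_model()
#' classify_timepoint_a(c(18, 42, 30), fig3)
#' @export
triage_model <- function(a_high_lt = 19, a_low_ge = 42,
                         b_high_cl_lt = 23, b_high_delta_ge = 21,
                         b_low_cl_ge = 38, b_low_delta_lt = 6,
                         c_rule1_a_lt = 28, c_rule1_delta_ge = 5,
                         c_rule2_c_le = 24, c_rule3_a_ge = 24,
                         c_rule3_b_lt = 26,
                         c_rule1_delta_interval = c("A-C", "B-C"),
                         b_low_rule = c("or", "and")) {
  c_rule1_delta_interval <- match.arg(c_rule1_delta_interval)
  b_low_rule <- match.arg(b_low_rule)
  mm <- c(a_high_lt, a_low_ge, b_high_cl_lt, b_low_cl_ge, c_rule1_a_lt,
          c_rule2_c_le, c_rule3_a_ge, c_rule3_b_lt)
  pct <- c(b_high_delta_ge, b_low_delta_lt, c_rule1_delta_ge)
  stopifnot(
    a_high_lt < a_low_ge, b_high_cl_lt < b_low_cl_ge,
    all(mm >= 5 & mm <= 60), all(pct >= 0 & pct <= 100)
  )
  structure(as.list(environment()), class = "triage_model")
}

#' @export
print.triage_model <- function(x, ...) {
  cat("<triage_model>\n")
  cat(sprintf("  A: high CL < %g mm | discharge CL >= %g mm\n",
              x$a_high_lt, x$a_low_ge))
  cat(sprintf("  B: high CL < %g mm or dCL(A-B) >= %g%% | discharge CL >= %g mm %s dCL(A-B) < %g%%\n",
              x$b_high_cl_lt, x$b_high_delta_ge, x$b_low_cl_ge,
              x$b_low_rule, x$b_low_delta_lt))
  cat(sprintf("  C: high (CL_A < %g mm & dCL(%s) >= %g%%) or CL_C <= %g mm or (CL_A >= %g mm & CL_B < %g mm) | else discharge\n",
              x$c_rule1_a_lt, x$c_rule1_delta_interval, x$c_rule1_delta_ge,
              x$c_rule2_c_le, x$c_rule3_a_ge, x$c_rule3_b_lt))
  if (!is.null(x$step3_tree)) cat("  (step C backed by a fitted partition tree)\n")
  invisible(x)
}

#' @rdname triage_model
#' @param x A `triage_model`; `...` unused.
#' @param ... Unused.
#' @method tidy triage_model
#' @export
tidy.triage_model <- function(x, ...) {
  keep <- c("a_high_lt", "a_low_ge", "b_high_cl_lt", "b_high_delta_ge",
            "b_low_cl_ge", "b_low_delta_lt", "c_rule1_a_lt",
            "c_rule1_delta_ge", "c_rule2_c_le", "c_rule3_a_ge", "c_rule3_b_lt")
  tibble::tibble(
    term = keep,
    step = c("A", "A", "B", "B", "B", "B", "C", "C", "C", "C", "C"),
    estimate = purrr::map_dbl(keep, ~ x[[.x]]),
    unit = ifelse(grepl("delta", keep), "percent", "mm")
  )
}

#' Per-visit triage decisions
#'
#' `classify_timepoint_a/b/c()` apply one step of a [triage_model()] to
#' vectors of cervical lengths. Missing measurements make the clauses that
#' need them inert: a missing CL at A leaves the step-B shortening clauses
#' unevaluable (CL-only clauses still apply), and a wholly missed visit
#' yields `CONTINUE`.
#'
#' @param cl_a,cl_b,cl_c Cervical lengths in mm (vectorised, `NA` = missing).
#' @param model A [triage_model()].
#' @return Character vector of `"HIGH_RISK"`, `"DISCHARGE"`, `"CONTINUE"`.
#' @export
classify_timepoint_a <- function(cl_a, model = triage_model()) {
  dplyr::case_when(
    is.na(cl_a) ~ "CONTINUE",
    cl_a < model$a_high_lt ~ "HIGH_RISK",
    cl_a >= model$a_low_ge ~ "DISCHARGE",
    TRUE ~ "CONTINUE"
  )
}

# clause helper: NA (unevaluable) counts as not satisfied
.holds <- function(x) !is.na(x) & x

#' @rdname classify_timepoint_a
#' @export
classify_timepoint_b <- function(cl_a, cl_b, model = triage_model()) {
  d_ab <- pct_delta_cl(cl_a, cl_b)
  high <- .holds(cl_b < model$b_high_cl_lt) |
    .holds(d_ab >= model$b_high_delta_ge)
  low_cl <- .holds(cl_b >= model$b_low_cl_ge)
  low_d <- .holds(d_ab < model$b_low_delta_lt)
  low <- if (model$b_low_rule == "or") low_cl | low_d else low_cl & low_d
  dplyr::case_when(
    is.na(cl_b) ~ "CONTINUE",
    high ~ "HIGH_RISK",
    low ~ "DISCHARGE",
    TRUE ~ "CONTINUE"
  )
}

#' @rdname classify_timepoint_a
#' @export
classify_timepoint_c <- function(cl_a, cl_b, cl_c, model = triage_model()) {
  d1 <- if (model$c_rule1_delta_interval == "A-C") {
    pct_delta_cl(cl_a, cl_c)
  } else {
    pct_delta_cl(cl_b, cl_c)
  }
  high <- (.holds(cl_a < model$c_rule1_a_lt) & .holds(d1 >= model$c_rule1_delta_ge)) |
    .holds(cl_c <= model$c_rule2_c_le) |
    (.holds(cl_a >= model$c_rule3_a_ge) & .holds(cl_b < model$c_rule3_b_lt))
  dplyr::case_when(
    is.na(cl_c) & !high ~ "CONTINUE",
    high ~ "HIGH_RISK",
    TRUE ~ "DISCHARGE"
  )
}

# Step-C decision via a fitted partition tree carried by a derived model.
.classify_c_tree <- function(cohort, model) {
  feats <- .derivation_features(cohort)
  disch <- .rpart_discharge(model$step3_tree, model$step3_p_cut, feats)
  dplyr::if_else(disch, "DISCHARGE", "HIGH_RISK")
}

#' Run the sequential triage model over a cohort
#'
#' Applies the step-A rule, then step B for records still `CONTINUE`, then
#' the terminal step C, recording the decision path, the exit visit and the
#' number of scans used (the index of the exit visit). Deterministic: a pure
#' function of the records and the model.
#'
#' @param cohort A cohort tibble; every record must have at least one CL
#'   measurement.
#' @param model A [triage_model()], possibly carrying a fitted step-C tree
#'   from [derive_triage_model()].
#' @return A tibble with one row per record: `id`, `decision_a`,
#'   `decision_b`, `decision_c` (`NA` after the exit visit),
#'   `exit_timepoint`, `final` (`HIGH_RISK`, `DISCHARGE`, or `COMPLETED`
#'   for records reaching C and discharged there), `scans_used`.
#' @export
run_triage <- function(cohort, model = triage_model()) {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      id = character(0), decision_a = character(0), decision_b = character(0),
      decision_c = character(0), exit_timepoint = character(0),
      final = character(0), scans_used = integer(0)
    ))
  }
  no_cl <- is.na(cohort$cl_a) & is.na(cohort$cl_b) & is.na(cohort$cl_c)
  if (any(no_cl)) {
    stop(sum(no_cl), " record(s) have no CL measurement at any timepoint; ",
         "apply_eligibility() first", call. = FALSE)
  }
  cohort <- censor_post_cerclage(cohort)

  dec_a <- classify_timepoint_a(cohort$cl_a, model)
  open_b <- dec_a == "CONTINUE"
  dec_b <- rep(NA_character_, nrow(cohort))
  dec_b[open_b] <- classify_timepoint_b(cohort$cl_a[open_b],
                                        cohort$cl_b[open_b], model)
  open_c <- open_b & dec_b == "CONTINUE"
  dec_c <- rep(NA_character_, nrow(cohort))
  if (any(open_c)) {
    sub <- cohort[open_c, , drop = FALSE]
    dec_c[open_c] <- if (!is.null(model$step3_const)) {
      model$step3_const
    } else if (!is.null(model$step3_tree)) {
      .classify_c_tree(sub, model)
    } else {
      classify_timepoint_c(sub$cl_a, sub$cl_b, sub$cl_c, model)
    }
    # C is terminal: a record still unresolved there completes surveillance
    dec_c[open_c][dec_c[open_c] == "CONTINUE"] <- "DISCHARGE"
  }

  exit_tp <- dplyr::case_when(!open_b ~ "A", !open_c ~ "B", TRUE ~ "C")
  final <- dplyr::case_when(
    exit_tp == "A" ~ dec_a,
    exit_tp == "B" ~ dec_b,
    dec_c == "HIGH_RISK" ~ "HIGH_RISK",
    TRUE ~ "COMPLETED"
  )
  tibble::tibble(
    id = cohort$id,
    decision_a = dec_a, decision_b = dec_b, decision_c = dec_c,
    exit_timepoint = exit_tp,
    final = final,
    scans_used = match(exit_tp, c("A", "B", "C"))
  )
}
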