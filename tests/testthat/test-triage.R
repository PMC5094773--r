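fig3 <- triage_model()

test_that("step-A thresholds split high / discharge / continue", {
  expect_identical(classify_timepoint_a(18, fig3), "HIGH_RISK")
  expect_identical(classify_timepoint_a(42, fig3), "DISCHARGE")
  expect_identical(classify_timepoint_a(30, fig3), "CONTINUE")
  expect_identical(classify_timepoint_a(NA, fig3), "CONTINUE")
})

test_that("step-B high rule wins over the discharge rule; delta clauses go inert without CL at A", {
  expect_identical(classify_timepoint_b(30, 22, fig3), "HIGH_RISK")       # CL < 23
  expect_identical(classify_timepoint_b(40, 30, fig3), "HIGH_RISK")       # 25% drop
  expect_identical(classify_timepoint_b(39, 38, fig3), "DISCHARGE")       # >= 38, drop 2.6%
  expect_identical(classify_timepoint_b(30, 29, fig3), "DISCHARGE")       # drop 3.3% < 6 (disjunctive rule)
  expect_identical(classify_timepoint_b(50, 39, fig3), "HIGH_RISK")       # both rules fire: safety first
  expect_identical(classify_timepoint_b(NA, 30, fig3), "CONTINUE")        # CL-only clauses both fail
  expect_identical(classify_timepoint_b(NA, 39, fig3), "DISCHARGE")       # CL-only discharge still applies
  expect_identical(classify_timepoint_b(30, NA, fig3), "CONTINUE")        # missed visit

  strict <- triage_model(b_low_rule = "and")
  expect_identical(classify_timepoint_b(30, 29, strict), "CONTINUE")
  expect_identical(classify_timepoint_b(39, 38, strict), "DISCHARGE")
})

test_that("step C fires on any of its three rules, else discharges", {
  expect_identical(classify_timepoint_c(27, 26, 25, fig3), "HIGH_RISK")   # short at A, 7.4% drop
  expect_identical(classify_timepoint_c(35, 34, 24, fig3), "HIGH_RISK")   # CL_C <= 24
  expect_identical(classify_timepoint_c(30, 25, 30, fig3), "HIGH_RISK")   # A >= 24 but B < 26
  expect_identical(classify_timepoint_c(35, 34, 33, fig3), "DISCHARGE")
  # the shortening interval is configurable
  bc <- triage_model(c_rule1_delta_interval = "B-C")
  expect_identical(classify_timepoint_c(27, 26, 26.5, bc), "DISCHARGE")   # B-C lengthened
  expect_identical(classify_timepoint_c(27, 30, 26, bc), "HIGH_RISK")     # B-C drop 13%
})

test_that("sequential application records exit point and scans used", {
  # note: a cervix stable at 30 mm is discharged at B by the disjunctive
  # rule (0% change < 6%); the third record shortens 10% so it continues
  co <- make_records(
    3,
    cl_a = c(42, 30, 30), cl_b = c(35, 22, 27), cl_c = c(35, 30, 26)
  )
  out <- run_triage(co, fig3)
  expect_equal(out$exit_timepoint, c("A", "B", "C"))
  expect_equal(out$final, c("DISCHARGE", "HIGH_RISK", "COMPLETED"))
  expect_equal(out$scans_used, c(1L, 2L, 3L))
  expect_true(all(is.na(out$decision_b[out$exit_timepoint == "A"])))
  expect_error(run_triage(make_records(1, cl_a = NA, cl_b = NA, cl_c = NA)),
               "no CL measurement")
})

test_that("triage is deterministic, exhaustive and safe on a large synthetic cohort", {
  subs <- default_subgroups()
  for (i in seq_along(subs)) subs[[i]]$n <- subs[[i]]$n * 14L  # ~10,150 records
  co <- add_risk_group(generate_cohort(cohort_config(subgroups = subs, seed = 31)))
  out1 <- run_triage(co, fig3)
  out2 <- run_triage(co, fig3)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), nrow(co))
  expect_true(all(out1$final %in% c("HIGH_RISK", "DISCHARGE", "COMPLETED")))
  expect_true(all(out1$scans_used == match(out1$exit_timepoint, c("A", "B", "C"))))
  # anyone with all three measurements >= 42 mm leaves at the first visit
  tall <- !is.na(co$cl_a) & co$cl_a >= 42
  expect_true(all(out1$exit_timepoint[tall] == "A" &
                    out1$final[tall] == "DISCHARGE"))
})
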