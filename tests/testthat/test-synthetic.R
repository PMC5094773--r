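test_that("truncated-normal sampler matches the numerical-integration moments", {
  set.seed(11)
  x <- rtnorm(50000, 25, 6, 5, 30)
  expect_true(all(x >= 5 & x <= 30))
  expect_equal(mean(x), tnorm_mean(25, 6, 5, 30), tolerance = 0.005)
  expect_error(rtnorm(10, 100, 2, 5, 60), "infeasible")
})

test_that("the generator is reproducible and honours subgroup contracts", {
  cfg <- cohort_config(seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  co <- add_risk_group(a)
  sizes <- table(co$subgroup)
  expect_equal(unname(sizes[c("term_no_cerclage", "ptb_no_cerclage",
                              "ptb_with_cerclage", "term_with_cerclage")]),
               c(581L, 46L, 24L, 74L), ignore_attr = TRUE)
  # preterm subgroups deliver before 37+0 by construction
  expect_true(all(is_preterm(co$ga_birth[grepl("^ptb", co$subgroup)])))
  expect_true(all(!is_preterm(co$ga_birth[!grepl("^ptb", co$subgroup)])))
  # every record keeps at least one screening measurement
  expect_false(any(is.na(co$cl_a) & is.na(co$cl_b) & is.na(co$cl_c)))
  # every cerclage recipient shows an observed pre-cerclage CL below 25 mm
  cer <- co[!is.na(co$cerclage_ga), ]
  expect_true(all(cer$cerclage_cl < 25))
  min_obs <- pmin(cer$cl_a, cer$cl_b, cer$cl_c, na.rm = TRUE)
  expect_true(all(min_obs < 25))
})

test_that("zero-size subgroups give an empty cohort", {
  subs <- default_subgroups()
  for (i in seq_along(subs)) subs[[i]]$n <- 0L
  co <- generate_cohort(cohort_config(subgroups = subs, seed = 1))
  expect_equal(nrow(co), 0)
})

test_that("large-sample calibration matches configured moments and missingness", {
  subs <- default_subgroups()
  subs$term_no_cerclage$n <- 10000L
  cfg <- cohort_config(
    subgroups = subs[c("term_no_cerclage", "ptb_no_cerclage")], seed = 21
  )
  co <- add_risk_group(generate_cohort(cfg))
  g1 <- co[co$subgroup == "term_no_cerclage", ]
  p <- subs$term_no_cerclage

  target <- tnorm_mean(p$mu_cl_a, p$sd_cl_a, 5, 60)
  expect_equal(mean(g1$cl_a, na.rm = TRUE), target, tolerance = 0.2 / target)

  d_ab <- pct_delta_cl(g1$cl_a, g1$cl_b)
  target_ab <- tnorm_mean(p$mu_pct_ab, p$sd_pct_ab, -50, 95)
  expect_lt(abs(mean(d_ab, na.rm = TRUE) - target_ab), 0.5)

  # realised missingness within 3 binomial SDs of the configured rates
  for (tp in c("a", "b", "c")) {
    pm <- p[[paste0("p_missing_", tp)]]
    frac <- mean(is.na(g1[[paste0("cl_", tp)]]))
    expect_lt(abs(frac - pm), 3 * sqrt(pm * (1 - pm) / nrow(g1)) + 1e-3)
  }
})

test_that("third-visit CL means order across subgroups as in the source cohort", {
  subs <- default_subgroups()
  for (i in seq_along(subs)) subs[[i]]$n <- subs[[i]]$n * 10L
  co <- add_risk_group(generate_cohort(cohort_config(subgroups = subs, seed = 5)))
  s <- summarize_cohort(co)
  m <- function(g) s$mean[s$group == g & s$measure == "cl_c"]
  expect_true(m("ptb_with_cerclage") < m("term_with_cerclage"))
  expect_true(m("term_with_cerclage") < m("ptb_no_cerclage"))
  expect_true(m("ptb_no_cerclage") < m("term_no_cerclage"))
})

test_that("cohort summaries reproduce the per-cell mean(SD)[n] layout", {
  rec <- add_risk_group(make_records(1, cl_a = 30, cl_b = 27, cl_c = NA_real_))
  s <- summarize_cohort(rec)
  cell <- s[s$group == "term_no_cerclage" & s$measure == "delta_ab", ]
  expect_equal(cell$mean, 10)
  expect_equal(cell$n, 1L)
  empty <- s[s$group == "ptb_with_cerclage" & s$measure == "cl_a", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})
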