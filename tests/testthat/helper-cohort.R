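# Builders for small hand-made cohorts. make_records() fills every cohort
# column with benign defaults so tests only state the fields they care about.

make_records <- function(n, ...) {
  out <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    hospital = rep_len(c("H1", "H2", "H3"), n),
    cl_a = rep(30, n), cl_b = rep(30, n), cl_c = rep(30, n),
    cerclage_cl = rep(NA_real_, n), cerclage_ga = rep(NA_integer_, n),
    suture = rep(NA_character_, n), declined_cerclage = rep(FALSE, n),
    ga_birth = rep(ga_days("39+0"), n),
    birthweight = rep(3300, n), apgar1 = rep(9L, n), apgar10 = rep(10L, n),
    nicu = rep(FALSE, n), age = rep(33, n), bmi = rep(24, n),
    parity = rep(0L, n), smoker = rep(FALSE, n),
    ethnicity = rep("caucasian", n), exclusion_flags = rep(NA_character_, n)
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# Two well-separated clusters with an empty CL gap between planted edges:
# GROUP2 below `lo_edge`, GROUP1 at/above `hi_edge`. CL identical at all
# three visits so steps B and C add nothing.
make_planted_cohort <- function(n, lo_edge = 20, hi_edge = 36,
                                p_group2 = 0.25, seed = 1) {
  set.seed(seed)
  g2 <- seq_len(n) <= round(p_group2 * n)
  cl <- ifelse(g2, runif(n, 8, lo_edge - 0.1), runif(n, hi_edge + 0.1, 50))
  make_records(
    n,
    hospital = sample(c("H1", "H2", "H3"), n, replace = TRUE),
    cl_a = cl, cl_b = cl, cl_c = cl,
    ga_birth = ifelse(g2, ga_days("34+0"), ga_days("39+0"))
  )
}

small_default_cohort <- function(seed = 101) {
  add_risk_group(generate_cohort(cohort_config(seed = seed)))
}
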