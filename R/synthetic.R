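#' Truncated-normal sampling by inverse CDF
#'
#' Draws from N(mu, sd) restricted to `[lo, hi]` by mapping uniforms through
#' the truncated quantile function, so the draw is a deterministic function
#' of the uniform stream.
#'
#' @param n Number of draws.
#' @param mu,sd Location and scale of the parent normal.
#' @param lo,hi Truncation bounds.
#' @return Numeric vector of length `n` inside `[lo, hi]`.
#' @export
rtnorm <- function(n, mu, sd, lo = -Inf, hi = Inf) {
  stopifnot(sd > 0, lo < hi)
  if (mu < lo - 6 * sd || mu > hi + 6 * sd) {
    stop("infeasible truncation: mean ", mu, " lies more than 6 sd outside [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sd)
}

#' Mean of a truncated normal by numerical integration
#'
#' Reference moment used to set calibration tolerances for the generator:
#' integrates `x f(x)` over the truncation interval rather than using the
#' closed form, so it is an independent check on the sampler.
#'
#' @inheritParams rtnorm
#' @return The mean of N(mu, sd) truncated to `[lo, hi]`.
#' @export
tnorm_mean <- function(mu, sd, lo = -Inf, hi = Inf) {
  mass <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mu, sd),
                   lower = lo, upper = hi,
                   rel.tol = 1e-10)$value / mass
}

#' Trajectory parameters for one outcome subgroup
#'
#' Bundles everything the generator needs for one outcome subgroup: size,
#' first-screening CL distribution, interval-shortening distributions,
#' per-timepoint missingness, and the gestation-at-birth distribution
#' (weeks; the range separates term from preterm subgroups by construction).
#'
#' @param name One of `term_no_cerclage`, `ptb_no_cerclage`,
#'   `ptb_with_cerclage`, `term_with_cerclage`.
#' @param n Subgroup size.
#' @param mu_cl_a,sd_cl_a First-screening CL distribution, mm.
#' @param mu_pct_ab,sd_pct_ab,mu_pct_bc,sd_pct_bc Interval shortening
#'   distributions, percent (positive = shortening).
#' @param p_missing_a,p_missing_b,p_missing_c Per-timepoint missed-visit
#'   probabilities.
#' @param ga_birth_mu,ga_birth_sd,ga_birth_range Gestation at birth, weeks.
#' @return A `subgroup_params` list.
#' @export
subgroup_params <- function(name, n, mu_cl_a, sd_cl_a,
                            mu_pct_ab, sd_pct_ab, mu_pct_bc, sd_pct_bc,
                            p_missing_a, p_missing_b, p_missing_c,
                            ga_birth_mu, ga_birth_sd, ga_birth_range) {
  stopifnot(
    name %in% c("term_no_cerclage", "ptb_no_cerclage",
                "ptb_with_cerclage", "term_with_cerclage"),
    n >= 0, sd_cl_a > 0, sd_pct_ab > 0, sd_pct_bc > 0, ga_birth_sd > 0,
    all(c(p_missing_a, p_missing_b, p_missing_c) >= 0),
    all(c(p_missing_a, p_missing_b, p_missing_c) <= 1),
    length(ga_birth_range) == 2, ga_birth_range[1] < ga_birth_range[2]
  )
  if (grepl("^ptb", name) && ga_birth_range[2] >= 37) {
    stop("preterm subgroup '", name, "' must have ga_birth_range capped below 37 weeks",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "subgroup_params")
}

#' Default subgroup parameters
#'
#' The four outcome subgroups with sizes, CL-at-A moments, interval
#' %-shortening moments and per-cell missingness matching the cohort this
#' package emulates (581 term births without cerclage, 46 preterm without,
#' 24 preterm with, 74 term with cerclage). Gestation at birth for the
#' cerclage subgroups uses the pooled suture-group distribution truncated at
#' 37 weeks; for preterm births without cerclage, a late-preterm-skewed
#' 34 +/- 2.5 week distribution.
#'
#' @return A named list of [subgroup_params()] objects.
#' @export
default_subgroups <- function() {
  list(
    term_no_cerclage = subgroup_params(
      "term_no_cerclage", n = 581, mu_cl_a = 33.6, sd_cl_a = 4.2,
      mu_pct_ab = 3, sd_pct_ab = 8, mu_pct_bc = 2, sd_pct_bc = 9,
      p_missing_a = 1 - 481 / 581, p_missing_b = 1 - 493 / 581,
      p_missing_c = 1 - 492 / 581,
      ga_birth_mu = 39.1, ga_birth_sd = 1.8, ga_birth_range = c(37, 42)
    ),
    ptb_no_cerclage = subgroup_params(
      "ptb_no_cerclage", n = 46, mu_cl_a = 32.3, sd_cl_a = 6.0,
      mu_pct_ab = 4, sd_pct_ab = 8, mu_pct_bc = 6, sd_pct_bc = 11,
      p_missing_a = 1 - 39 / 46, p_missing_b = 1 - 35 / 46,
      p_missing_c = 1 - 35 / 46,
      ga_birth_mu = 34.0, ga_birth_sd = 2.5, ga_birth_range = c(24, 36.85)
    ),
    ptb_with_cerclage = subgroup_params(
      "ptb_with_cerclage", n = 24, mu_cl_a = 26.8, sd_cl_a = 5.4,
      mu_pct_ab = 18, sd_pct_ab = 12, mu_pct_bc = 39, sd_pct_bc = 23,
      p_missing_a = 1 - 22 / 24, p_missing_b = 0.1, p_missing_c = 0.1,
      ga_birth_mu = 38.0, ga_birth_sd = 3.1, ga_birth_range = c(25, 36.85)
    ),
    term_with_cerclage = subgroup_params(
      "term_with_cerclage", n = 74, mu_cl_a = 25.8, sd_cl_a = 5.4,
      mu_pct_ab = 12, sd_pct_ab = 15, mu_pct_bc = 30, sd_pct_bc = 15,
      p_missing_a = 1 - 68 / 74, p_missing_b = 0.1, p_missing_c = 0.1,
      ga_birth_mu = 38.0, ga_birth_sd = 3.1, ga_birth_range = c(37, 42)
    )
  )
}

#' Synthetic cohort configuration
#'
#' @param subgroups Named list of [subgroup_params()]; defaults to
#'   [default_subgroups()].
#' @param hospital_weights Proportions for the three sites (must sum to 1).
#' @param suture_split Named counts `c(monofilament =, braided =)` giving
#'   the marginal split among cerclage recipients; used when
#'   `p_mono_by_outcome` is `NULL`.
#' @param p_mono_by_outcome Probability of monofilament suture given the
#'   delivery outcome, `c(ptb =, term =)`. The default encodes the observed
#'   suture-outcome association (9 of 24 preterm and 51 of 74 term cerclage
#'   deliveries had monofilament suture), so the synthetic suture 2x2
#'   reproduces the reported effect in expectation; set `NULL` for
#'   outcome-independent assignment by `suture_split`.
#' @param smoker_rate_g1,smoker_rate_g2 Smoking prevalence in the low- and
#'   high-risk groups.
#' @param cl_bounds Physiological CL bounds, mm.
#' @param cerclage_threshold CL below which a cerclage is inserted, mm.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(subgroups = default_subgroups(),
                          hospital_weights = c(QCH = 1, SMH = 1, CWH = 1) / 3,
                          suture_split = c(monofilament = 60, braided = 38),
                          p_mono_by_outcome = c(ptb = 9 / 24, term = 51 / 74),
                          smoker_rate_g1 = 0.07, smoker_rate_g2 = 0.23,
                          cl_bounds = c(5, 60), cerclage_threshold = 25,
                          seed = 1L) {
  stopifnot(
    abs(sum(hospital_weights) - 1) < 1e-8, length(hospital_weights) == 3,
    all(suture_split >= 0), sum(suture_split) > 0,
    length(cl_bounds) == 2, cl_bounds[1] < cl_bounds[2]
  )
  structure(as.list(environment()), class = "cohort_config")
}

# One subgroup's trajectories: truncated-normal CL at A, multiplicative
# shortening fractions for A->B and B->C, per-timepoint missingness.
.draw_trajectories <- function(p, bounds) {
  clip <- function(x) pmin(pmax(x, bounds[1]), bounds[2])
  cl_a <- rtnorm(p$n, p$mu_cl_a, p$sd_cl_a, bounds[1], bounds[2])
  f_ab <- rtnorm(p$n, p$mu_pct_ab, p$sd_pct_ab, -50, 95)
  f_bc <- rtnorm(p$n, p$mu_pct_bc, p$sd_pct_bc, -50, 95)
  cl_b <- clip(cl_a * (1 - f_ab / 100))
  cl_c <- clip(cl_b * (1 - f_bc / 100))
  obs <- function(x, pm, rows) {
    x[stats::runif(length(rows)) < pm] <- NA_real_
    x
  }
  out <- tibble::tibble(
    cl_a = obs(cl_a, p$p_missing_a, seq_len(p$n)),
    cl_b = obs(cl_b, p$p_missing_b, seq_len(p$n)),
    cl_c = obs(cl_c, p$p_missing_c, seq_len(p$n))
  )
  # inclusion criterion: at least one screening measurement per record;
  # redraw the missingness pattern for rows that lost all three
  repeat {
    gone <- which(is.na(out$cl_a) & is.na(out$cl_b) & is.na(out$cl_c))
    if (!length(gone)) break
    out$cl_a[gone] <- obs(cl_a[gone], p$p_missing_a, gone)
    out$cl_b[gone] <- obs(cl_b[gone], p$p_missing_b, gone)
    out$cl_c[gone] <- obs(cl_c[gone], p$p_missing_c, gone)
  }
  out
}

#' Generate a synthetic post-conization surveillance cohort
#'
#' Draws one pregnancy record per row with the longitudinal structure the
#' downstream analyses expect. Per subgroup: CL at the first screening from
#' a truncated normal; per-record interval shortening fractions from
#' truncated normals (applied multiplicatively, so the configured interval
#' %-change moments are the direct calibration targets); per-timepoint
#' missed visits; for cerclage subgroups an insertion at the first observed
#' visit with CL below the threshold (trajectories are redrawn until such a
#' visit exists), with suture material by the configured split and later CL
#' values censored; gestation at birth from the subgroup truncated normal —
#' so preterm subgroups deliver before 37+0 weeks by construction.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble (see [read_cohort()] for columns) with one row
#'   per pregnancy, reproducible given `config$seed`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  win <- .timepoint_windows()
  bounds <- config$cl_bounds
  thr <- config$cerclage_threshold

  rows <- purrr::imap(config$subgroups, function(p, name) {
    if (p$n == 0) return(NULL)
    traj <- .draw_trajectories(p, bounds)
    with_cerclage <- grepl("with_cerclage$", name)
    if (with_cerclage) {
      # protocol: every cerclage recipient must show an observed CL below
      # threshold at some visit; redraw trajectories until one exists
      for (iter in seq_len(1000)) {
        need <- which(purrr::pmap_lgl(traj, function(cl_a, cl_b, cl_c) {
          m <- suppressWarnings(min(c(cl_a, cl_b, cl_c), na.rm = TRUE))
          !is.finite(m) || m >= thr
        }))
        if (!length(need)) break
        sub <- p
        sub$n <- length(need)
        traj[need, ] <- .draw_trajectories(sub, bounds)
      }
      if (length(need)) {
        stop("could not realise CL < ", thr,
             " mm for all cerclage recipients in subgroup ", name,
             call. = FALSE)
      }
    }

    ga_lo <- ceiling(p$ga_birth_range[1] * 7)
    ga_hi <- floor(p$ga_birth_range[2] * 7)
    ga_birth <- pmin(pmax(round(rtnorm(
      p$n, p$ga_birth_mu * 7, p$ga_birth_sd * 7, ga_lo, ga_hi
    )), ga_lo), ga_hi)

    out <- dplyr::mutate(traj, subgroup = name, ga_birth = ga_birth,
                         cerclage_cl = NA_real_, cerclage_ga = NA_integer_,
                         suture = NA_character_)
    if (with_cerclage) {
      cl_mat <- as.matrix(out[, c("cl_a", "cl_b", "cl_c")])
      first_short <- apply(cl_mat, 1, function(x) {
        which(!is.na(x) & x < thr)[1]
      })
      out$cerclage_cl <- cl_mat[cbind(seq_len(p$n), first_short)]
      out$cerclage_ga <- win$start[first_short] +
        floor(stats::runif(p$n) * (win$end[first_short] - win$start[first_short] + 1))
      # post-insertion visits are censored: surveillance stops at cerclage
      for (tp in 1:3) {
        col <- paste0("cl_", tolower(win$timepoint[tp]))
        out[[col]][first_short < tp] <- NA_real_
      }
      p_mono <- if (is.null(config$p_mono_by_outcome)) {
        config$suture_split[["monofilament"]] / sum(config$suture_split)
      } else if (grepl("^ptb", name)) {
        config$p_mono_by_outcome[["ptb"]]
      } else {
        config$p_mono_by_outcome[["term"]]
      }
      out$suture <- ifelse(stats::runif(p$n) < p_mono,
                           "monofilament", "braided")
    }
    out
  })
  cohort <- dplyr::bind_rows(rows)
  n <- nrow(cohort)
  if (n == 0) {
    return(tibble::as_tibble(
      stats::setNames(rep(list(logical(0)), length(.cohort_cols)), .cohort_cols)
    ))
  }

  g2 <- cohort$subgroup != "term_no_cerclage"
  preterm_w <- cohort$ga_birth / 7
  cohort <- dplyr::mutate(
    cohort,
    id = sprintf("S%05d", seq_len(n)),
    hospital = sample(names(config$hospital_weights), n, replace = TRUE,
                      prob = config$hospital_weights),
    declined_cerclage = is.na(.data$cerclage_ga) &
      pmin(dplyr::coalesce(.data$cl_a, Inf), dplyr::coalesce(.data$cl_b, Inf),
           dplyr::coalesce(.data$cl_c, Inf)) < thr,
    birthweight = round(pmax(
      450, stats::rnorm(n, 3350 - 170 * pmax(40 - preterm_w, 0), 450)
    )),
    apgar1 = pmin(pmax(round(stats::rnorm(n, ifelse(g2, 8, 9), 1.5)), 0L), 10L),
    apgar10 = pmin(pmax(round(stats::rnorm(n, ifelse(g2, 9, 10), 1.0)), 0L), 10L),
    nicu = stats::runif(n) < ifelse(is_preterm(.data$ga_birth), 0.30, 0.013),
    age = round(rtnorm(n, 33.8, 4.1, 18, 50), 1),
    bmi = round(rtnorm(n, 24.1, 3.9, 17, 45), 1),
    parity = ifelse(stats::runif(n) < ifelse(g2, 0.86, 0.76), 0L,
                    1L + stats::rpois(n, 0.3)),
    smoker = stats::runif(n) <
      ifelse(g2, config$smoker_rate_g2, config$smoker_rate_g1),
    ethnicity = sample(c("caucasian", "asian", "black"), n, replace = TRUE,
                       prob = c(0.66, 0.16, 0.18)),
    exclusion_flags = NA_character_
  )
  cohort <- cohort[sample.int(n), c(.cohort_cols, "subgroup")]
  cohort$subgroup <- NULL
  cohort
}

#' Summarise a cohort in the per-subgroup longitudinal layout
#'
#' Per outcome subgroup (plus the high-risk aggregate and the total cohort),
#' reports mean (SD) [n] of cervical length at each screening timepoint and
#' of the interval percentage change, using pre-cerclage measurements only
#' and, for the deltas, records with both endpoints observed.
#'
#' @param cohort A cohort tibble; risk groups are assigned if absent.
#' @return A tibble with columns `group`, `measure` (`cl_a`...`delta_ac`),
#'   `mean`, `sd`, `n`. Empty cells have `n = 0` and `NA` moments.
#' @export
summarize_cohort <- function(cohort) {
  if (!"subgroup" %in% names(cohort)) cohort <- add_risk_group(cohort)
  cohort <- add_deltas(censor_post_cerclage(cohort))
  measures <- c("cl_a", "cl_b", "cl_c", "delta_ab", "delta_bc", "delta_ac")
  one <- function(df, label) {
    purrr::map_dfr(measures, function(m) {
      x <- df[[m]][!is.na(df[[m]])]
      tibble::tibble(
        group = label, measure = m,
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        n = length(x)
      )
    })
  }
  groups <- c("term_no_cerclage", "ptb_no_cerclage", "ptb_with_cerclage",
              "term_with_cerclage")
  dplyr::bind_rows(
    purrr::map_dfr(groups, function(g) {
      one(cohort[cohort$subgroup == g, , drop = FALSE], g)
    }),
    one(cohort[cohort$subgroup != "term_no_cerclage", , drop = FALSE], "GROUP2"),
    one(cohort, "total")
  )
}
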