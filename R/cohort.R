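#' Percentage change in cervical length between two screenings
#'
#' Computes `100 * (cl_early - cl_late) / cl_early`, the percentage change in
#' cervical length relative to the *earlier* measurement. Positive values
#' denote shortening, negative values lengthening (a 30 mm cervix measuring
#' 27 mm at the next visit has shortened by 10%).
#'
#' @param cl_early,cl_late Cervical lengths in mm at the earlier and later
#'   screening timepoint. Vectorised; `NA`s propagate.
#' @return Numeric vector of percentage changes.
#' @examples
#' pct_delta_cl(30, 27)
#' pct_delta_cl(20, 25) # lengthening is negative
#' @export
pct_delta_cl <- function(cl_early, cl_late) {
  if (any(!is.na(cl_early) & cl_early <= 0)) {
    stop("cl_early must be positive", call. = FALSE)
  }
  100 * (cl_early - cl_late) / cl_early
}

# Columns every cohort tibble carries, in file order. Gestational-age columns
# (cerclage_ga, ga_birth) are total days internally, "W+D" strings on disk.
.cohort_cols <- c(
  "id", "hospital", "cl_a", "cl_b", "cl_c", "cerclage_cl", "cerclage_ga",
  "suture", "declined_cerclage", "ga_birth", "birthweight", "apgar1",
  "apgar10", "nicu", "age", "bmi", "parity", "smoker", "ethnicity",
  "exclusion_flags"
)

.exclusion_flags <- c(
  "prior_preterm", "mid_trimester_loss", "uterine_anomaly", "multifetal",
  "history_indicated_cerclage"
)

#' Censor cervical-length measurements made after cerclage insertion
#'
#' Only measurements made before (or at the visit triggering) cerclage
#' insertion are analysable: a CL value at a screening timepoint whose window
#' opens after the recorded insertion gestation is replaced by `NA`. Records
#' without a cerclage are untouched.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @return The cohort with post-insertion `cl_a`/`cl_b`/`cl_c` set to `NA`.
#' @export
censor_post_cerclage <- function(cohort) {
  win <- .timepoint_windows()
  has <- !is.na(cohort$cerclage_ga)
  for (i in seq_len(nrow(win))) {
    col <- paste0("cl_", tolower(win$timepoint[i]))
    drop <- has & win$start[i] > cohort$cerclage_ga
    cohort[[col]][drop] <- NA_real_
  }
  cohort
}

#' Add interval percentage-change columns to a cohort
#'
#' Computes per-record `%ΔCL` for the A-B, B-C and A-C screening intervals
#' from pre-cerclage measurements only (post-insertion values are censored
#' first). A delta is defined only when both endpoint measurements are
#' observed.
#'
#' @param cohort A cohort tibble.
#' @return The cohort with `delta_ab`, `delta_bc`, `delta_ac` columns added.
#' @export
add_deltas <- function(cohort) {
  cc <- censor_post_cerclage(cohort)
  dplyr::mutate(
    cohort,
    delta_ab = pct_delta_cl(cc$cl_a, cc$cl_b),
    delta_bc = pct_delta_cl(cc$cl_b, cc$cl_c),
    delta_ac = pct_delta_cl(cc$cl_a, cc$cl_c)
  )
}

#' Assign outcome risk groups
#'
#' `assign_risk_group()` applies the outcome stratification: GROUP2
#' ("high-risk") is preterm birth (<37+0 weeks) and/or an
#' ultrasound-indicated cerclage; GROUP1 ("low-risk") is term birth with no
#' cerclage. `risk_subgroup()` splits GROUP2 into its three outcome columns.
#' `add_risk_group()` appends both as columns to a cohort tibble.
#'
#' Women who declined cerclage despite a short cervix are classified by what
#' happened: they are GROUP2 only if they delivered preterm (group membership
#' keys on cerclage *insertion*).
#'
#' @param ga_birth Gestational age at birth in total days.
#' @param has_cerclage Logical, cerclage inserted.
#' @param cohort A cohort tibble.
#' @return Character vectors (`"GROUP1"`/`"GROUP2"`; subgroup labels
#'   `term_no_cerclage`, `ptb_no_cerclage`, `ptb_with_cerclage`,
#'   `term_with_cerclage`), or the cohort with `risk_group` and `subgroup`
#'   columns.
#' @examples
#' assign_risk_group(ga_days("39+0"), FALSE)
#' risk_subgroup(ga_days("34+0"), FALSE)
#' @export
assign_risk_group <- function(ga_birth, has_cerclage) {
  if (any(is.na(ga_birth))) {
    stop("ga_birth is required to assign a risk group", call. = FALSE)
  }
  dplyr::if_else(is_preterm(ga_birth) | has_cerclage, "GROUP2", "GROUP1")
}

#' @rdname assign_risk_group
#' @export
risk_subgroup <- function(ga_birth, has_cerclage) {
  pt <- is_preterm(ga_birth)
  dplyr::case_when(
    pt & !has_cerclage ~ "ptb_no_cerclage",
    pt & has_cerclage ~ "ptb_with_cerclage",
    !pt & has_cerclage ~ "term_with_cerclage",
    TRUE ~ "term_no_cerclage"
  )
}

#' @rdname assign_risk_group
#' @export
add_risk_group <- function(cohort) {
  has <- !is.na(cohort$cerclage_ga) | !is.na(cohort$cerclage_cl)
  dplyr::mutate(
    cohort,
    risk_group = assign_risk_group(.data$ga_birth, has),
    subgroup = risk_subgroup(.data$ga_birth, has)
  )
}

#' Apply the study eligibility criteria
#'
#' Removes records carrying any exclusion flag (prior preterm birth,
#' mid-trimester loss, uterine anomaly, multifetal pregnancy,
#' history-indicated cerclage) and records with no cervical-length
#' measurement at any of the three screening timepoints.
#'
#' @param cohort A cohort tibble.
#' @return A list with `eligible` (cohort tibble) and `excluded` (the removed
#'   rows plus a `reason` column; the first matching reason is reported).
#' @export
apply_eligibility <- function(cohort) {
  flags <- cohort$exclusion_flags
  flags[is.na(flags)] <- ""
  flag_list <- strsplit(flags, ";", fixed = TRUE)
  first_flag <- purrr::map_chr(flag_list, function(f) {
    f <- f[f != ""]
    if (length(f)) f[1] else NA_character_
  })
  no_cl <- is.na(cohort$cl_a) & is.na(cohort$cl_b) & is.na(cohort$cl_c)
  reason <- dplyr::coalesce(first_flag, ifelse(no_cl, "no_screening", NA))
  list(
    eligible = cohort[is.na(reason), , drop = FALSE],
    excluded = dplyr::mutate(cohort[!is.na(reason), , drop = FALSE],
                             reason = reason[!is.na(reason)])
  )
}

#' Read and write cohort files
#'
#' The cohort file is comma-separated UTF-8 with one row per pregnancy and a
#' fixed header: `id, hospital, cl_a, cl_b, cl_c, cerclage_cl, cerclage_ga,
#' suture, declined_cerclage, ga_birth, birthweight, apgar1, apgar10, nicu,
#' age, bmi, parity, smoker, ethnicity, exclusion_flags`. Gestational ages
#' are `"W+D"` tokens, missing values empty fields, exclusion flags
#' semicolon-joined. Writing then reading reproduces every field.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a cohort tibble with gestational ages in
#'   total days; `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      hospital = readr::col_character(),
      cl_a = readr::col_double(),
      cl_b = readr::col_double(),
      cl_c = readr::col_double(),
      cerclage_cl = readr::col_double(),
      cerclage_ga = readr::col_character(),
      suture = readr::col_character(),
      declined_cerclage = readr::col_logical(),
      ga_birth = readr::col_character(),
      birthweight = readr::col_double(),
      apgar1 = readr::col_integer(),
      apgar10 = readr::col_integer(),
      nicu = readr::col_logical(),
      age = readr::col_double(),
      bmi = readr::col_double(),
      parity = readr::col_integer(),
      smoker = readr::col_logical(),
      ethnicity = readr::col_character(),
      exclusion_flags = readr::col_character()
    ),
    na = "",
    progress = FALSE,
    show_col_types = FALSE
  )
  missing_cols <- setdiff(.cohort_cols, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("cerclage_ga", "ga_birth")) {
    parsed <- tryCatch(ga_days(raw[[col]]), error = function(e) e)
    if (inherits(parsed, "error")) {
      bad <- which(!grepl("^\\s*[0-9]+\\+[0-6]\\s*$", raw[[col]]) &
                     !is.na(raw[[col]]))
      stop("column '", col, "', row(s) ", paste(bad, collapse = ", "), ": ",
           conditionMessage(parsed), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  raw[.cohort_cols]
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[.cohort_cols]
  out$cerclage_ga <- ga_format(out$cerclage_ga)
  out$ga_birth <- ga_format(out$ga_birth)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
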