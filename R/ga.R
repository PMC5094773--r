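#' Gestational-age arithmetic
#'
#' Gestational ages are written clinically as completed weeks plus days,
#' e.g. `"16+0"` or `"36+6"`. Internally the package works in total days
#' (`7 * weeks + days`), which is order-isomorphic to the `(weeks, days)`
#' pair. `ga_days()` parses the clinical notation, `ga_format()` renders it
#' back, and `is_preterm()` applies the standard `< 37+0` weeks (259 days)
#' definition of preterm birth.
#'
#' @param x For `ga_days()`, a character vector of `"W+D"` tokens (days must
#'   be 0-6). For `ga_format()` and `is_preterm()`, a numeric vector of
#'   gestational ages in total days.
#' @return `ga_days()`: integer days. `ga_format()`: character `"W+D"`.
#'   `is_preterm()`: logical, `TRUE` below 259 days.
#' @examples
#' ga_days("16+0")
#' ga_format(259)
#' is_preterm(ga_days(c("36+6", "37+0")))
#' @name gestational-age
NULL

#' @rdname gestational-age
#' @export
ga_days <- function(x) {
  if (length(x) == 0L) return(integer(0))
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & x != ""
  m <- regmatches(x[ok], regexec("^\\s*([0-9]+)\\+([0-9])\\s*$", x[ok]))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed gestational-age token(s): ",
         paste(unique(x[ok][bad]), collapse = ", "),
         " (expected \"W+D\" with D in 0-6)", call. = FALSE)
  }
  weeks <- vapply(m, function(g) as.integer(g[2]), 1L)
  days <- vapply(m, function(g) as.integer(g[3]), 1L)
  if (any(days > 6L)) {
    stop("gestational-age day component must be 0-6, got: ",
         paste(unique(x[ok][days > 6L]), collapse = ", "), call. = FALSE)
  }
  out[ok] <- 7L * weeks + days
  out
}

#' @rdname gestational-age
#' @export
ga_format <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  d <- as.integer(round(x[ok]))
  out[ok] <- paste0(d %/% 7L, "+", d %% 7L)
  out
}

#' @rdname gestational-age
#' @export
is_preterm <- function(x) {
  x < 259
}

# Screening timepoint windows in days: A 13+0-15+6, B 16+0-18+6, C 20+0-22+6.
.timepoint_windows <- function() {
  tibble::tibble(
    timepoint = c("A", "B", "C"),
    start = c(7L * 13L, 7L * 16L, 7L * 20L),
    end = c(7L * 15L + 6L, 7L * 18L + 6L, 7L * 22L + 6L)
  )
}
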