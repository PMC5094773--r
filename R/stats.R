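#' Build a 2x2 contingency table
#'
#' Rows are exposure groups, columns outcome / non-outcome:
#' `a` events and `b` non-events in the exposed row, `c` and `d` in the
#' reference row.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A 2x2 integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("all four cells must be non-negative counts", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table total must be positive", call. = FALSE)
  structure(matrix(as.integer(counts), 2, 2, byrow = TRUE),
            class = c("two_by_two", "matrix"))
}

#' Relative risk with Katz log-normal confidence interval
#'
#' The risk ratio between the two rows of a 2x2 table,
#' `rr = (a/(a+b)) / (c/(c+d))`, with the Katz interval
#' `exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. For a 95%
#' interval `z = 1.959964`. With a zero event cell the interval is
#' undefined unless `correct = TRUE` adds 0.5 to every cell (flagged in the
#' result).
#'
#' @param table A [two_by_two()] (or anything `two_by_two()` accepts via
#'   `relative_risk(a, b, c, d)`).
#' @param a,b,c,d Alternative direct cell counts.
#' @param conf_level Confidence level, default 0.95.
#' @param correct Apply the 0.5 continuity correction when an event cell is
#'   zero.
#' @return An `rr_result` list: `rr`, `ci_low`, `ci_high`, `conf_level`,
#'   `corrected`.
#' @examples
#' # term birth, braided vs monofilament suture
#' tidy(relative_risk(a = 23, b = 15, c = 51, d = 9))
#' @export
relative_risk <- function(table = NULL, a = NULL, b = NULL, c = NULL, d = NULL,
                          conf_level = 0.95, correct = FALSE) {
  if (is.null(table)) table <- two_by_two(a, b, c, d)
  stopifnot(inherits(table, "two_by_two"))
  x <- as.numeric(t(unclass(table)))  # a b c d
  if (x[1] + x[2] == 0 || x[3] + x[4] == 0) {
    stop("both row totals must be positive", call. = FALSE)
  }
  corrected <- FALSE
  rr <- (x[1] / (x[1] + x[2])) / (x[3] / (x[3] + x[4]))
  ci <- c(NA_real_, NA_real_)
  xx <- x
  if (x[1] == 0 || x[3] == 0) {
    if (correct) {
      xx <- x + 0.5
      corrected <- TRUE
    } else {
      xx <- NULL
    }
  }
  if (!is.null(xx)) {
    lrr <- log((xx[1] / (xx[1] + xx[2])) / (xx[3] / (xx[3] + xx[4])))
    se <- sqrt(1 / xx[1] - 1 / (xx[1] + xx[2]) + 1 / xx[3] - 1 / (xx[3] + xx[4]))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(lrr + c(-1, 1) * z * se)
    if (corrected) rr <- exp(lrr)
  }
  structure(list(rr = rr, ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, corrected = corrected,
                 table = table),
            class = "rr_result")
}

#' @rdname relative_risk
#' @param x An `rr_result`.
#' @param ... Unused.
#' @method tidy rr_result
#' @export
tidy.rr_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$rr, conf_low = x$ci_low, conf_high = x$ci_high,
    conf_level = x$conf_level, corrected = x$corrected
  )
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("RR %.2f, %d%% CI %.2f to %.2f%s\n", x$rr,
              round(100 * x$conf_level), x$ci_low, x$ci_high,
              if (x$corrected) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With the margins fixed, sums the hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table (the
#' "small-p" two-sided definition), accumulating in ascending order of
#' probability. A small relative tolerance admits tables tied with the
#' observed probability up to floating-point error.
#'
#' @inheritParams relative_risk
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(a = 9, b = 51, c = 15, d = 23)
#' @export
fisher_exact <- function(table = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(table)) table <- two_by_two(a, b, c, d)
  stopifnot(inherits(table, "two_by_two"))
  m <- unclass(table)
  if (sum(m) > 10000) {
    stop("enumeration bound exceeded: table total must be <= 10,000",
         call. = FALSE)
  }
  r1 <- sum(m[1, ])
  n <- sum(m)
  k1 <- sum(m[, 1])
  support <- max(0L, k1 - (n - r1)):min(r1, k1)
  probs <- stats::dhyper(support, r1, n - r1, k1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, k1)
  min(1, sum(sort(probs[probs <= p_obs * (1 + 1e-7)])))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank tie handling. For small
#' samples (both sides at most `exact_max`) the two-sided p-value comes
#' from exact enumeration of all group assignments (valid under ties);
#' otherwise from the tie-corrected normal approximation. The reported `u`
#' is `min(U_x, U_y)`; both one-sided statistics are returned too.
#'
#' @param x,y Numeric samples.
#' @param exact_max Per-side size bound for the exact branch (default 8).
#' @return A list: `u`, `u_x`, `u_y`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_y <- nx * ny - u_x
  dev_obs <- abs(u_x - nx * ny / 2)

  if (max(nx, ny) <= exact_max) {
    idx <- utils::combn(nx + ny, nx)
    dev <- apply(idx, 2, function(i) {
      abs(sum(r[i]) - nx * (nx + 1) / 2 - nx * ny / 2)
    })
    p <- mean(dev >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1
    } else {
      p <- 2 * stats::pnorm(-dev_obs / sqrt(sigma2))
    }
    method <- "normal approximation with tie correction"
  }
  list(u = min(u_x, u_y), u_x = u_x, u_y = u_y, p_value = min(p, 1),
       method = method)
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around the standard tie-corrected Kruskal-Wallis test,
#' returning the H statistic and the chi-square p-value with `k - 1`
#' degrees of freedom.
#'
#' @param groups A list of at least two non-empty numeric samples.
#' @return A list: `h`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (length(groups) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(unique(unlist(groups))) == 1) {
    # a single tied value carries no rank information: H = 0 by convention
    return(list(h = 0, df = length(groups) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Simple percentage rate
#'
#' `100 * numerator / denominator`, kept unrounded; `format_rate()` renders
#' it for display at a chosen number of decimals.
#'
#' @param numerator,denominator Counts; the denominator must be positive.
#' @param digits Decimals for display.
#' @return `rate_percent()`: numeric percent. `format_rate()`: character.
#' @examples
#' rate_percent(70, 725)
#' format_rate(rate_percent(70, 725), 1)
#' @export
rate_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  100 * numerator / denominator
}

#' @rdname rate_percent
#' @param rate A percentage from `rate_percent()`.
#' @export
format_rate <- function(rate, digits = 1) {
  paste0(formatC(round(rate, digits), format = "f", digits = digits), "%")
}

#' Suture-material comparison from a cohort
#'
#' Tabulates preterm birth by suture material among cerclage recipients and
#' returns the 2x2 table, the preterm-rate summary, the Katz relative risk
#' for term birth (braided vs monofilament — the direction whose interval
#' matches the published report) and the two-sided exact test on the
#' preterm table.
#'
#' @param cohort A cohort tibble.
#' @return A list: `table` (preterm x suture counts), `rates` tibble,
#'   `rr_term_braided_vs_mono`, `fisher_p`.
#' @export
suture_comparison <- function(cohort) {
  cer <- cohort[!is.na(cohort$suture), , drop = FALSE]
  if (!nrow(cer)) stop("no cerclage records with suture material", call. = FALSE)
  pt <- is_preterm(cer$ga_birth)
  mono <- cer$suture == "monofilament"
  tab <- two_by_two(sum(mono & pt), sum(mono & !pt),
                    sum(!mono & pt), sum(!mono & !pt))
  rr <- relative_risk(two_by_two(sum(!mono & !pt), sum(!mono & pt),
                                 sum(mono & !pt), sum(mono & pt)))
  list(
    table = tab,
    rates = tibble::tibble(
      suture = c("monofilament", "braided"),
      n = c(sum(mono), sum(!mono)),
      preterm = c(sum(mono & pt), sum(!mono & pt)),
      preterm_pct = rate_percent(c(sum(mono & pt), sum(!mono & pt)),
                                 c(sum(mono), sum(!mono)))
    ),
    rr_term_braided_vs_mono = rr,
    fisher_p = fisher_exact(tab)
  )
}
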