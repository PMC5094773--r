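#' Scan-utilisation accounting under a triage policy
#'
#' Given per-record triage outcomes, tabulates exits after one, two and
#' three scans and converts them to scans performed and scans avoided
#' against a schedule of `scheduled_per_woman` scans each (default three,
#' i.e. two scheduled follow-ups per woman). A woman exiting after scan
#' `k` avoids `scheduled_per_woman - k` scans; by default every exit —
#' discharge or high-risk (surveillance stops at cerclage) — counts.
#'
#' @param outcomes A tibble with a `scans_used` column (from
#'   [run_triage()]), or the accounting can be given directly through
#'   `exits`.
#' @param exits Alternative to `outcomes`: counts `c(n_exit_after_1,
#'   n_exit_after_2, n_complete_3)`.
#' @param scheduled_per_woman Scans scheduled per woman (default 3).
#' @return A one-row `scan_accounting` tibble: `n_total`,
#'   `scheduled_per_woman`, `n_exit_after_1`, `n_exit_after_2`,
#'   `n_complete_3`, `scans_performed`, `scans_avoided`,
#'   `scheduled_followups`, `pct_exit_after_1`, `pct_exit_after_2`,
#'   `pct_followups_avoided`.
#' @examples
#' scan_savings(exits = c(40, 156, 529))
#' @export
scan_savings <- function(outcomes = NULL, exits = NULL,
                         scheduled_per_woman = 3) {
  if (is.null(exits)) {
    if (any(outcomes$scans_used > scheduled_per_woman)) {
      stop("scans_used exceeds the scheduled number of scans", call. = FALSE)
    }
    exits <- vapply(seq_len(scheduled_per_woman), function(k) {
      sum(outcomes$scans_used == k)
    }, 1L)
  }
  stopifnot(length(exits) == scheduled_per_woman, all(exits >= 0))
  n_total <- sum(exits)
  performed <- sum(exits * seq_len(scheduled_per_woman))
  avoided <- n_total * scheduled_per_woman - performed
  followups <- n_total * (scheduled_per_woman - 1)
  tibble::new_tibble(tibble::tibble(
    n_total = n_total,
    scheduled_per_woman = scheduled_per_woman,
    n_exit_after_1 = exits[1],
    n_exit_after_2 = if (scheduled_per_woman >= 2) exits[2] else 0L,
    n_complete_3 = exits[scheduled_per_woman],
    scans_performed = performed,
    scans_avoided = avoided,
    scheduled_followups = followups,
    pct_exit_after_1 = rate_percent(exits[1], n_total),
    pct_exit_after_2 = if (scheduled_per_woman >= 2)
      rate_percent(exits[2], n_total) else 0,
    pct_followups_avoided = rate_percent(avoided, followups)
  ), class = "scan_accounting")
}
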