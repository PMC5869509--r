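# Clone GFP-trajectory summaries: stable/silenced calls and cohort
# fractions per vector group and timepoint.

#' Call a clone stable at a timepoint
#'
#' A clone is stably expressing at a timepoint when its %GFP+ is at or
#' above the threshold (inclusive: a clone at exactly 90% is stable).
#'
#' @param clones Clone data.frame with `dpi<N>` columns.
#' @param timepoint Integer dpi; the column `dpi<timepoint>` must exist.
#' @param threshold Stability threshold in percent (default 90).
#' @return Logical vector per clone (`NA` where the measurement is
#'   missing).
#' @examples
#' cl <- data.frame(clone_id = c("a", "b"), vector = "ASLV",
#'                  dpi60 = c(90, 89.9))
#' call_stable(cl, 60)
#' @export
call_stable <- function(clones, timepoint, threshold = 90) {
  col <- paste0("dpi", as.integer(timepoint))
  if (!col %in% names(clones)) {
    stop_bad("no measurement at ", timepoint, " dpi (missing column ", col,
             ")")
  }
  clones[[col]] >= threshold
}

#' Summarize clone stability per vector and timepoint
#'
#' Counts stably expressing clones (>= `threshold` %GFP+) per vector group
#' at each timepoint and reports both denominators: `"initial"` (all clones
#' with a measurement at that timepoint — the denominator of the cohort
#' percentages, where 100% is the number of clones obtained after
#' single-cell sorting) and, for timepoints after the first,
#' `"conditional"` (only clones that were stable at the first timepoint —
#' the survival-style question of how many stable clones stay stable).
#' Clones missing a timepoint's measurement are excluded from that
#' timepoint's denominator and reported in a message.
#'
#' @param clones Clone data.frame.
#' @param timepoints Integer dpi vector present in the table.
#' @param threshold Stability threshold in percent.
#' @return data.frame with `vector`, `timepoint`, `denominator`, `n_total`,
#'   `n_stable`, `fraction_stable`.
#' @export
summarize_stability <- function(clones, timepoints = c(30L, 60L),
                                threshold = 90) {
  if (nrow(clones) == 0L) stop_bad("empty clone cohort")
  timepoints <- sort(as.integer(timepoints))
  first_tp <- timepoints[1L]
  rows <- list()
  for (vec in unique(clones$vector)) {
    cv <- clones[clones$vector == vec, , drop = FALSE]
    base_stable <- call_stable(cv, first_tp, threshold)
    for (tp in timepoints) {
      st <- call_stable(cv, tp, threshold)
      n_missing <- sum(is.na(st))
      if (n_missing > 0L) {
        message(vec, " @", tp, " dpi: ", n_missing,
                " clone(s) without measurement excluded")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        vector = vec, timepoint = tp, denominator = "initial",
        n_total = sum(!is.na(st)), n_stable = sum(st, na.rm = TRUE),
        stringsAsFactors = FALSE)
      if (tp != first_tp) {
        keep <- !is.na(base_stable) & base_stable & !is.na(st)
        rows[[length(rows) + 1L]] <- data.frame(
          vector = vec, timepoint = tp, denominator = "conditional",
          n_total = sum(keep), n_stable = sum(st[keep]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fraction_stable <- ifelse(out$n_total > 0L,
                                out$n_stable / out$n_total, NA_real_)
  out
}
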