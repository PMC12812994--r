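# Assembling the full signal table and applying the four-algorithm
# signal criterion.

#' Default four-algorithm signal thresholds
#'
#' The conventional concordance criterion: at least 3 reports with the ROR
#' interval's lower bound above 1; PRR at least 2 with chi-square at least
#' 4; IC025 above 0; EB05 above 2. All thresholds are overridable because
#' different programmes tune them.
#'
#' @param min_reports,ror_low,prr,chi2,ic025,eb05 Threshold values.
#' @return A named list of thresholds.
#' @export
signal_criteria <- function(min_reports = 3, ror_low = 1, prr = 2,
                            chi2 = 4, ic025 = 0, eb05 = 2) {
  list(min_reports = min_reports, ror_low = ror_low, prr = prr,
       chi2 = chi2, ic025 = ic025, eb05 = eb05)
}

#' Apply the four-algorithm signal criterion
#'
#' A pair is a signal iff all four algorithms agree: `a >= min_reports` and
#' `ror_low > 1`; `prr >= 2` and `chi2 >= 4`; `ic025 > 0`; `eb05 > 2`
#' (defaults from [signal_criteria()]). Because the criterion is a
#' conjunction, the signal set is a subset of each single algorithm's set.
#'
#' @param stats A tibble carrying `a`, `ror_low`, `prr`, `chi2`, `ic025`,
#'   `eb05` columns (as built by [signal_stats()]).
#' @param criteria A [signal_criteria()] list.
#' @return The input with a logical `is_signal` column appended.
#' @export
evaluate_signal <- function(stats, criteria = signal_criteria()) {
  mutate(stats, is_signal =
           .data$a >= criteria$min_reports &
           .data$ror_low > criteria$ror_low &
           .data$prr >= criteria$prr &
           .data$chi2 >= criteria$chi2 &
           .data$ic025 > criteria$ic025 &
           .data$eb05 > criteria$eb05)
}

#' Compute all four disproportionality statistics for every drug-event pair
#'
#' Builds the fourfold table for each (drug, PT) pair of the requested drugs
#' against the full event universe, computes ROR (Woolf interval), PRR with
#' Yates chi-square, the shrinkage IC with IC025, fits the GPS prior over
#' all cells of the universe, scores EBGM/EB05, and applies the
#' four-algorithm criterion.
#'
#' @param records An [event_records()] universe (all drugs, all PTs).
#' @param drugs Drug labels to score (default: the tagged target drugs).
#' @param criteria A [signal_criteria()] list.
#' @param gps_universe Fit the GPS prior on every drug-event cell of the
#'   universe (`TRUE`, default) or only on the scored pairs.
#' @return A tibble, one row per (drug, pt): the counts `a..d`, `ror`,
#'   `ror_low`, `ror_high`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `eb05`,
#'   `is_signal`, plus `soc` for convenience.
#' @export
signal_stats <- function(records, drugs = NULL,
                         criteria = signal_criteria(),
                         gps_universe = TRUE) {
  if (is.null(drugs)) drugs <- sort(unique(records$drug[records$is_target]))
  if (length(drugs) == 0) abort("no target drugs to score")
  tabs <- contingency_tables(records, drugs)
  h <- gps_fit(if (gps_universe) contingency_tables(records, unique(records$drug))
               else tabs)
  soc_map <- distinct(records, .data$pt, .data$soc)
  tabs |>
    ror_stat() |>
    prr_chi2() |>
    bcpnn_ic() |>
    ebgm_stat(h = h) |>
    evaluate_signal(criteria = criteria) |>
    left_join(soc_map, by = "pt") |>
    relocate("soc", .after = "pt")
}

#' Rank signal statistics by frequency or signal strength
#'
#' Top-k drug-event pairs among those passing the signal criterion, ordered
#' by report count (`by = "frequency"`) or by ROR (`by = "ror"`); ties are
#' broken by the other key and then alphabetically by PT.
#'
#' @param stats A [signal_stats()] tibble.
#' @param by `"frequency"` or `"ror"`.
#' @param k Number of rows per drug.
#' @param signals_only Keep only pairs with `is_signal` (default `TRUE`).
#' @return The ranked tibble with a `rank` column, grouped within drug.
#' @export
rank_signals <- function(stats, by = c("frequency", "ror"), k = 10,
                         signals_only = TRUE) {
  by <- match.arg(by)
  if (k <= 0) abort("k must be a positive integer")
  out <- if (signals_only) filter(stats, .data$is_signal) else stats
  out <- if (by == "frequency") {
    arrange(out, .data$drug, desc(.data$a), desc(.data$ror), .data$pt)
  } else {
    arrange(out, .data$drug, desc(.data$ror), desc(.data$a), .data$pt)
  }
  out |>
    group_by(.data$drug) |>
    slice_head(n = k) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Bubble-plot coordinates for ranked signals
#'
#' Plot-ready table in the shape of a signal-strength bubble chart: x = PT
#' rank within drug, bubble size = report count, colour = ROR.
#'
#' @param ranked A [rank_signals()] tibble.
#' @return A tibble `drug, pt, rank, n, ror`.
#' @export
bubble_coords <- function(ranked) {
  transmute(ranked, drug = .data$drug, pt = .data$pt, rank = .data$rank,
            n = .data$a, ror = .data$ror)
}
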