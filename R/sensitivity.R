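# Sensitivity re-analysis: drop reports co-mentioning a named drug and
# compare the signal tables.

#' Exclude reports co-mentioning a drug
#'
#' Drops every report that carries a mention of `drug_name` (matched through
#' the lexicon normaliser) in a non-primary-suspect role — the concomitant
#' reading of "combined use". Set `any_role = TRUE` to also drop reports
#' where the named drug is itself a suspect. A pure filter: output is a
#' subset of input and the operation is idempotent.
#'
#' @param reports A deduplicated `faers_reports`.
#' @param drug_name Canonical label of the drug to exclude (e.g.
#'   `"thalidomide"`).
#' @param lexicon A [read_drug_lexicon()] tibble used to normalise names.
#' @param any_role Drop on any role, not just non-primary-suspect.
#' @return The filtered collection; the removed count is reported via a
#'   message.
#' @export
exclude_concomitant <- function(reports, drug_name,
                                lexicon = read_drug_lexicon(),
                                any_role = FALSE) {
  stopifnot(inherits(reports, "faers_reports"))
  hits <- reports$drugs |>
    mutate(label = match_lexicon(.data$verbatim_name, lexicon)) |>
    filter(!is.na(.data$label) & .data$label == drug_name)
  if (!any_role) hits <- filter(hits, .data$role != "PS")
  drop_pid <- unique(hits$primaryid)
  inform(sprintf("exclude_concomitant: removed %d report(s) co-mentioning %s",
                 length(drop_pid), drug_name))
  filter_reports(reports, setdiff(reports$demo$primaryid, drop_pid))
}

#' Compare a base and a filtered signal table
#'
#' Joins two [signal_stats()] runs on (drug, pt) and reports per pair the
#' report-count change, the ROR ratio and whether the signal flag agreed;
#' pairs present in only one run appear with NA markers. A summary of the
#' flag agreement is attached as the `"agreement"` attribute and reported
#' via a message.
#'
#' @param base,filtered Signal tables from [signal_stats()] on the same
#'   universe definition.
#' @return A tibble `drug, pt, a_base, a_filtered, delta_n, ror_base,
#'   ror_filtered, ror_ratio, signal_base, signal_filtered, flag_agrees`.
#' @export
compare_runs <- function(base, filtered) {
  merged <- full_join(
    select(base, "drug", "pt", a_base = "a", ror_base = "ror",
           signal_base = "is_signal"),
    select(filtered, "drug", "pt", a_filtered = "a", ror_filtered = "ror",
           signal_filtered = "is_signal"),
    by = c("drug", "pt")) |>
    mutate(delta_n = tidyr::replace_na(.data$a_filtered, 0L) -
             tidyr::replace_na(.data$a_base, 0L),
           ror_ratio = .data$ror_filtered / .data$ror_base,
           flag_agrees = tidyr::replace_na(.data$signal_base, FALSE) ==
             tidyr::replace_na(.data$signal_filtered, FALSE))
  pct <- round_half_up(100 * mean(merged$flag_agrees), 1)
  inform(sprintf("compare_runs: %.1f%% of signal flags unchanged across %d pairs",
                 pct, nrow(merged)))
  attr(merged, "agreement") <- pct
  merged
}
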