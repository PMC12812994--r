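# The report collection container and the case-level operations:
# deduplication, target-drug tagging, SOC mapping, baseline summary.

new_faers_reports <- function(demo, drugs, events, outcomes,
                              targets = NULL) {
  stopifnot(is.data.frame(demo), is.data.frame(drugs),
            is.data.frame(events), is.data.frame(outcomes))
  x <- list(demo = as_tibble(demo), drugs = as_tibble(drugs),
            events = as_tibble(events), outcomes = as_tibble(outcomes),
            targets = if (is.null(targets)) NULL else as_tibble(targets))
  class(x) <- "faers_reports"
  x
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>\n")
  cat(sprintf("  %d report versions, %d distinct cases\n",
              nrow(x$demo), dplyr::n_distinct(x$demo$case_id)))
  cat(sprintf("  %d drug mentions, %d event mentions, %d outcome entries\n",
              nrow(x$drugs), nrow(x$events), nrow(x$outcomes)))
  if (!is.null(x$targets)) {
    tc <- count(x$targets, .data$drug)
    cat("  tagged:", paste(sprintf("%s=%d", tc$drug, tc$n), collapse = ", "), "\n")
  }
  invisible(x)
}

# Restrict every member table to a set of primaryids, preserving order.
filter_reports <- function(x, keep_pid) {
  new_faers_reports(
    demo = filter(x$demo, .data$primaryid %in% keep_pid),
    drugs = filter(x$drugs, .data$primaryid %in% keep_pid),
    events = filter(x$events, .data$primaryid %in% keep_pid),
    outcomes = filter(x$outcomes, .data$primaryid %in% keep_pid),
    targets = if (is.null(x$targets)) NULL else
      filter(x$targets, .data$primaryid %in% keep_pid))
}

#' Deduplicate a report collection
#'
#' Spontaneous reporting systems carry multiple versions of the same case
#' (follow-up reports). Retains exactly one version per `case_id`: the one
#' with the latest receipt date, ties broken by the greatest `version_id` —
#' the convention recommended for FAERS case drill-down. Idempotent.
#'
#' @param reports A `faers_reports` collection.
#' @return A `faers_reports` with one version per case; the number of
#'   removed versions is reported via a message.
#' @export
dedup_reports <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  if (nrow(reports$demo) == 0) return(reports)
  keep <- reports$demo |>
    arrange(desc(.data$receipt_date), desc(.data$version_id)) |>
    distinct(.data$case_id, .keep_all = TRUE)
  removed <- nrow(reports$demo) - nrow(keep)
  if (removed > 0) {
    inform(sprintf("dedup_reports: removed %d duplicate version(s) of %d case(s)",
                   removed, sum(table(reports$demo$case_id) > 1)))
  }
  filter_reports(reports, keep$primaryid)
}

#' Tag reports whose primary suspect matches a target drug
#'
#' A report is tagged for a lexicon label iff it carries a drug mention with
#' role primary suspect (`"PS"`) whose normalised verbatim name equals one of
#' the label's synonyms (exact token match after case-folding and
#' punctuation-stripping — never substring). A report can carry at most one
#' tag per label; a report tagged for two target drugs contributes to both
#' and is reported via a message.
#'
#' @param reports A deduplicated `faers_reports`.
#' @param lexicon A [read_drug_lexicon()] tibble.
#' @param labels Optional subset of lexicon labels to tag (default: all).
#' @return The collection with a `targets` tibble (`primaryid`, `case_id`,
#'   `drug`) attached.
#' @export
tag_target_reports <- function(reports, lexicon = read_drug_lexicon(),
                               labels = NULL) {
  stopifnot(inherits(reports, "faers_reports"))
  if (nrow(lexicon) == 0) abort("empty drug lexicon")
  if (!is.null(labels)) lexicon <- filter(lexicon, .data$label %in% labels)
  ps <- filter(reports$drugs, .data$role == "PS")
  tags <- ps |>
    mutate(drug = match_lexicon(.data$verbatim_name, lexicon)) |>
    filter(!is.na(.data$drug)) |>
    distinct(.data$primaryid, .data$drug) |>
    left_join(select(reports$demo, "primaryid", "case_id"), by = "primaryid") |>
    select("primaryid", "case_id", "drug")
  multi <- tags |> count(.data$primaryid) |> filter(.data$n > 1)
  if (nrow(multi) > 0) {
    inform(sprintf("tag_target_reports: %d report(s) tagged for more than one target drug",
                   nrow(multi)))
  }
  reports$targets <- tags
  reports
}

#' Fill system organ classes from a PT mapping
#'
#' @param reports A `faers_reports`.
#' @param pt_to_soc A tibble with columns `pt`, `soc` (see [read_pt_soc()]).
#' @return The collection with `events$soc` filled; events whose PT is not in
#'   the mapping keep `soc = NA` and their count is reported via a message.
#' @export
map_soc <- function(reports, pt_to_soc = read_pt_soc()) {
  stopifnot(inherits(reports, "faers_reports"))
  if (nrow(pt_to_soc) == 0) abort("PT/SOC mapping must cover at least one PT")
  reports$events <- reports$events |>
    select(-"soc") |>
    left_join(pt_to_soc, by = "pt") |>
    relocate("soc", .after = "pt")
  n_miss <- sum(is.na(reports$events$soc))
  if (n_miss > 0) {
    inform(sprintf("map_soc: %d event mention(s) with PT outside the mapping left unmapped",
                   n_miss))
  }
  reports
}

#' Flatten a collection into analysis-ready drug-event records
#'
#' Produces the event universe disproportionality works on: one row per
#' distinct (case, drug, PT) combination, where `drug` is the tagged target
#' label when the report is tagged and the normalised primary-suspect name
#' otherwise. Counting at this report-PT pair level means a PT repeated
#' within a report is still counted once — each adverse event case counts
#' once per pair.
#'
#' @param reports A deduplicated, tagged (and usually SOC-mapped)
#'   `faers_reports`.
#' @return A tibble with columns `case_id`, `primaryid`, `drug`, `is_target`,
#'   `pt`, `soc`, `sex`, `age_years`, `event_date`, `therapy_start`
#'   (earliest start of that drug in the report).
#' @export
event_records <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  if (is.null(reports$targets)) {
    abort("run tag_target_reports() before event_records()")
  }
  # earliest non-missing therapy start per (report, drug): sort with NAs
  # last and keep the first row of each group
  ps <- reports$drugs |>
    filter(.data$role == "PS") |>
    mutate(verbatim = normalize_drug_name(.data$verbatim_name)) |>
    arrange(.data$primaryid, .data$verbatim, .data$therapy_start) |>
    distinct(.data$primaryid, .data$verbatim, .keep_all = TRUE) |>
    select("primaryid", "verbatim", "therapy_start")
  tagged <- reports$targets |> select("primaryid", "drug")
  tagged_pids <- unique(tagged$primaryid)
  ps <- ps |>
    left_join(mutate(tagged, is_target = TRUE),
              by = "primaryid", relationship = "many-to-many") |>
    mutate(is_target = !is.na(.data$is_target),
           drug = ifelse(is.na(.data$drug), .data$verbatim, .data$drug)) |>
    # tagged reports contribute under their tag(s) only
    filter(!(.data$primaryid %in% tagged_pids) | .data$is_target) |>
    distinct(.data$primaryid, .data$drug, .data$is_target, .data$therapy_start)
  ps |>
    inner_join(select(reports$events, "primaryid", "pt", "soc", "event_date"),
               by = "primaryid", relationship = "many-to-many") |>
    left_join(select(reports$demo, "primaryid", "case_id", "sex", "age_years"),
              by = "primaryid") |>
    distinct(.data$case_id, .data$drug, .data$pt, .keep_all = TRUE) |>
    select("case_id", "primaryid", "drug", "is_target", "pt", "soc",
           "sex", "age_years", "event_date", "therapy_start")
}

#' Restrict event records to one system organ class
#'
#' @param records An [event_records()] tibble with `soc` mapped.
#' @param soc_name SOC to keep, e.g. `"Nervous system disorders"`.
#' @return The subset of records in that SOC; an unknown SOC returns an
#'   empty tibble with a warning.
#' @export
restrict_to_soc <- function(records, soc_name) {
  out <- filter(records, !is.na(.data$soc) & .data$soc == soc_name)
  if (nrow(out) == 0) {
    warn(sprintf("restrict_to_soc: no records in SOC '%s'", soc_name))
  }
  out
}

#' Baseline descriptive table per target drug
#'
#' Per-drug counts and percentages for sex (including missing), age bands
#' (<18, 18-64.9, 65-85, >85, missing), reporter source, reporting country,
#' and outcome categories. Percentages use the drug's total report count as
#' denominator and are rounded half-up to one decimal, the convention of
#' clinical baseline tables. Outcome percentages need not sum to 100 because
#' a report may carry several outcomes.
#'
#' @param reports A deduplicated, tagged `faers_reports`.
#' @return A tibble with columns `drug`, `group`, `category`, `n`, `pct`.
#' @export
summarize_baseline <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  if (is.null(reports$targets)) abort("run tag_target_reports() first")
  demo <- inner_join(reports$targets, reports$demo,
                     by = c("primaryid", "case_id"))
  totals <- count(demo, .data$drug, name = "total")

  one_group <- function(tbl, group, var) {
    tbl |>
      count(.data$drug, category = .data[[var]]) |>
      mutate(group = group)
  }
  sex_tbl <- demo |>
    mutate(sex_cat = case_when(.data$sex == "F" ~ "Female",
                               .data$sex == "M" ~ "Male",
                               TRUE ~ "Missing")) |>
    one_group("sex", "sex_cat")
  age_tbl <- demo |>
    mutate(age_cat = case_when(is.na(.data$age_years) ~ "Missing",
                               .data$age_years < 18 ~ "<18",
                               .data$age_years < 65 ~ "18-64.9",
                               .data$age_years <= 85 ~ "65-85",
                               TRUE ~ ">85")) |>
    one_group("age", "age_cat")
  rep_tbl <- demo |>
    mutate(rep_cat = ifelse(is.na(.data$reporter), "Missing", .data$reporter)) |>
    one_group("reporter", "rep_cat")
  ctry_tbl <- demo |>
    mutate(ctry = ifelse(is.na(.data$country), "Missing", .data$country)) |>
    one_group("country", "ctry")
  out_tbl <- reports$targets |>
    inner_join(reports$outcomes, by = "primaryid",
               relationship = "many-to-many") |>
    distinct(.data$case_id, .data$drug, .data$outcome) |>
    count(.data$drug, category = .data$outcome) |>
    mutate(group = "outcome")

  bind_rows(sex_tbl, age_tbl, rep_tbl, ctry_tbl, out_tbl) |>
    left_join(totals, by = "drug") |>
    mutate(pct = round_half_up(100 * .data$n / .data$total, 1)) |>
    select("drug", "group", "category", "n", "pct") |>
    arrange(.data$drug, .data$group, desc(.data$n))
}
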