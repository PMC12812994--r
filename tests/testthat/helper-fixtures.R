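# Shared fixtures, built in code.

# Hand-built three-case collection exercising versions, roles, partial
# dates and outcomes.
tiny_reports <- function() {
  demo <- tibble::tibble(
    primaryid = c("C1-1", "C1-2", "C2-1", "C3-1"),
    case_id = c("C1", "C1", "C2", "C3"),
    version_id = c(1L, 2L, 1L, 1L),
    receipt_date = as.Date(c("2020-01-01", "2020-06-01", "2021-03-01",
                             "2021-04-01")),
    sex = c("F", "F", "M", NA),
    age_years = c(64, 64, 71, NA),
    country = c("US", "US", "JP", "FR"),
    reporter = c("physician", "physician", "consumer", NA))
  drugs <- tibble::tibble(
    primaryid = c("C1-1", "C1-2", "C1-2", "C2-1", "C3-1"),
    drug_seq = c(1L, 1L, 2L, 1L, 1L),
    verbatim_name = c("VELCADE", "VELCADE", "THALOMID", "bortezomib",
                      "KYPROLIS"),
    role = c("PS", "PS", "C", "C", "PS"),
    therapy_start = as.Date(c("2020-01-01", "2020-01-01", NA,
                              "2021-01-01", "2021-02-01")))
  events <- tibble::tibble(
    primaryid = c("C1-1", "C1-2", "C1-2", "C2-1", "C3-1"),
    pt = c("Neuropathy peripheral", "Neuropathy peripheral",
           "Nausea", "Fatigue", "Hypertensive encephalopathy"),
    soc = NA_character_,
    event_date = as.Date(c("2020-02-03", "2020-02-03", NA, "2021-02-15",
                           "2021-03-10")))
  outcomes <- tibble::tibble(
    primaryid = c("C1-2", "C2-1", "C3-1"),
    outcome = c("hospitalization", "other", "death"))
  faersignal:::new_faers_reports(demo, drugs, events, outcomes)
}

# One moderately sized simulated universe shared across test files.
.shared <- new.env(parent = emptyenv())
shared_universe <- function() {
  if (is.null(.shared$records)) {
    sim <- synth_generate(synth_config(n_cases = 5000, seed = 42))
    reports <- suppressMessages(
      map_soc(tag_target_reports(dedup_reports(sim$reports))))
    .shared$sim <- sim
    .shared$reports <- reports
    .shared$records <- event_records(reports)
  }
  list(sim = .shared$sim, reports = .shared$reports,
       records = .shared$records)
}

# Random strictly positive 2x2 tables for property checks.
random_tables <- function(n, seed, min_cell = 1) {
  set.seed(seed)
  tibble::tibble(
    a = min_cell + stats::rpois(n, 10),
    b = min_cell + stats::rpois(n, 150),
    c = min_cell + stats::rpois(n, 80),
    d = min_cell + stats::rpois(n, 5000))
}
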