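# Reading and writing FAERS-style multi-table bundles.
#
# The "faers-ascii" dialect mirrors the quarterly FAERS extract layout:
# one "$"-delimited text file per table with a header row (DEMO, DRUG, THER,
# REAC, OUTC). A CSV dialect with identical columns is accepted as well.
# Dates travel as YYYYMMDD strings; partial-precision dates (YYYY or YYYYMM)
# are read as missing rather than fabricated.

bundle_tables <- c("DEMO", "DRUG", "THER", "REAC", "OUTC")

bundle_delim <- function(dialect) {
  switch(dialect,
         "faers-ascii" = "$",
         "csv" = ",",
         abort(sprintf("unknown dialect '%s' (use 'faers-ascii' or 'csv')",
                       dialect)))
}

bundle_ext <- function(dialect) if (dialect == "csv") ".csv" else ".txt"

outcome_codes <- c(death = "DE", disability = "DS", hospitalization = "HO",
                   `life-threatening` = "LT", other = "OT")
reporter_codes <- c(physician = "MD", pharmacist = "PH",
                    `health-professional` = "OT", consumer = "CN")

#' Write a report collection as a FAERS-style bundle
#'
#' The inverse of [read_faers_bundle()] up to field equality. Writes five
#' tables (DEMO, DRUG, THER, REAC, OUTC) in the chosen dialect; an empty
#' collection yields valid header-only files.
#'
#' @param reports A `faers_reports` collection.
#' @param dir Output directory (created if needed).
#' @param dialect `"faers-ascii"` ("$"-delimited) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(reports, dir, dialect = "faers-ascii") {
  stopifnot(inherits(reports, "faers_reports"))
  delim <- bundle_delim(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- reports$demo |>
    transmute(primaryid = .data$primaryid, caseid = .data$case_id,
              caseversion = .data$version_id,
              fda_dt = format_faers_date(.data$receipt_date),
              sex = ifelse(is.na(.data$sex), "", .data$sex),
              age = ifelse(is.na(.data$age_years), "", .data$age_years),
              reporter_country = ifelse(is.na(.data$country), "", .data$country),
              occp_cod = ifelse(is.na(.data$reporter), "",
                                unname(reporter_codes[.data$reporter])))
  drug <- reports$drugs |>
    transmute(primaryid = .data$primaryid, drug_seq = .data$drug_seq,
              drugname = .data$verbatim_name, role_cod = .data$role)
  ther <- reports$drugs |>
    filter(!is.na(.data$therapy_start)) |>
    transmute(primaryid = .data$primaryid, drug_seq = .data$drug_seq,
              start_dt = format_faers_date(.data$therapy_start))
  reac <- reports$events |>
    transmute(primaryid = .data$primaryid, pt = .data$pt,
              event_dt = format_faers_date(.data$event_date))
  outc <- reports$outcomes |>
    transmute(primaryid = .data$primaryid,
              outc_cod = unname(outcome_codes[.data$outcome]))
  tbls <- list(DEMO = demo, DRUG = drug, THER = ther, REAC = reac, OUTC = outc)
  for (nm in names(tbls)) {
    readr::write_delim(tbls[[nm]],
                       file.path(dir, paste0(nm, bundle_ext(dialect))),
                       delim = delim, na = "", progress = FALSE)
  }
  invisible(dir)
}

read_bundle_table <- function(dir, name, dialect, required_cols) {
  path <- file.path(dir, paste0(name, bundle_ext(dialect)))
  if (!file.exists(path)) abort(sprintf("bundle table missing: %s", path))
  tbl <- readr::read_delim(path, delim = bundle_delim(dialect),
                           col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  missing <- setdiff(required_cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("table %s is missing mandatory column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) {
    warn(sprintf("bundle table %s is empty", name))
  }
  tbl
}

#' Read a FAERS-style bundle into a report collection
#'
#' Expects the five tables written by [write_faers_bundle()] (DEMO, DRUG,
#' THER, REAC, OUTC). One report version is formed per DEMO row, i.e. per
#' (caseid, caseversion); drug, event and outcome rows attach via
#' `primaryid`. Dates that are not full-precision YYYYMMDD become missing.
#' Per-table row counts are reported via a message.
#'
#' @param dir Directory holding the bundle.
#' @param dialect `"faers-ascii"` or `"csv"`.
#' @return A `faers_reports` collection (untagged, SOC unmapped).
#' @export
read_faers_bundle <- function(dir, dialect = "faers-ascii") {
  demo_raw <- read_bundle_table(dir, "DEMO", dialect,
                                c("primaryid", "caseid", "caseversion", "fda_dt"))
  drug_raw <- read_bundle_table(dir, "DRUG", dialect,
                                c("primaryid", "drug_seq", "drugname", "role_cod"))
  ther_raw <- read_bundle_table(dir, "THER", dialect,
                                c("primaryid", "drug_seq", "start_dt"))
  reac_raw <- read_bundle_table(dir, "REAC", dialect, c("primaryid", "pt"))
  outc_raw <- read_bundle_table(dir, "OUTC", dialect, c("primaryid", "outc_cod"))
  inform(sprintf("read_faers_bundle: DEMO %d, DRUG %d, THER %d, REAC %d, OUTC %d rows",
                 nrow(demo_raw), nrow(drug_raw), nrow(ther_raw),
                 nrow(reac_raw), nrow(outc_raw)))

  rev_reporter <- setNames(names(reporter_codes), unname(reporter_codes))
  demo <- demo_raw |>
    transmute(primaryid = .data$primaryid, case_id = .data$caseid,
              version_id = as.integer(.data$caseversion),
              receipt_date = parse_faers_date(.data$fda_dt),
              sex = ifelse(.data$sex %in% c("F", "M"), .data$sex, NA_character_),
              age_years = suppressWarnings(as.numeric(.data$age)),
              country = .data$reporter_country,
              reporter = unname(rev_reporter[.data$occp_cod]))
  ther <- ther_raw |>
    mutate(drug_seq = as.integer(.data$drug_seq),
           therapy_start = parse_faers_date(.data$start_dt)) |>
    select("primaryid", "drug_seq", "therapy_start")
  drugs <- drug_raw |>
    mutate(drug_seq = as.integer(.data$drug_seq)) |>
    left_join(ther, by = c("primaryid", "drug_seq")) |>
    transmute(primaryid = .data$primaryid, drug_seq = .data$drug_seq,
              verbatim_name = .data$drugname, role = .data$role_cod,
              therapy_start = .data$therapy_start)
  if (!"event_dt" %in% names(reac_raw)) reac_raw$event_dt <- NA_character_
  events <- reac_raw |>
    transmute(primaryid = .data$primaryid, pt = .data$pt, soc = NA_character_,
              event_date = parse_faers_date(.data$event_dt))
  rev_outcome <- setNames(names(outcome_codes), unname(outcome_codes))
  outcomes <- outc_raw |>
    transmute(primaryid = .data$primaryid,
              outcome = unname(rev_outcome[.data$outc_cod])) |>
    filter(!is.na(.data$outcome)) |>
    distinct()
  new_faers_reports(demo, drugs, events, outcomes)
}
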