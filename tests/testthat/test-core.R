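# Case-level operations: deduplication, tagging, SOC mapping, baseline.

test_that("deduplication keeps the latest receipt date, breaking ties on version, and is idempotent", {
  r <- tiny_reports()
  once <- suppressMessages(dedup_reports(r))
  expect_setequal(once$demo$primaryid, c("C1-2", "C2-1", "C3-1"))
  twice <- suppressMessages(dedup_reports(once))
  expect_identical(once, twice)

  # tie on receipt date -> greatest version wins
  tie <- r
  tie$demo$receipt_date[tie$demo$case_id == "C1"] <- as.Date("2020-01-01")
  kept <- suppressMessages(dedup_reports(tie))
  expect_true("C1-2" %in% kept$demo$primaryid)

  # all-distinct case ids -> identity
  distinct_r <- faersignal:::filter_reports(r, c("C2-1", "C3-1"))
  expect_identical(suppressMessages(dedup_reports(distinct_r)), distinct_r)
})

test_that("duplicate versions planted by the generator are all removed", {
  sim <- synth_generate(synth_config(n_cases = 1500, duplicate_rate = 0.2,
                                     seed = 11))
  expect_identical(nrow(sim$reports$demo),
                   1500L + sim$truth$n_duplicates)
  dd <- suppressMessages(dedup_reports(sim$reports))
  expect_identical(nrow(dd$demo), 1500L)
  expect_false(any(duplicated(dd$demo$case_id)))
  # the later (higher-version) record is the one retained
  expect_true(all(dd$demo$version_id[dd$demo$case_id %in%
    dd$demo$case_id[dd$demo$version_id == 2L]] == 2L))
})

test_that("primary-suspect tagging matches synonyms case-insensitively after punctuation stripping, and respects roles", {
  r <- suppressMessages(dedup_reports(tiny_reports()))
  r$drugs$verbatim_name[r$drugs$primaryid == "C1-2" &
                          r$drugs$drug_seq == 1L] <- "velcade."
  tagged <- tag_target_reports(r)
  tags <- tagged$targets
  expect_identical(tags$drug[tags$case_id == "C1"], "bortezomib")
  expect_identical(tags$drug[tags$case_id == "C3"], "carfilzomib")
  # concomitant bortezomib mention in C2 must not tag
  expect_false("C2" %in% tags$case_id)
  expect_error(tag_target_reports(r, lexicon = tibble::tibble()),
               "empty")
})

test_that("tagging commutes with deduplication on generated data", {
  sim <- synth_generate(synth_config(n_cases = 1000, seed = 5))
  a <- suppressMessages(tag_target_reports(dedup_reports(sim$reports)))
  b <- suppressMessages(dedup_reports(tag_target_reports(sim$reports)))
  expect_identical(
    dplyr::arrange(a$targets, primaryid, drug),
    dplyr::arrange(b$targets, primaryid, drug))
})

test_that("SOC mapping fills known PTs, leaves unknown PTs absent, and covers the generator vocabulary", {
  r <- tiny_reports()
  r$events$pt[4] <- "Not a real PT"
  mapped <- suppressMessages(map_soc(r))
  expect_identical(
    mapped$events$soc[mapped$events$pt == "Neuropathy peripheral"][1],
    "Nervous system disorders")
  expect_true(is.na(mapped$events$soc[mapped$events$pt == "Not a real PT"]))

  u <- shared_universe()
  expect_false(anyNA(u$reports$events$soc))
})

test_that("restricting to a SOC keeps exactly that SOC's event records", {
  u <- shared_universe()
  nerv <- restrict_to_soc(u$records, "Nervous system disorders")
  expect_true(all(nerv$soc == "Nervous system disorders"))
  expect_identical(restrict_to_soc(nerv, "Nervous system disorders"), nerv)
  expect_warning(out <- restrict_to_soc(u$records, "No such SOC"), "no records")
  expect_identical(nrow(out), 0L)
})

test_that("baseline summary computes half-up percentages against the drug total and partitions sum to 100", {
  u <- shared_universe()
  base <- summarize_baseline(u$reports)
  totals <- dplyr::count(u$reports$targets, drug)
  for (g in c("sex", "age", "reporter")) {
    sums <- base |>
      dplyr::filter(group == g) |>
      dplyr::group_by(drug) |>
      dplyr::summarise(p = sum(pct), n = sum(n))
    expect_true(all(abs(sums$p - 100) <= 0.2), info = g)
    expect_identical(sums$n, totals$n[match(sums$drug, totals$drug)])
  }
  # spot-check the arithmetic
  one <- base |> dplyr::filter(drug == "ixazomib", group == "sex",
                               category == "Female")
  tot <- totals$n[totals$drug == "ixazomib"]
  expect_equal(one$pct, round_half_up(100 * one$n / tot, 1))
})

test_that("event records count once per (case, drug, PT) and split pairs by target tagging", {
  r <- suppressMessages(dedup_reports(tiny_reports()))
  # duplicate PT within one report must still count once
  r$events <- dplyr::bind_rows(r$events, r$events[1, ])
  rec <- event_records(suppressMessages(map_soc(tag_target_reports(r))))
  expect_identical(sum(rec$drug == "bortezomib" &
                         rec$pt == "Neuropathy peripheral"), 1L)
  expect_false(any(duplicated(rec[, c("case_id", "drug", "pt")])))
  # untagged report contributes under its normalised verbatim PS name
  expect_true(all(rec$is_target | rec$drug ==
                    normalize_drug_name(rec$drug)))
})
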