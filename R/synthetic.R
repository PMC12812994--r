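# Synthetic spontaneous-report generator with planted ground truth.
#
# The generator emulates the statistical skeleton of a spontaneous reporting
# system: each case carries one primary-suspect drug, a handful of PT-coded
# events drawn from a background multinomial that planted signals tilt, a
# Weibull-distributed therapy-start-to-event latency, demographic fields with
# realistic missingness, and (for a configurable fraction of cases) an extra
# earlier-dated duplicate version. Everything is driven by one seed so a
# config + seed pair reproduces the bundle bit-exactly.

#' Build a synthetic-report generator configuration
#'
#' The defaults describe the study conditions the package validates itself
#' under: three target proteasome inhibitors against a 10-drug background
#' universe, 40 preferred terms (20 in "Nervous system disorders"), one
#' strongly planted drug-event association, one planted male-biased effect,
#' per-drug Weibull onset laws, 5% duplicated cases and 10% thalidomide
#' co-mentions on bortezomib reports.
#'
#' @param n_cases Number of distinct cases (before duplication).
#' @param background_drugs Number of background (non-target) drugs.
#' @param background_pts Number of preferred terms in the event vocabulary;
#'   must not exceed the shipped PT/SOC mapping (40).
#' @param target_shares Named numeric vector: probability that a case's
#'   primary suspect is each target drug. The remainder is spread uniformly
#'   over the background drugs.
#' @param planted_signals Tibble/data frame with columns `drug`, `pt`,
#'   `rrr` (relative reporting ratio, the multiplicative tilt applied to the
#'   PT's event weight for cases on that drug). `NULL` for a global null.
#' @param sex_effects Tibble/data frame with columns `drug`, `pt`,
#'   `male_multiplier` (extra tilt applied for male cases on that drug).
#' @param tto_laws Tibble/data frame with columns `drug`, `shape`, `scale`:
#'   Weibull onset-time law (days) per drug. Drugs without a law use
#'   shape 1, scale 90.
#' @param duplicate_rate Fraction of cases in `[0, 1)` that receive an extra
#'   earlier-dated version (same case id, lower version id).
#' @param concomitant_drug,concomitant_rate A named concomitant co-mention
#'   (role "C") added to this fraction of bortezomib cases; used by the
#'   sensitivity-analysis stage.
#' @param sex_missing,age_missing Missingness rates for sex and age.
#' @param mean_extra_events Mean of the Poisson count of events beyond the
#'   first per case.
#' @param seed Integer seed; the generator derives all stage seeds from it.
#' @return A list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_cases = 500, seed = 1)
#' sim <- synth_generate(cfg)
#' sim$reports
#' @export
synth_config <- function(n_cases = 20000,
                         background_drugs = 10,
                         background_pts = 40,
                         target_shares = c(bortezomib = 0.10,
                                           carfilzomib = 0.045,
                                           ixazomib = 0.055),
                         planted_signals = tibble(
                           drug = "bortezomib",
                           pt = "Neuropathy peripheral",
                           rrr = 20),
                         sex_effects = tibble(
                           drug = "bortezomib",
                           pt = "Polyneuropathy",
                           male_multiplier = 3),
                         tto_laws = tibble(
                           drug = c("bortezomib", "carfilzomib", "ixazomib"),
                           shape = c(0.70, 0.61, 0.65),
                           scale = c(68.8, 81.9, 153.5)),
                         duplicate_rate = 0.05,
                         concomitant_drug = "thalidomide",
                         concomitant_rate = 0.10,
                         sex_missing = 0.15,
                         age_missing = 0.30,
                         mean_extra_events = 1,
                         seed = 1L) {
  stopifnot(n_cases >= 1, background_drugs >= 1, background_pts >= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            sum(target_shares) < 1, all(target_shares > 0))
  planted_signals <- if (is.null(planted_signals)) {
    tibble(drug = character(), pt = character(), rrr = numeric())
  } else as_tibble(planted_signals)
  sex_effects <- if (is.null(sex_effects)) {
    tibble(drug = character(), pt = character(), male_multiplier = numeric())
  } else as_tibble(sex_effects)
  if (nrow(planted_signals) > 0 && any(planted_signals$rrr <= 0)) {
    abort("planted rrr values must be strictly positive")
  }
  if (nrow(sex_effects) > 0 && any(sex_effects$male_multiplier <= 0)) {
    abort("sex multipliers must be strictly positive")
  }
  tto_laws <- as_tibble(tto_laws)
  if (nrow(tto_laws) > 0 && any(tto_laws$shape <= 0 | tto_laws$scale <= 0)) {
    abort("Weibull shape and scale must be strictly positive")
  }
  cfg <- list(n_cases = as.integer(n_cases),
              background_drugs = as.integer(background_drugs),
              background_pts = as.integer(background_pts),
              target_shares = target_shares,
              planted_signals = planted_signals,
              sex_effects = sex_effects,
              tto_laws = tto_laws,
              duplicate_rate = duplicate_rate,
              concomitant_drug = concomitant_drug,
              concomitant_rate = concomitant_rate,
              sex_missing = sex_missing,
              age_missing = age_missing,
              mean_extra_events = mean_extra_events,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [synth_config()];
#'   `planted_signals`, `sex_effects` and `tto_laws` are lists of maps.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  to_tbl <- function(x) if (is.null(x)) NULL else purrr::map_dfr(x, as_tibble)
  args <- raw
  args$planted_signals <- to_tbl(raw$planted_signals)
  args$sex_effects <- to_tbl(raw$sex_effects)
  if (!is.null(raw$tto_laws)) args$tto_laws <- purrr::map_dfr(raw$tto_laws, as_tibble)
  if (!is.null(raw$target_shares)) args$target_shares <- unlist(raw$target_shares)
  do.call(synth_config, args)
}

# PT vocabulary: the shipped mapping, truncated to the configured size.
synth_pt_vocab <- function(cfg) {
  map <- read_pt_soc()
  if (cfg$background_pts > nrow(map)) {
    abort(sprintf("background_pts (%d) exceeds the shipped PT vocabulary (%d)",
                  cfg$background_pts, nrow(map)))
  }
  map[seq_len(cfg$background_pts), ]
}

synth_drug_universe <- function(cfg) {
  targets <- names(cfg$target_shares)
  bg <- sprintf("backgrounddrug%02d", seq_len(cfg$background_drugs))
  bg_share <- (1 - sum(cfg$target_shares)) / cfg$background_drugs
  tibble(drug = c(targets, bg),
         share = c(unname(cfg$target_shares), rep(bg_share, cfg$background_drugs)),
         is_target = c(rep(TRUE, length(targets)), rep(FALSE, cfg$background_drugs)))
}

#' Generate a synthetic report collection with ground truth
#'
#' Draws `n_cases` cases: one primary-suspect drug per case (categorical over
#' targets + background), sex Bernoulli(0.5) before missingness, one plus a
#' Poisson count of PT-coded events from the background multinomial tilted by
#' any planted association (and sex multiplier for male cases), a therapy
#' start date, per-event onset latencies `ceiling(Weibull(shape, scale))`
#' days (so onsets are whole days >= 1), and an event/receipt date derived
#' from them. A `duplicate_rate` fraction of cases gains an extra version
#' with an earlier receipt date and lower version id, differing only in
#' those two fields.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `reports` (a `faers_reports` collection
#'   including duplicate versions) and `truth` (planted parameters plus exact
#'   bookkept counts: per-drug case counts, per-(drug, pt) distinct-report
#'   counts, onset draws, duplicate and co-mention bookkeeping).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(derive_seed(cfg$seed, "generate"))
  n <- cfg$n_cases
  vocab <- synth_pt_vocab(cfg)
  universe <- synth_drug_universe(cfg)

  case_id <- sprintf("C%07d", seq_len(n))
  drug <- sample(universe$drug, n, replace = TRUE, prob = universe$share)
  sex_true <- sample(c("F", "M"), n, replace = TRUE)
  sex <- ifelse(runif(n) < cfg$sex_missing, NA_character_, sex_true)
  age <- round(pmin(pmax(rnorm(n, 66, 12), 1), 100), 0)
  age[runif(n) < cfg$age_missing] <- NA_real_
  country <- sample(c("US", "JP", "FR", "DE", "CN", "AU"), n, replace = TRUE,
                    prob = c(0.45, 0.10, 0.08, 0.06, 0.06, 0.25))
  reporter <- sample(c("physician", "consumer", "health-professional",
                       "pharmacist", NA_character_),
                     n, replace = TRUE, prob = c(0.50, 0.19, 0.10, 0.07, 0.14))
  therapy_start <- as.Date("2004-01-01") +
    sample.int(7000, n, replace = TRUE) - 1

  # Events: 1 + Poisson extra PT draws per case; the PT distribution is the
  # uniform background tilted by planted rrr (per drug) and male multipliers.
  n_events <- 1L + rpois(n, cfg$mean_extra_events)
  case_idx <- rep(seq_len(n), n_events)
  pt <- character(length(case_idx))
  male <- !is.na(sex_true) & sex_true == "M"
  tilt_key <- paste(drug, male)[case_idx]
  base_w <- rep(1, nrow(vocab))
  for (key in unique(tilt_key)) {
    rows <- which(tilt_key == key)
    parts <- strsplit(key, " ")[[1]]
    d <- parts[1]; is_male <- parts[2] == "TRUE"
    w <- base_w
    ps <- cfg$planted_signals[cfg$planted_signals$drug == d, ]
    if (nrow(ps) > 0) {
      j <- match(ps$pt, vocab$pt)
      if (anyNA(j)) abort("planted signal PT not in the generator vocabulary")
      w[j] <- w[j] * ps$rrr
    }
    if (is_male) {
      se <- cfg$sex_effects[cfg$sex_effects$drug == d, ]
      if (nrow(se) > 0) {
        j <- match(se$pt, vocab$pt)
        if (anyNA(j)) abort("sex-effect PT not in the generator vocabulary")
        w[j] <- w[j] * se$male_multiplier
      }
    }
    pt[rows] <- sample(vocab$pt, length(rows), replace = TRUE, prob = w)
  }

  events <- tibble(case_idx = case_idx, pt = pt) |> distinct()

  # Per-event onset from the drug's Weibull law; whole days >= 1.
  law <- left_join(tibble(drug = drug[events$case_idx]), cfg$tto_laws,
                   by = "drug")
  law$shape[is.na(law$shape)] <- 1
  law$scale[is.na(law$scale)] <- 90
  onset <- as.integer(ceiling(rweibull(nrow(events), law$shape, law$scale)))
  onset[onset < 1L] <- 1L
  events$event_date <- therapy_start[events$case_idx] + onset
  events$onset_days <- onset

  receipt <- as.Date(vapply(split(as.numeric(events$event_date),
                                  events$case_idx),
                            max, numeric(1))[as.character(seq_len(n))],
                     origin = "1970-01-01") + sample.int(60, n, replace = TRUE)

  outcome_pool <- c("death", "disability", "hospitalization",
                    "life-threatening", "other")
  outcome_p <- c(0.15, 0.01, 0.20, 0.03, 0.60)
  draws <- matrix(runif(n * 5) < rep(outcome_p, each = n), nrow = n)
  draws[rowSums(draws) == 0, 5] <- TRUE
  outcomes <- tibble(case_idx = rep(seq_len(n), 5)[as.vector(draws)],
                     outcome = rep(outcome_pool, each = n)[as.vector(draws)]) |>
    arrange(.data$case_idx, .data$outcome)

  # Concomitant thalidomide-style co-mentions on bortezomib cases.
  comed <- drug == "bortezomib" & runif(n) < cfg$concomitant_rate

  dup <- runif(n) < cfg$duplicate_rate
  version <- ifelse(dup, 2L, 1L)
  primaryid <- paste0(case_id, "-", version)

  demo <- tibble(primaryid = primaryid, case_id = case_id,
                 version_id = version, receipt_date = receipt, sex = sex,
                 age_years = age, country = country, reporter = reporter)
  drugs <- tibble(primaryid = primaryid[c(seq_len(n), which(comed))],
                  drug_seq = c(rep(1L, n), rep(2L, sum(comed))),
                  verbatim_name = c(toupper(drug),
                                    rep(toupper(cfg$concomitant_drug), sum(comed))),
                  role = c(rep("PS", n), rep("C", sum(comed))),
                  therapy_start = c(therapy_start,
                                    therapy_start[comed])) |>
    arrange(.data$primaryid, .data$drug_seq)
  events_tbl <- tibble(primaryid = primaryid[events$case_idx],
                       pt = events$pt, soc = NA_character_,
                       event_date = events$event_date) |>
    arrange(.data$primaryid, .data$pt)
  outcomes_tbl <- tibble(primaryid = primaryid[outcomes$case_idx],
                         outcome = outcomes$outcome)

  # Duplicate versions: identical content, earlier receipt, lower version.
  if (any(dup)) {
    di <- which(dup)
    dup_pid <- paste0(case_id[di], "-1")
    demo_dup <- demo[di, ]
    demo_dup$primaryid <- dup_pid
    demo_dup$version_id <- 1L
    demo_dup$receipt_date <- demo_dup$receipt_date -
      sample.int(365, length(di), replace = TRUE)
    copy_sub <- function(tbl, old, new) {
      sub <- tbl[tbl$primaryid %in% old, ]
      sub$primaryid <- new[match(sub$primaryid, old)]
      sub
    }
    demo <- bind_rows(demo, demo_dup)
    drugs <- bind_rows(drugs, copy_sub(drugs, primaryid[di], dup_pid))
    events_tbl <- bind_rows(events_tbl, copy_sub(events_tbl, primaryid[di], dup_pid))
    outcomes_tbl <- bind_rows(outcomes_tbl, copy_sub(outcomes_tbl, primaryid[di], dup_pid))
  }
  demo <- arrange(demo, .data$case_id, .data$version_id)
  drugs <- arrange(drugs, .data$primaryid, .data$drug_seq)
  events_tbl <- arrange(events_tbl, .data$primaryid, .data$pt)
  outcomes_tbl <- arrange(outcomes_tbl, .data$primaryid, .data$outcome)

  reports <- new_faers_reports(demo, drugs, events_tbl, outcomes_tbl)

  pair_counts <- tibble(drug = drug[events$case_idx], pt = events$pt) |>
    count(.data$drug, .data$pt, name = "a")
  truth <- list(config = cfg,
                drug_of_case = tibble(case_id = case_id, drug = drug,
                                      sex = sex_true,
                                      therapy_start = therapy_start),
                case_counts = tibble(drug = drug) |> count(.data$drug, name = "n_cases"),
                pair_counts = pair_counts,
                onsets = tibble(case_id = case_id[events$case_idx],
                                drug = drug[events$case_idx],
                                pt = events$pt, onset_days = events$onset_days),
                n_duplicates = sum(dup),
                comed_case_ids = case_id[comed],
                pt_vocab = vocab)
  list(reports = reports, truth = truth)
}
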