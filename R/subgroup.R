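# Sex-stratified disproportionality and volcano-plot coordinates.

#' Sex-stratified ROR within a drug's reports
#'
#' For each (drug, PT), builds the 2x2 of (male vs female) x (PT vs other
#' PTs) restricted to the drug's reports with known sex, and computes the
#' ROR (male odds over female odds of reporting the PT) with its Woolf
#' interval and a chi-square p-value on the same table. Reports with missing
#' sex are excluded and counted. An ROR above 1 means the event is reported
#' relatively more often in males.
#'
#' @param records An [event_records()] universe.
#' @param drugs Drug labels (default: tagged target drugs).
#' @param min_count Minimum PT count within the drug to score (default 1).
#' @param yates Yates correction for the chi-square (default `TRUE`).
#' @return A tibble, one row per (drug, pt): cells `m1` (male, PT), `m0`
#'   (male, other), `f1`, `f0`, `ror`, `ror_low`, `ror_high`, `p_value`,
#'   `log2_ror`, `neg_log10_p`, `n_excluded_missing_sex`.
#' @export
sex_stratified_ror <- function(records, drugs = NULL, min_count = 1,
                               yates = TRUE) {
  if (is.null(drugs)) drugs <- sort(unique(records$drug[records$is_target]))
  sub <- filter(records, .data$drug %in% drugs)
  n_missing <- sub |> distinct(.data$case_id, .data$drug, .data$sex) |>
    filter(is.na(.data$sex)) |> nrow()
  sub <- filter(sub, !is.na(.data$sex))
  if (nrow(sub) == 0) abort("no sex-known records for the requested drugs")
  cells <- sub |>
    count(.data$drug, .data$pt, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L)
  if (!"M" %in% names(cells)) cells$M <- 0L
  if (!"F" %in% names(cells)) cells$F <- 0L
  totals <- sub |> count(.data$drug, .data$sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n",
                       values_fill = 0L, names_prefix = "tot_")
  if (!"tot_M" %in% names(totals)) totals$tot_M <- 0L
  if (!"tot_F" %in% names(totals)) totals$tot_F <- 0L
  out <- cells |>
    left_join(totals, by = "drug") |>
    mutate(a = .data$M, b = .data$tot_M - .data$M,
           c = .data$F, d = .data$tot_F - .data$F) |>
    filter(.data$a + .data$c >= min_count)
  degen <- out$a + out$b == 0 | out$c + out$d == 0
  if (any(degen)) {
    warn(sprintf("sex_stratified_ror: %d degenerate stratum/strata dropped",
                 sum(degen)))
    out <- out[!degen, ]
  }
  out <- out |> ror_stat() |> prr_chi2(yates = yates)
  out |>
    transmute(drug = .data$drug, pt = .data$pt,
              m1 = .data$a, m0 = .data$b, f1 = .data$c, f0 = .data$d,
              ror = .data$ror, ror_low = .data$ror_low,
              ror_high = .data$ror_high,
              p_value = pchisq(.data$chi2, df = 1, lower.tail = FALSE),
              log2_ror = log2(.data$ror),
              neg_log10_p = -log10(.data$p_value),
              n_excluded_missing_sex = n_missing)
}

#' Volcano-plot coordinate table
#'
#' Emits `(log2_ror, neg_log10_p)` coordinates with a significance flag at
#' the configured level; the flag uses `p < alpha` strictly (a p-value
#' exactly at the boundary is not flagged). Optional Benjamini-Hochberg
#' adjustment replaces the p-values used for flagging and for the y
#' coordinate.
#'
#' @param results A [sex_stratified_ror()] tibble.
#' @param p_adjust `"none"` (the raw chi-square p-values) or `"BH"`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble `drug, pt, log2_ror, neg_log10_p, p_value, significant`.
#' @export
volcano_table <- function(results, p_adjust = c("none", "BH"),
                          alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(results) == 0) abort("volcano_table needs at least one result")
  p <- results$p_value
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  transmute(results, drug = .data$drug, pt = .data$pt,
            log2_ror = .data$log2_ror,
            p_value = p,
            neg_log10_p = -log10(p),
            significant = p < alpha)
}
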