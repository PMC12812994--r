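# Fourfold tables and the frequentist disproportionality statistics:
# reporting odds ratio (Woolf interval), proportional reporting ratio with
# Yates-corrected chi-square, and the BCPNN information component with its
# closed-form posterior credibility bound.

#' Build the 2x2 fourfold table for one drug-event pair
#'
#' Counts at the report-PT pair level over the full event universe:
#' `a` = distinct reports with the drug and the PT, `b` = the drug's other
#' report-PT pairs, `c` = the PT's pairs under all other drugs, `d` = the
#' remainder, so `a + b` equals the drug's total report-PT pairs.
#'
#' @param records An [event_records()] tibble (the full, SOC-agnostic
#'   universe — disproportionality needs all drugs and PTs for b, c, d).
#' @param drug,pt The target pair.
#' @return A one-row tibble `drug, pt, a, b, c, d`.
#' @export
build_contingency <- function(records, drug, pt) {
  is_d <- records$drug == drug
  is_p <- records$pt == pt
  a <- sum(is_d & is_p)
  b <- sum(is_d & !is_p)
  c_ <- sum(!is_d & is_p)
  d <- sum(!is_d & !is_p)
  if (a + b == 0 || c_ + d == 0) {
    abort(sprintf("degenerate fourfold table for (%s, %s): an empty margin",
                  drug, pt))
  }
  tibble(drug = drug, pt = pt, a = a, b = b, c = c_, d = d)
}

# All pairs for the given drugs at once (vectorised contingency build).
contingency_tables <- function(records, drugs = NULL) {
  if (is.null(drugs)) drugs <- unique(records$drug[records$is_target])
  pair <- records |> count(.data$drug, .data$pt, name = "a")
  drug_tot <- pair |> group_by(.data$drug) |> summarise(nd = sum(.data$a))
  pt_tot <- pair |> group_by(.data$pt) |> summarise(np = sum(.data$a))
  N <- sum(pair$a)
  pair |>
    filter(.data$drug %in% drugs) |>
    left_join(drug_tot, by = "drug") |>
    left_join(pt_tot, by = "pt") |>
    mutate(b = .data$nd - .data$a,
           c = .data$np - .data$a,
           d = N - .data$nd - .data$np + .data$a) |>
    select("drug", "pt", "a", "b", "c", "d")
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' `ROR = ad / bc`; the interval is `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b +
#' 1/c + 1/d))`. When any cell is zero the Haldane-Anscombe continuity
#' correction (0.5 added to all four cells) is applied and flagged in the
#' `ror_corrected` column; the Bayesian statistics regularise on their own
#' and are left untouched.
#'
#' @param tables A tibble with columns `a`, `b`, `c`, `d` (one row per pair).
#' @return The input with `ror`, `ror_low`, `ror_high`, `ror_corrected`
#'   appended.
#' @export
ror_stat <- function(tables) {
  zero <- with(tables, a == 0 | b == 0 | c == 0 | d == 0)
  k <- ifelse(zero, 0.5, 0)
  a <- as.numeric(tables$a) + k; b <- as.numeric(tables$b) + k
  c_ <- as.numeric(tables$c) + k; d <- as.numeric(tables$d) + k
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  mutate(tables,
         ror = ror,
         ror_low = exp(log(ror) - 1.96 * se),
         ror_high = exp(log(ror) + 1.96 * se),
         ror_corrected = zero)
}

#' Proportional reporting ratio and Yates-corrected chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-square is the Yates
#' continuity-corrected Pearson statistic on the same 2x2 (set
#' `yates = FALSE` for the uncorrected form).
#'
#' @param tables A tibble with columns `a`, `b`, `c`, `d`.
#' @param yates Apply the Yates continuity correction (default `TRUE`).
#' @return The input with `prr` and `chi2` appended.
#' @export
prr_chi2 <- function(tables, yates = TRUE) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c_ <- as.numeric(tables$c); d <- as.numeric(tables$d)
  if (any(a + b == 0 | c_ + d == 0)) abort("zero row margin in PRR")
  n <- a + b + c_ + d
  prr <- (a / (a + b)) / (c_ / (c_ + d))
  dev <- abs(a * d - b * c_)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  chi2[(a + c_) == 0 | (b + d) == 0] <- 0
  mutate(tables, prr = prr, chi2 = chi2)
}

# Pseudo-count of the closed-form shrinkage posterior behind the
# information component. With 0.5 added to both the observed and the
# expected count the posterior of the observed-to-expected ratio is
# Gamma(a + 1/2, E + 1/2), the form in current routine BCPNN practice.
bcpnn_pseudo <- 0.5

#' BCPNN information component and lower credibility bound
#'
#' The information component `IC = log2 p(drug, event) /
#' (p(drug) p(event))` with closed-form Bayesian shrinkage: writing
#' `E = (a+b)(a+c)/N` for the expected count under independence,
#' `IC = log2((a + 1/2)/(E + 1/2))` and the reporting-rate ratio posterior is
#' `Gamma(a + 1/2, E + 1/2)`, whose 2.5th percentile gives `IC025`. As the
#' pseudo-counts shrink to zero (and a grows) `IC` tends to the naive
#' `log2(a N / ((a+b)(a+c)))`.
#'
#' @param tables A tibble with columns `a`, `b`, `c`, `d`.
#' @return The input with `ic` and `ic025` appended (bits).
#' @export
bcpnn_ic <- function(tables) {
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c_ <- as.numeric(tables$c); d <- as.numeric(tables$d)
  N <- a + b + c_ + d
  if (any(N <= 0)) abort("empty universe in BCPNN")
  E <- (a + b) * (a + c_) / N
  k <- bcpnn_pseudo
  ic <- log2((a + k) / (E + k))
  ic025 <- log2(qgamma(0.025, shape = a + k, rate = E + k))
  mutate(tables, ic = ic, ic025 = ic025)
}
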