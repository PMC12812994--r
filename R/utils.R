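# Shared helpers: rounding, date parsing, name normalisation.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for the percentages in descriptive
#' tables so that printed values match the usual convention of clinical
#' tables (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Parse dates stored as YYYYMMDD strings. Partial precision (YYYY or YYYYMM)
# is deliberately mapped to NA: year- or month-level dates cannot support
# day-resolution latency arithmetic, and fabricating a day would bias
# time-to-onset downwards or upwards depending on the fill rule.
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !grepl("^[0-9]{8}$", x)] <- NA_character_
  out <- as.Date(x, format = "%Y%m%d")
  out
}

format_faers_date <- function(d) {
  ifelse(is.na(d), "", format(d, "%Y%m%d"))
}

#' Normalise a drug name for lexicon matching
#'
#' Case-folds, strips punctuation, and collapses whitespace so that verbatim
#' FAERS drug strings such as `"VELCADE."` or `"Velcade "` match a lexicon
#' synonym by exact token comparison. Matching is exact-token, never
#' substring, so combination strings do not produce false positives.
#'
#' @param x Character vector of verbatim drug names.
#' @return Character vector of normalised names.
#' @examples
#' normalize_drug_name("VELCADE.") # "velcade"
#' @export
normalize_drug_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Derive a child RNG seed from a root seed and a stage label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
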