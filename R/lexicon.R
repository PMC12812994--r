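# Drug lexicon (label -> synonyms) and PT -> SOC mapping.

#' Read a drug lexicon
#'
#' A lexicon maps a canonical drug label (generic name) to a set of synonyms
#' (generic plus brand names). Two on-disk forms are accepted: a two-column
#' CSV (`label,synonym`, one row per synonym) or a YAML map of
#' `label: [synonyms]`. Synonyms are normalised with [normalize_drug_name()]
#' and the label itself is always included as a synonym.
#'
#' @param path Path to a `.csv` or `.yaml`/`.yml` file. The default is the
#'   lexicon shipped with the package (bortezomib/VELCADE,
#'   carfilzomib/KYPROLIS, ixazomib/NINLARO, thalidomide/THALOMID).
#' @return A tibble with columns `label` and `synonym` (normalised), class
#'   `drug_lexicon`.
#' @examples
#' lex <- read_drug_lexicon()
#' lex
#' @export
read_drug_lexicon <- function(path = system.file("extdata", "drug_lexicon.csv",
                                                 package = "faersignal")) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    lex <- purrr::imap_dfr(raw, function(syns, label) {
      tibble(label = label, synonym = as.character(syns))
    })
  } else {
    lex <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (!all(c("label", "synonym") %in% names(lex))) {
      abort("lexicon CSV must have columns 'label' and 'synonym'")
    }
  }
  lex <- lex |>
    transmute(label = .data$label,
              synonym = normalize_drug_name(.data$synonym)) |>
    bind_rows(tibble(label = unique(lex$label),
                     synonym = normalize_drug_name(unique(lex$label)))) |>
    distinct()
  dup <- lex |> count(.data$synonym) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("synonym maps to more than one label: ",
                 paste(dup$synonym, collapse = ", ")))
  }
  class(lex) <- c("drug_lexicon", class(lex))
  lex
}

#' Read a preferred-term to system-organ-class mapping
#'
#' @param path Two-column CSV (`pt,soc`), UTF-8. Defaults to the miniature
#'   MedDRA-like mapping shipped with the package (40 PTs, of which 20 fall
#'   under "Nervous system disorders").
#' @return A tibble with columns `pt` and `soc`.
#' @export
read_pt_soc <- function(path = system.file("extdata", "pt_soc.csv",
                                           package = "faersignal")) {
  if (!file.exists(path)) abort(paste0("PT/SOC mapping not found: ", path))
  map <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("pt", "soc") %in% names(map))) {
    abort("PT/SOC CSV must have columns 'pt' and 'soc'")
  }
  distinct(as_tibble(map[, c("pt", "soc")]))
}

# Resolve verbatim drug names against a lexicon; returns the label or NA.
match_lexicon <- function(verbatim, lexicon) {
  norm <- normalize_drug_name(verbatim)
  lexicon$label[match(norm, lexicon$synonym)]
}
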