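#' Normalize clinical condition text
#'
#' Lowercases, strips Spanish diacritics, collapses internal whitespace and
#' trims. All lexicon matching in the package operates on normalized text, so
#' "Neumonía  Bacteriana" and "neumonia bacteriana" are the same condition.
#'
#' @param x character vector (NA becomes "").
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text("  Insuficiencia   Cardíaca ")
normalize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- chartr("áéíóúüñ", "aeiouun", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Escape a literal string for use inside a regular expression.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Alternation regex matching any of the given literal phrases.
phrase_regex <- function(phrases) {
  paste0("(", paste(regex_escape(phrases), collapse = "|"), ")")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
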