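#' Normalize a term string
#'
#' Lowercases, strips outer whitespace and collapses internal whitespace runs
#' to a single space. This is the normalization applied to every lexicon term
#' at insert time and to every query, so lookups are case-insensitive.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' norm_term("  Whole   Brain ")
norm_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Canonical lexicon lookup key: normalized term with whitespace absorbed
# around punctuation, so "S/C", "s / c" and "s/c" address one entry and a
# token run [whole, -, brain, radiotherapy] keys as "whole-brain radiotherapy".
term_key <- function(x) {
  x <- norm_term(x)
  gsub("[[:space:]]*([^[:alnum:][:space:]])[[:space:]]*", "\\1", x)
}

#' Split a raw site name into classified tokens
#'
#' Splits on whitespace; every non-alphanumeric character becomes its own
#' punctuation token except `#` immediately followed by digits, which forms a
#' single number token (site names such as "Whole Brain #2" use that idiom).
#' Alphanumeric runs are `word` tokens unless they are all digits, in which
#' case they are `number` tokens.
#'
#' @param raw a single site-name string (may be empty).
#' @return a data.frame with one row per token and columns `text` (surface),
#'   `norm` (lowercased surface), `kind` (`"word"`, `"number"` or `"punct"`),
#'   `index` (1-based position) and `start`/`end` (1-based inclusive character
#'   span in `raw`).
#' @export
#' @examples
#' tokenize("Prostate/Prox SV")
tokenize <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  empty <- data.frame(
    text = character(), norm = character(), kind = character(),
    index = integer(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  if (!nzchar(raw)) {
    return(empty)
  }
  m <- gregexpr("#[0-9]+|[[:alnum:]]+|[^[:alnum:][:space:]]", raw)[[1]]
  if (m[1] == -1L) {
    return(empty)
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  text <- substring(raw, start, start + len - 1L)
  kind <- ifelse(
    grepl("^#?[0-9]+$", text), "number",
    ifelse(grepl("^[^[:alnum:]]$", text), "punct", "word")
  )
  data.frame(
    text = text, norm = tolower(text), kind = kind,
    index = seq_along(text), start = start, end = start + len - 1L,
    stringsAsFactors = FALSE
  )
}
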