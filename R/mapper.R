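concept_annotation <- function(label, cuis, semtypes, span, kind, term = NA_character_) {
  structure(
    list(surface_label = label, cuis = as.character(cuis),
         semtypes = as.character(semtypes), token_span = as.integer(span),
         kind = kind, term = term),
    class = "rt_concept_annotation"
  )
}

new_site_annotation <- function(raw, annotations = list(),
                                unresolved_tokens = integer(),
                                tokens = NULL, resolutions = NULL) {
  structure(
    list(raw = raw, annotations = annotations,
         unresolved_tokens = as.integer(unresolved_tokens),
         tokens = tokens, resolutions = resolutions),
    class = "rt_site_annotation"
  )
}

#' Assemble resolved tokens into maximal lexicon terms
#'
#' Greedy leftmost-longest segmentation: at each position the longest
#' contiguous token run whose joined, normalized form is a lexicon term
#' becomes one concept annotation, and matching restarts after it. Runs are
#' joined with single spaces and keyed through the same normalization used at
#' lexicon insert, so a run may span punctuation tokens only when a
#' punctuation-bearing term ("s/c", "whole-brain radiotherapy") exists; for
#' all-word runs this is exactly the space-joined word match. Punctuation
#' tokens outside a term become punctuation annotations, number tokens and
#' unmatched resolved words become unmapped annotations, and unresolved word
#' tokens are reported by index.
#'
#' @param tokens data.frame from [tokenize()].
#' @param resolved character vector, one element per token: the resolved word
#'   for word tokens (`NA` when unresolved), ignored for punctuation/number
#'   tokens. Defaults to the token norms (everything treated as resolved).
#' @param lexicon an `rt_lexicon`.
#' @return list with `annotations` (list of concept annotations) and
#'   `unresolved_tokens` (integer indices).
#' @export
assemble_terms <- function(tokens, resolved = tokens$norm, lexicon) {
  stopifnot(is.data.frame(tokens), length(resolved) == nrow(tokens))
  n <- nrow(tokens)
  piece <- ifelse(tokens$kind == "word", resolved, tokens$norm)
  anns <- list()
  unresolved <- integer()
  emit <- function(a) anns[[length(anns) + 1L]] <<- a
  maxrun <- max(1L, lexicon$meta$max_term_tokens)
  i <- 1L
  while (i <= n) {
    kind <- tokens$kind[i]
    if (kind == "word" && is.na(piece[i])) {
      unresolved <- c(unresolved, i)
      i <- i + 1L
      next
    }
    if (kind == "word") {
      matched <- FALSE
      for (j in seq(min(n, i + maxrun - 1L), i)) {
        if (tokens$kind[j] != "word") next # a term run ends on a word
        run <- i:j
        if (anyNA(piece[run])) next
        key <- term_key(paste(piece[run], collapse = " "))
        hit <- lexicon_lookup(lexicon, key)
        if (!is.null(hit)) {
          e <- hit[[1L]]
          emit(concept_annotation(e$preferred_label, e$cuis, e$semtypes,
                                  span = c(i, j), kind = "concept",
                                  term = key))
          i <- j + 1L
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        emit(concept_annotation(tokens$text[i], character(), character(),
                                span = c(i, i), kind = "unmapped"))
        i <- i + 1L
      }
    } else if (kind == "punct") {
      emit(concept_annotation(tokens$text[i], character(), "T000",
                              span = c(i, i), kind = "punctuation"))
      i <- i + 1L
    } else { # number
      emit(concept_annotation(tokens$text[i], character(), character(),
                              span = c(i, i), kind = "unmapped"))
      i <- i + 1L
    }
  }
  list(annotations = anns, unresolved_tokens = unresolved)
}

#' Annotate one site name
#'
#' The full pipeline for a single raw string: tokenize; mark each word token
#' found in the lexicon vocabulary (or as a whole term) as an exact hit; look
#' the remainder up in the general-English wordlist; resolve what is left via
#' bigram-context candidates ranked by edit distance ([resolve_token()]); then
#' assemble maximal lexicon terms ([assemble_terms()]). Deterministic — no
#' randomness anywhere.
#'
#' @param raw site-name string.
#' @param lexicon an `rt_lexicon`.
#' @param model an `rt_bigrams` model; trained from the lexicon's own term
#'   token sequences when `NULL` (pass a pre-trained model in loops).
#' @param config an [resolver_config()].
#' @return object of class `rt_site_annotation`: `raw`, `annotations` (ordered
#'   concept/punctuation/unmapped annotations), `unresolved_tokens` (indices),
#'   plus the token table and per-token resolution statuses.
#' @export
#' @examples
#' lex <- build_fixture_lexicon()
#' annotate_site("SCV-MLB", lex)
annotate_site <- function(raw, lexicon, model = NULL,
                          config = resolver_config()) {
  stopifnot(inherits(lexicon, "rt_lexicon"))
  if (is.null(model)) {
    model <- train_bigrams(lexicon_token_sequences(lexicon))
  }
  tokens <- tokenize(raw)
  n <- nrow(tokens)
  if (n == 0L) {
    return(new_site_annotation(raw, tokens = tokens,
                               resolutions = character()))
  }
  status <- rep(NA_character_, n)
  piece <- rep(NA_character_, n)
  is_word <- tokens$kind == "word"
  # pass 1: exact lexicon hits, then the English fallback dictionary
  for (i in which(is_word)) {
    nm <- tokens$norm[i]
    if (lexicon_has_token(lexicon, nm) || !is.null(lexicon_lookup(lexicon, nm))) {
      status[i] <- "exact"
      piece[i] <- nm
    } else if (nm %in% config$english_words) {
      status[i] <- "english"
      piece[i] <- nm
    }
  }
  # pass 2: bigram + edit-distance resolution, contexts from pass-1 words only
  vocab <- lexicon_vocab(lexicon, words_only = TRUE)
  pending <- which(is_word & is.na(status))
  pass1_piece <- piece
  for (i in pending) {
    left <- if (i > 1L && is_word[i - 1L] && !is.na(pass1_piece[i - 1L])) {
      pass1_piece[i - 1L]
    }
    right <- if (i < n && is_word[i + 1L] && !is.na(pass1_piece[i + 1L])) {
      pass1_piece[i + 1L]
    }
    res <- resolve_token(tokens$norm[i], left, right, model, vocab, config)
    status[i] <- res$status
    if (res$status == "fuzzy") piece[i] <- res$resolved_word
  }
  asm <- assemble_terms(tokens, piece, lexicon)
  new_site_annotation(raw, asm$annotations, asm$unresolved_tokens,
                      tokens = tokens, resolutions = status)
}

#' Annotate a corpus of site names
#'
#' @param raws character vector of site names.
#' @inheritParams annotate_site
#' @return list of `rt_site_annotation`.
#' @export
annotate_corpus <- function(raws, lexicon, model = NULL,
                            config = resolver_config()) {
  if (is.null(model)) {
    model <- train_bigrams(lexicon_token_sequences(lexicon))
  }
  lapply(as.character(raws), annotate_site, lexicon = lexicon, model = model,
         config = config)
}

format_concept <- function(ann) {
  switch(ann$kind,
    punctuation = sprintf("%s [PUNC:T000]", ann$surface_label),
    concept = sprintf("%s [%s:%s]", ann$surface_label,
                      paste(ann$cuis, collapse = ","),
                      paste(ann$semtypes, collapse = ",")),
    ann$surface_label
  )
}

#' Bracket-style strings for the annotations of a site
#'
#' @param sa an `rt_site_annotation`.
#' @param kinds which annotation kinds to include.
#' @return character vector, one element per retained annotation, in the
#'   `label [cui1,cui2:Ta,Tb]` style (an empty CUI list renders as `[:Ta]`,
#'   punctuation as `[PUNC:T000]`).
#' @export
site_concept_strings <- function(sa, kinds = "concept") {
  stopifnot(inherits(sa, "rt_site_annotation"))
  keep <- vapply(sa$annotations, function(a) a$kind %in% kinds, logical(1))
  vapply(sa$annotations[keep], format_concept, character(1))
}

#' Serialize a site annotation
#'
#' @param sa an `rt_site_annotation`.
#' @param style `"bracket"` (tab-joined bracket cells, the display form),
#'   `"tsv"` (raw, number of concepts, one column per annotation, unresolved
#'   token surfaces) or `"jsonl"` (one JSON object).
#' @return a single string.
#' @export
serialize_annotation <- function(sa, style = c("bracket", "tsv", "jsonl")) {
  style <- match.arg(style)
  stopifnot(inherits(sa, "rt_site_annotation"))
  cells <- vapply(sa$annotations, format_concept, character(1))
  if (style == "bracket") {
    return(paste(cells, collapse = "\t"))
  }
  unres <- if (length(sa$unresolved_tokens)) {
    paste(sa$tokens$text[sa$unresolved_tokens], collapse = ",")
  } else {
    ""
  }
  if (style == "tsv") {
    n_con <- sum(vapply(sa$annotations, function(a) a$kind == "concept",
                        logical(1)))
    return(paste(c(sa$raw, n_con, cells, unres), collapse = "\t"))
  }
  as.character(jsonlite::toJSON(list(
    raw = sa$raw,
    annotations = lapply(sa$annotations, function(a) {
      list(label = a$surface_label, cuis = a$cuis, semtypes = a$semtypes,
           span = a$token_span, kind = a$kind)
    }),
    unresolved_tokens = sa$unresolved_tokens
  ), auto_unbox = TRUE))
}

#' @export
print.rt_site_annotation <- function(x, ...) {
  cat(sprintf("<site> %s\n", x$raw))
  for (a in x$annotations) cat("  ", format_concept(a), "\n", sep = "")
  if (length(x$unresolved_tokens)) {
    cat("  unresolved: ",
        paste(x$tokens$text[x$unresolved_tokens], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
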