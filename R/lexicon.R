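#' Construct a concept entry
#'
#' A concept entry ties one normalized surface term to its concept identifiers
#' (CUIs) and semantic-type codes. Supplement entries (manually curated
#' radiotherapy abbreviations and concepts) may carry an empty CUI list;
#' entries from a concept source may not.
#'
#' @param term surface term (normalized internally).
#' @param cuis character vector of concept identifiers, possibly empty.
#' @param semtypes character vector of semantic-type codes (`Tddd`; the
#'   sentinel `T000` is reserved for punctuation).
#' @param source `"umls_subset"` or `"supplement"`.
#' @param preferred_label display string; defaults to `term`.
#' @return an object of class `rt_concept_entry`.
#' @export
concept_entry <- function(term, cuis = character(), semtypes, source,
                          preferred_label = term) {
  term <- norm_term(term)
  cuis <- as.character(cuis)
  semtypes <- as.character(semtypes)
  source <- match.arg(source, c("umls_subset", "supplement"))
  if (length(semtypes) == 0L || !all(grepl("^T[0-9]{3}$", semtypes))) {
    stop("semtypes must be non-empty and match 'T' followed by 3 digits")
  }
  if (length(cuis) == 0L && source != "supplement") {
    stop("an entry without CUIs is only permitted for supplement concepts")
  }
  structure(
    list(term = term, cuis = cuis, semtypes = semtypes, source = source,
         preferred_label = preferred_label),
    class = "rt_concept_entry"
  )
}

#' Create an empty lexicon
#'
#' A lexicon maps normalized terms to concept entries and maintains the token
#' vocabulary used for fuzzy resolution. Entries are stored in hashed
#' environments, so insertion mutates the object in place.
#'
#' @param semtype_filter character vector of admitted semantic-type codes
#'   (informational; recorded from [read_concept_source()]).
#' @return an object of class `rt_lexicon`.
#' @export
new_lexicon <- function(semtype_filter = character()) {
  meta <- new.env(parent = emptyenv())
  meta$max_term_tokens <- 1L
  structure(
    list(
      entries = new.env(parent = emptyenv(), hash = TRUE),
      vocab = new.env(parent = emptyenv(), hash = TRUE),
      meta = meta,
      semtype_filter = as.character(semtype_filter)
    ),
    class = "rt_lexicon"
  )
}

# Insert an entry under `key` (defaults to the entry's own term). shadow=TRUE
# prepends, so the entry is returned first on lookup. Identical duplicates
# under the same key are dropped.
lexicon_insert <- function(lexicon, entry, key = entry$term, shadow = FALSE) {
  stopifnot(inherits(lexicon, "rt_lexicon"), inherits(entry, "rt_concept_entry"))
  k <- term_key(key)
  if (!nzchar(k)) stop("cannot insert an entry under an empty key")
  existing <- get0(k, envir = lexicon$entries, inherits = FALSE)
  if (is.null(existing)) existing <- list()
  if (any(vapply(existing, identical, logical(1), y = entry))) {
    return(invisible(lexicon))
  }
  assign(k, if (shadow) c(list(entry), existing) else c(existing, list(entry)),
         envir = lexicon$entries)
  toks <- tokenize(k)
  for (tk in toks$norm) assign(tk, TRUE, envir = lexicon$vocab)
  if (nrow(toks) > lexicon$meta$max_term_tokens) {
    lexicon$meta$max_term_tokens <- nrow(toks)
  }
  invisible(lexicon)
}

#' Look up a term in a lexicon
#'
#' Queries are normalized with the same rules used at insert time, so the
#' lookup is case-insensitive and whitespace-insensitive around punctuation.
#'
#' @param lexicon an `rt_lexicon`.
#' @param term query string.
#' @return a list of `rt_concept_entry` (supplement entries first when they
#'   shadow a concept-source entry), or `NULL` when the term is unknown.
#' @export
lexicon_lookup <- function(lexicon, term) {
  stopifnot(inherits(lexicon, "rt_lexicon"))
  get0(term_key(term), envir = lexicon$entries, inherits = FALSE)
}

#' @rdname lexicon_lookup
#' @export
lexicon_terms <- function(lexicon) {
  sort(ls(lexicon$entries))
}

#' Token vocabulary of a lexicon
#'
#' All single tokens occurring in any entry term. `words_only = TRUE` drops
#' punctuation tokens; that subset is the candidate pool for fuzzy resolution.
#'
#' @param lexicon an `rt_lexicon`.
#' @param words_only drop punctuation-character tokens.
#' @return sorted character vector.
#' @export
lexicon_vocab <- function(lexicon, words_only = FALSE) {
  v <- sort(ls(lexicon$vocab))
  if (words_only) v <- v[grepl("[[:alnum:]]", v)]
  v
}

lexicon_has_token <- function(lexicon, token) {
  exists(token, envir = lexicon$vocab, inherits = FALSE)
}

#' Token sequences of all lexicon terms
#'
#' Tokenizes every entry term and keeps the word and number tokens; these
#' sequences are the default training corpus for the bigram model used in
#' abbreviation resolution.
#'
#' @param lexicon an `rt_lexicon`.
#' @return list of character vectors.
#' @export
lexicon_token_sequences <- function(lexicon) {
  lapply(lexicon_terms(lexicon), function(tm) {
    toks <- tokenize(tm)
    toks$norm[toks$kind != "punct"]
  })
}

#' Read a pipe-delimited concept source filtered by semantic type
#'
#' Reads a minimal two-column concept file (`string|CUI`) and a semantic-type
#' file (`CUI|semtype`) in the style of UMLS MRCONSO/MRSTY, and admits exactly
#' the strings whose CUI carries at least one semantic type in `semtype_filter`.
#' Strings sharing a normalized term are merged into one entry with
#' concatenated, de-duplicated CUI and semantic-type lists in first-seen order;
#' only admitted semantic types are attached. Column positions are
#' configurable so wider RRF-style exports can be consumed.
#'
#' @param path_concepts path to the `string|CUI` file.
#' @param path_semtypes path to the `CUI|semtype` file.
#' @param semtype_filter non-empty character vector of admitted codes,
#'   e.g. `c("T023","T029","T030","T082")`.
#' @param concept_cols integer positions of the string and CUI columns.
#' @param semtype_cols integer positions of the CUI and semtype columns.
#' @return an `rt_lexicon`. Malformed rows are skipped with one summary
#'   warning; a missing file is a fatal error.
#' @export
read_concept_source <- function(path_concepts, path_semtypes, semtype_filter,
                                concept_cols = c(string = 1L, cui = 2L),
                                semtype_cols = c(cui = 1L, semtype = 2L)) {
  stopifnot(length(semtype_filter) >= 1L)
  for (p in c(path_concepts, path_semtypes)) {
    if (!file.exists(p)) stop("concept source file not found: ", p)
  }
  read_rows <- function(path, cols) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "|", fixed = TRUE)
    need <- max(cols)
    ok <- vapply(parts, function(p) {
      length(p) >= need && all(nzchar(trimws(p[cols])))
    }, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " malformed row(s) skipped in ", path, call. = FALSE)
    }
    parts <- parts[ok]
    data.frame(
      a = trimws(vapply(parts, `[`, "", cols[1L])),
      b = trimws(vapply(parts, `[`, "", cols[2L])),
      stringsAsFactors = FALSE
    )
  }
  sty <- read_rows(path_semtypes, semtype_cols) # a = cui, b = semtype
  con <- read_rows(path_concepts, concept_cols) # a = string, b = cui
  # semtypes per CUI in first-seen order
  sty_map <- lapply(split(sty$b, sty$a), unique)

  lexicon <- new_lexicon(semtype_filter)
  acc <- list() # term -> list(cuis, semtypes, label)
  order_seen <- character()
  for (i in seq_len(nrow(con))) {
    cui <- con$b[i]
    sems <- sty_map[[cui]]
    sems <- sems[sems %in% semtype_filter]
    if (length(sems) == 0L) next
    tm <- norm_term(con$a[i])
    if (!nzchar(tm)) next
    if (is.null(acc[[tm]])) {
      acc[[tm]] <- list(cuis = cui, semtypes = sems, label = con$a[i])
      order_seen <- c(order_seen, tm)
    } else {
      acc[[tm]]$cuis <- unique(c(acc[[tm]]$cuis, cui))
      acc[[tm]]$semtypes <- unique(c(acc[[tm]]$semtypes, sems))
    }
  }
  for (tm in order_seen) {
    e <- acc[[tm]]
    lexicon_insert(lexicon, concept_entry(
      tm, cuis = e$cuis, semtypes = e$semtypes,
      source = "umls_subset", preferred_label = e$label
    ))
  }
  lexicon
}

#' Load a supplement terminology file
#'
#' The supplement is a TSV with header columns `surface`, `expansion`, `cuis`
#' and `semtypes` (the last two semicolon-joined; `cuis` may be blank). It
#' carries the manually curated radiotherapy abbreviations and concepts that a
#' general-purpose concept source misses.
#'
#' @param path TSV path.
#' @return list of supplement records (`surface`, `expansion`, `cuis`,
#'   `semtypes`). Duplicate surfaces with identical payloads collapse to one
#'   record; conflicting duplicates or blank semtypes are fatal.
#' @export
load_supplement <- function(path) {
  if (!file.exists(path)) stop("supplement file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   quote = "", fileEncoding = "UTF-8")
  need <- c("surface", "expansion", "cuis", "semtypes")
  if (!all(need %in% names(df))) {
    stop("supplement must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) return(list())
  split_field <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)[[1]]
    trimws(out[nzchar(trimws(out))])
  }
  records <- list()
  for (i in seq_len(nrow(df))) {
    surface <- trimws(df$surface[i])
    expansion <- trimws(df$expansion[i])
    if (!nzchar(surface) || !nzchar(expansion)) {
      stop("supplement row ", i, ": surface and expansion must be non-empty")
    }
    semtypes <- split_field(df$semtypes[i])
    if (length(semtypes) == 0L) {
      stop("supplement row ", i, " ('", surface, "'): blank semtypes")
    }
    rec <- list(surface = surface, expansion = expansion,
                cuis = split_field(df$cuis[i]), semtypes = semtypes)
    key <- term_key(surface)
    prev <- records[[key]]
    if (!is.null(prev)) {
      if (!identical(prev[c("expansion", "cuis", "semtypes")],
                     rec[c("expansion", "cuis", "semtypes")])) {
        stop("conflicting duplicate supplement surface '", surface, "': (",
             prev$expansion, " | ", paste(prev$cuis, collapse = ";"), ") vs (",
             rec$expansion, " | ", paste(rec$cuis, collapse = ";"), ")")
      }
      next
    }
    records[[key]] <- rec
  }
  unname(records)
}

#' Merge supplement records into a lexicon
#'
#' Each record's surface and expansion both become lookup keys resolving to
#' the same supplement entry. Supplement entries shadow concept-source entries
#' on exact surface collision (manual curation exists to correct gaps in the
#' general source, so it wins).
#'
#' @param lexicon an `rt_lexicon` (mutated in place).
#' @param records list of records from [load_supplement()].
#' @return the lexicon, invisibly.
#' @export
merge_supplement <- function(lexicon, records) {
  for (rec in records) {
    entry <- concept_entry(
      rec$expansion, cuis = rec$cuis, semtypes = rec$semtypes,
      source = "supplement", preferred_label = rec$expansion
    )
    lexicon_insert(lexicon, entry, key = rec$surface, shadow = TRUE)
    lexicon_insert(lexicon, entry, key = rec$expansion, shadow = TRUE)
  }
  invisible(lexicon)
}

#' Serialize a lexicon to TSV / read it back
#'
#' The on-disk form has columns `term`, `cuis`, `semtypes`, `source`,
#' `preferred_label` (lists semicolon-joined), one row per (term, entry) pair,
#' terms sorted, entries in stored (shadow-first) order. A write/read
#' round-trip reproduces the lexicon.
#'
#' @param lexicon an `rt_lexicon`.
#' @param path output / input TSV path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` returns an
#'   `rt_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- lexicon_to_df(lexicon)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   quote = "", fileEncoding = "UTF-8")
  lexicon <- new_lexicon()
  split_field <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)[[1]]
    out[nzchar(out)]
  }
  for (i in seq_len(nrow(df))) {
    entry <- concept_entry(
      df$preferred_label[i], cuis = split_field(df$cuis[i]),
      semtypes = split_field(df$semtypes[i]), source = df$source[i],
      preferred_label = df$preferred_label[i]
    )
    entry$term <- norm_term(df$preferred_label[i])
    lexicon_insert(lexicon, entry, key = df$term[i], shadow = FALSE)
  }
  lexicon
}

# Flat data.frame view (used for serialization and equality checks).
lexicon_to_df <- function(lexicon) {
  terms <- lexicon_terms(lexicon)
  rows <- list()
  for (tm in terms) {
    for (e in lexicon_lookup(lexicon, tm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = tm,
        cuis = paste(e$cuis, collapse = ";"),
        semtypes = paste(e$semtypes, collapse = ";"),
        source = e$source,
        preferred_label = e$preferred_label,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(term = character(), cuis = character(),
                      semtypes = character(), source = character(),
                      preferred_label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.rt_lexicon <- function(x, ...) {
  cat("<rt_lexicon> ", length(ls(x$entries)), " terms, ",
      length(ls(x$vocab)), " vocabulary tokens\n", sep = "")
  invisible(x)
}

#' @export
print.rt_concept_entry <- function(x, ...) {
  cat(sprintf("%s [%s:%s] <%s>\n", x$preferred_label,
              paste(x$cuis, collapse = ","),
              paste(x$semtypes, collapse = ","), x$source))
  invisible(x)
}
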