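# Shared fixtures built in code.

fixture_env <- new.env(parent = emptyenv())

get_fixture_lexicon <- function() {
  if (is.null(fixture_env$lex)) fixture_env$lex <- build_fixture_lexicon()
  fixture_env$lex
}

get_fixture_model <- function() {
  if (is.null(fixture_env$model)) {
    fixture_env$model <- train_bigrams(
      lexicon_token_sequences(get_fixture_lexicon())
    )
  }
  fixture_env$model
}

get_fixture_config <- function() {
  if (is.null(fixture_env$cfg)) {
    fixture_env$cfg <- resolver_config(english_words = fixture_english_words())
  }
  fixture_env$cfg
}

# A tiny lexicon with known structure, built from scratch.
tiny_lexicon <- function(terms = c("left breast", "chest wall", "left",
                                   "breast", "wall")) {
  lex <- new_lexicon()
  for (i in seq_along(terms)) {
    lexicon_insert(lex, concept_entry(
      terms[i], cuis = sprintf("C%07d", i), semtypes = "T023",
      source = "umls_subset", preferred_label = terms[i]
    ))
  }
  lex
}

# Write a minimal pipe-delimited concept source; rows are "string|CUI" and
# "CUI|semtype" character vectors.
write_concept_source <- function(concept_rows, semtype_rows,
                                 dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pc <- file.path(dir, "concepts.psv")
  ps <- file.path(dir, "semtypes.psv")
  writeLines(concept_rows, pc)
  writeLines(semtype_rows, ps)
  list(concepts = pc, semtypes = ps)
}

write_supplement_file <- function(rows,
                                  path = withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())) {
  writeLines(c("surface\texpansion\tcuis\tsemtypes", rows), path)
  path
}

# Annotate the corrupted side of synthetic cases and score them against the
# frozen expected annotations of their canonicals.
eval_synthetic <- function(cases, lexicon = get_fixture_lexicon(),
                           model = get_fixture_model(),
                           config = get_fixture_config()) {
  preds <- annotate_corpus(vapply(cases, `[[`, "", "corrupted"),
                           lexicon, model, config)
  golds <- lapply(cases, function(cs) {
    list(raw = cs$corrupted,
         concepts = parse_bracket_concept(site_concept_strings(cs$expected)))
  })
  evaluate_corpus(preds, golds)
}

# Random token-level corruption used by resolver recovery tests: one random
# single-character edit over lowercase letters.
one_edit <- function(word) {
  type <- sample(c("sub", "ins", "del"), 1)
  if (type == "del" && nchar(word) <= 1) type <- "sub"
  pos <- sample.int(nchar(word) + (type == "ins"), 1)
  switch(type,
    sub = paste0(substr(word, 1, pos - 1), sample(letters, 1),
                 substr(word, pos + 1, nchar(word))),
    ins = paste0(substr(word, 1, pos - 1), sample(letters, 1),
                 substr(word, pos, nchar(word))),
    del = paste0(substr(word, 1, pos - 1), substr(word, pos + 1, nchar(word)))
  )
}
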