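test_that("read_concept_source admits strings by semantic-type filter", {
  paths <- write_concept_source(
    c("Pelvis|C0030797", "Heart|C0018787"),
    c("C0030797|T023", "C0018787|T047")
  )
  lex <- read_concept_source(paths$concepts, paths$semtypes, "T023")
  expect_identical(lexicon_terms(lex), "pelvis")
  e <- lexicon_lookup(lex, "PELVIS")[[1]]
  expect_identical(e$cuis, "C0030797")
  expect_identical(e$semtypes, "T023")
  expect_null(lexicon_lookup(lex, "heart"))
})

test_that("an empty concept file yields an empty lexicon without error", {
  paths <- write_concept_source(character(), "C1|T023")
  lex <- read_concept_source(paths$concepts, paths$semtypes, "T023")
  expect_length(lexicon_terms(lex), 0L)
})

test_that("only admitted semantic types are attached to admitted strings", {
  strings <- c("alpha", "beta", "gamma", "delta", "epsilon")
  paths <- write_concept_source(
    paste0(strings, "|C0000001"),
    c("C0000001|T023", "C0000001|T047")
  )
  lex <- read_concept_source(paths$concepts, paths$semtypes, "T023")
  # brute-force re-filter: a string is admitted iff its CUI has a filtered type
  expect_setequal(lexicon_terms(lex), strings)
  for (s in strings) {
    expect_identical(lexicon_lookup(lex, s)[[1]]$semtypes, "T023")
  }
})

test_that("malformed concept rows are skipped with a warning", {
  paths <- write_concept_source(
    c("Pelvis|C1", "nocui", "|C2", "Spine|C1"),
    c("C1|T023")
  )
  expect_warning(
    lex <- read_concept_source(paths$concepts, paths$semtypes, "T023"),
    "malformed"
  )
  expect_setequal(lexicon_terms(lex), c("pelvis", "spine"))
})

test_that("strings sharing a normalized term merge into one entry", {
  paths <- write_concept_source(
    c("Whole Brain|C1", "whole  brain|C2", "WHOLE BRAIN|C1"),
    c("C1|T023", "C2|T029")
  )
  lex <- read_concept_source(paths$concepts, paths$semtypes, c("T023", "T029"))
  entries <- lexicon_lookup(lex, "whole brain")
  expect_length(entries, 1L)
  expect_identical(entries[[1]]$cuis, c("C1", "C2"))
  expect_identical(entries[[1]]$semtypes, c("T023", "T029"))
  expect_identical(entries[[1]]$preferred_label, "Whole Brain")
})

test_that("filter soundness holds against a brute-force line scan", {
  withr::local_seed(13)
  types <- sprintf("T%03d", 20:29)
  for (rep in 1:20) {
    n_cui <- sample(3:8, 1)
    cuis <- sprintf("C%07d", seq_len(n_cui))
    sem_rows <- unlist(lapply(cuis, function(cu) {
      paste0(cu, "|", sample(types, sample.int(3, 1)))
    }))
    n_str <- sample(5:15, 1)
    con_rows <- paste0(
      replicate(n_str, paste(sample(letters, 5, replace = TRUE),
                             collapse = "")),
      "|", sample(cuis, n_str, replace = TRUE)
    )
    filt <- sample(types, 3)
    paths <- write_concept_source(con_rows, sem_rows)
    lex <- read_concept_source(paths$concepts, paths$semtypes, filt)
    # oracle: line scan of the two files
    sem_map <- list()
    for (r in sem_rows) {
      p <- strsplit(r, "|", fixed = TRUE)[[1]]
      sem_map[[p[1]]] <- c(sem_map[[p[1]]], p[2])
    }
    expected_terms <- character()
    for (r in con_rows) {
      p <- strsplit(r, "|", fixed = TRUE)[[1]]
      if (any(sem_map[[p[2]]] %in% filt)) {
        expected_terms <- c(expected_terms, norm_term(p[1]))
      }
    }
    expect_setequal(lexicon_terms(lex), unique(expected_terms))
    for (tm in lexicon_terms(lex)) {
      expect_true(any(lexicon_lookup(lex, tm)[[1]]$semtypes %in% filt))
    }
  }
})

test_that("load_supplement parses, collapses and rejects rows as specified", {
  p <- write_supplement_file(c(
    "WBRT\twhole-brain radiotherapy\tC1520143\tT061",
    "MLB\tmidline block\t\tT169",
    "WBRT\twhole-brain radiotherapy\tC1520143\tT061"
  ))
  recs <- load_supplement(p)
  expect_length(recs, 2L) # identical duplicate collapsed
  expect_identical(recs[[1]]$cuis, "C1520143")
  expect_identical(recs[[2]]$cuis, character(0))
  expect_identical(recs[[2]]$semtypes, "T169")

  expect_length(load_supplement(write_supplement_file(character())), 0L)

  expect_error(
    load_supplement(write_supplement_file(
      c("X\ta\tC1\tT061", "X\tb\tC1\tT061")
    )),
    "conflicting duplicate"
  )
  expect_error(
    load_supplement(write_supplement_file("X\ta\tC1\t")),
    "blank semtypes"
  )
})

test_that("merge_supplement keys both surface and expansion to one entry", {
  lex <- tiny_lexicon(terms = "supraclavicular region")
  recs <- load_supplement(write_supplement_file(
    "SCV\tsupraclavicular region\tC0446461\tT029"
  ))
  merge_supplement(lex, recs)
  by_surface <- lexicon_lookup(lex, "scv")
  by_expansion <- lexicon_lookup(lex, "Supraclavicular  Region")
  expect_identical(by_surface[[1]]$cuis, "C0446461")
  expect_identical(by_surface[[1]], by_expansion[[1]])
  # supplement shadows the pre-existing entry on collision
  expect_identical(by_expansion[[1]]$source, "supplement")
  expect_length(by_expansion, 2L)
  expect_identical(by_expansion[[2]]$source, "umls_subset")

  empty <- new_lexicon()
  merge_supplement(empty, recs)
  expect_setequal(lexicon_terms(empty), c("scv", "supraclavicular region"))
})

test_that("a lexicon survives a serialization round-trip", {
  lex <- get_fixture_lexicon()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  lex2 <- read_lexicon(path)
  expect_identical(rtsites:::lexicon_to_df(lex2), rtsites:::lexicon_to_df(lex))
  expect_identical(lexicon_vocab(lex2), lexicon_vocab(lex))
})

test_that("the built-in lexicon answers the documented lookups", {
  lex <- get_fixture_lexicon()
  e <- lexicon_lookup(lex, "pelvis")[[1]]
  expect_identical(e$cuis, c("C0030797", "C0559769", "C0030786", "C1279864"))
  expect_identical(e$semtypes, c("T023", "T029", "T030"))
  w <- lexicon_lookup(lex, "wbrt")[[1]]
  expect_identical(w$cuis, "C1520143")
  expect_identical(w$semtypes, "T061")
  expect_null(lexicon_lookup(lex, "zzz"))
  # every abbreviation surface resolves
  for (s in c("SCV", "SCL", "S/C", "SC", "S Clav", "Sc V", "Sclav", "SCLV",
              "WBRT", "wbxrt", "MLB", "Prox", "SV", "PCI", "RT")) {
    expect_false(is.null(lexicon_lookup(lex, s)), label = s)
  }
})

test_that("every concept of the reference table is retrievable by surface", {
  lex <- get_fixture_lexicon()
  ref <- fixture_top_sites()
  cells <- unlist(strsplit(ref$concepts, ";", fixed = TRUE))
  for (co in parse_bracket_concept(trimws(cells))) {
    if (co$kind != "concept") next
    hits <- lexicon_lookup(lex, co$label)
    expect_false(is.null(hits), label = co$label)
    expect_true(any(vapply(hits, function(e) {
      setequal(e$cuis, co$cuis) && setequal(e$semtypes, co$semtypes)
    }, logical(1))), label = co$label)
  }
})

test_that("invalid concept entries are rejected", {
  expect_error(concept_entry("x", "C1", character(), "umls_subset"),
               "semtypes")
  expect_error(concept_entry("x", "C1", "X023", "umls_subset"), "semtypes")
  expect_error(concept_entry("x", character(), "T023", "umls_subset"),
               "supplement")
  expect_silent(concept_entry("x", character(), "T169", "supplement"))
})
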