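#' Built-in demonstration lexicon
#'
#' Returns the self-contained lexicon shipped with the package: the coded
#' concepts behind the most frequent treatment-site labels of a radiation
#' oncology department (pelvis, supraclavicular region, whole/brain, tumor bed
#' boost, breast and chest-wall laterality terms, prostate, proximal seminal
#' vesicles, midline block, whole-brain radiotherapy), merged with the bundled
#' supplement of abbreviation surfaces (SCV, SCL, S/C, SC, S Clav, Sc V,
#' Sclav, SCLV, WBRT, wbxrt, MLB, Prox, SV, PCI, RT). It makes the whole
#' pipeline runnable without access to a licensed concept source.
#'
#' @return an `rt_lexicon`.
#' @export
#' @examples
#' lex <- build_fixture_lexicon()
#' lexicon_lookup(lex, "WBRT")
build_fixture_lexicon <- function() {
  lexicon <- new_lexicon(c("T023", "T029", "T030", "T082"))
  add <- function(label, cuis, semtypes) {
    lexicon_insert(lexicon, concept_entry(
      label, cuis = cuis, semtypes = semtypes,
      source = "umls_subset", preferred_label = label
    ))
  }
  add("pelvis", c("C0030797", "C0559769", "C0030786", "C1279864"),
      c("T023", "T029", "T030"))
  add("whole", "C0444667", "T081")
  add("brain", c("C0006104", "C1269537", "C1882598", "C1273723"),
      c("T023", "T029"))
  add("tumor", c("C0027651", "C3273930", "C1578706"),
      c("T191", "T170", "T033"))
  add("bed", "C1547114", "T082")
  add("Boost", "C1511253", "T169")
  add("Left Breast", "C0222601", "T023")
  add("right", "C0205090", "T082")
  add("Chest wall", "C0205076", "T023")
  add("Right Breast", "C0222600", "T023")
  add("Left", "C0205091", "T082")
  add("Prostate", c("C0033572", "C1278980", "C1882832"), "T023")
  add("Proximal", "C0205107", "T082")
  add("Seminal Vesicle", "C1278984", "T023")
  merge_supplement(lexicon, load_supplement(
    system.file("extdata", "supplement.tsv", package = "rtsites")
  ))
  lexicon
}

#' Bundled reference tables and wordlist
#'
#' `fixture_top_sites()` returns the package's reference table of the most
#' frequent site labels with their usage counts and expected concept
#' annotations (bracket style, semicolon-joined). `fixture_whole_brain_variants()`
#' returns the 27 observed spellings of whole-brain treatment with counts.
#' `fixture_corpus_summary()` returns the size of the corpus those tables were
#' drawn from (31118 site entries, 11018 unique labels).
#' `fixture_english_words()` returns a small general-English wordlist of
#' filler words seen in site labels.
#'
#' @return a data.frame with columns site, count and optionally concepts; a list; or a
#'   character vector respectively.
#' @export
fixture_top_sites <- function() {
  read.delim(system.file("extdata", "top_sites.tsv", package = "rtsites"),
             sep = "\t", colClasses = "character", quote = "",
             fileEncoding = "UTF-8") -> df
  df$count <- as.integer(df$count)
  df
}

#' @rdname fixture_top_sites
#' @export
fixture_whole_brain_variants <- function() {
  df <- read.delim(
    system.file("extdata", "whole_brain_variants.tsv", package = "rtsites"),
    sep = "\t", colClasses = "character", quote = "", fileEncoding = "UTF-8"
  )
  df$count <- as.integer(df$count)
  df
}

#' @rdname fixture_top_sites
#' @export
fixture_corpus_summary <- function() {
  list(n_site_entries = 31118L, n_unique_sites = 11018L,
       mean_sites_per_patient = 2.2)
}

#' @rdname fixture_top_sites
#' @export
fixture_english_words <- function() {
  readLines(system.file("extdata", "english_words.txt", package = "rtsites"),
            warn = FALSE, encoding = "UTF-8")
}

#' Default canonical site names for synthetic corpora
#'
#' Clean, fully mappable site labels covering the concepts of the built-in
#' lexicon; the synthetic generator corrupts these.
#'
#' @return character vector.
#' @export
default_canonical_sites <- function() {
  c("pelvis", "supraclavicular region", "whole brain", "tumor bed boost",
    "left breast", "right breast", "right chest wall", "left chest wall",
    "boost", "prostate", "seminal vesicle", "midline block",
    "whole-brain radiotherapy")
}

#' Check annotations against the bundled reference table
#'
#' Annotates each reference site label and compares the result with the
#' stored expected annotation. Bracket payloads (CUI list and semantic-type
#' list) must match byte-for-byte; display labels are compared
#' case-insensitively because the reference table itself capitalizes the same
#' concept differently across rows. Punctuation annotations are compared only
#' for rows whose reference annotation prints one.
#'
#' @param lexicon an `rt_lexicon`; defaults to [build_fixture_lexicon()].
#' @param reference a data.frame as from [fixture_top_sites()].
#' @param model optional pre-trained [train_bigrams()] model.
#' @param config resolver configuration, see [resolver_config()].
#' @return logical vector, one element per reference row, named by site.
#' @export
check_reference_sites <- function(lexicon = build_fixture_lexicon(),
                                  reference = fixture_top_sites(),
                                  model = NULL,
                                  config = resolver_config()) {
  if (is.null(model)) {
    model <- train_bigrams(lexicon_token_sequences(lexicon))
  }
  norm_cell <- function(cell) {
    # "label [payload]" -> "lowercased-label [payload]"
    sub("^(.*?)(\\s*\\[[^]]*\\])$", "\\L\\1\\E\\2", cell, perl = TRUE)
  }
  ok <- logical(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    expected <- trimws(strsplit(reference$concepts[i], ";", fixed = TRUE)[[1]])
    sa <- annotate_site(reference$site[i], lexicon, model, config)
    has_punc <- any(grepl("[PUNC:T000]", expected, fixed = TRUE))
    kinds <- if (has_punc) c("concept", "punctuation") else "concept"
    got <- site_concept_strings(sa, kinds = kinds)
    exp_cmp <- if (has_punc) expected else {
      expected[!grepl("[PUNC:T000]", expected, fixed = TRUE)]
    }
    ok[i] <- identical(norm_cell(got), norm_cell(exp_cmp))
  }
  names(ok) <- reference$site
  ok
}
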