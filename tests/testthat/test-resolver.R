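test_that("levenshtein handles the documented cases", {
  expect_identical(levenshtein("scv", "scv"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  expect_identical(levenshtein("abc", ""), 3L)
  expect_identical(levenshtein("sclv", "sclav"), 1L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein(c("a", "ab"), "abc"), c(2L, 1L))
  expect_true(is.na(levenshtein(NA_character_, "a")))
})

test_that("levenshtein equals a recursive oracle on all short pairs", {
  strings <- all_strings(c("a", "b", "c"), 3)
  grid <- expand.grid(a = strings, b = strings, stringsAsFactors = FALSE)
  got <- levenshtein(grid$a, grid$b)
  want <- mapply(lev_oracle, grid$a, grid$b, USE.NAMES = FALSE)
  expect_identical(got, as.integer(want))
})

test_that("levenshtein is symmetric, zero iff equal, and triangular", {
  withr::local_seed(17)
  rand <- replicate(60, paste(sample(letters[1:4], sample.int(8, 1),
                                     replace = TRUE), collapse = ""))
  a <- sample(rand, 200, replace = TRUE)
  b <- sample(rand, 200, replace = TRUE)
  c_ <- sample(rand, 200, replace = TRUE)
  expect_identical(levenshtein(a, b), levenshtein(b, a))
  expect_identical(levenshtein(a, b) == 0L, a == b)
  expect_true(all(levenshtein(a, c_) <= levenshtein(a, b) + levenshtein(b, c_)))
})

test_that("train_bigrams counts adjacent pairs and unigrams", {
  m <- train_bigrams(list(c("whole", "brain")))
  expect_identical(m$next_counts[["whole"]][["brain"]], 1L)
  expect_identical(m$prev_counts[["brain"]][["whole"]], 1L)
  expect_identical(m$unigrams[["whole"]], 1L)
  expect_identical(m$next_counts[["whole"]][["brain"]] /
                     m$unigrams[["whole"]], 1)

  empty <- train_bigrams(list())
  expect_length(empty$unigrams, 0L)
  expect_length(empty$next_counts, 0L)
})

test_that("bigram counts over the reference site names match a hand tally", {
  sites <- fixture_top_sites()$site
  seqs <- lapply(sites, function(s) {
    tk <- tokenize(s)
    tk$norm[tk$kind != "punct"]
  })
  m <- train_bigrams(seqs)
  # oracle: naive nested-loop tally
  `%||%` <- function(a, b) if (is.null(a)) b else a
  uni <- list(); nxt <- list()
  for (sq in seqs) {
    for (t in sq) uni[[t]] <- (uni[[t]] %||% 0L) + 1L
    if (length(sq) >= 2) {
      for (i in seq_len(length(sq) - 1)) {
        key <- paste(sq[i], sq[i + 1], sep = " ")
        nxt[[key]] <- (nxt[[key]] %||% 0L) + 1L
      }
    }
  }
  for (t in names(uni)) {
    expect_identical(m$unigrams[[t]], uni[[t]], label = t)
  }
  for (key in names(nxt)) {
    p <- strsplit(key, " ", fixed = TRUE)[[1]]
    expect_identical(m$next_counts[[p[1]]][[p[2]]], nxt[[key]], label = key)
  }
  # a token has at most one successor per occurrence
  for (t in names(m$next_counts)) {
    expect_lte(sum(m$next_counts[[t]]), m$unigrams[[t]])
  }
})

test_that("generate_candidates uses context, then the global fallback", {
  m <- train_bigrams(list(c("whole", "brain")))
  cand <- generate_candidates("brian", left = "whole", model = m,
                              vocab = c("whole", "brain"))
  expect_identical(cand$word, "brain")
  expect_identical(cand$distance, 2L)
  expect_identical(cand$context_prob, 1)
  expect_identical(cand$origin, "left_context")

  cand2 <- generate_candidates("brian", right = "brain", model = m,
                               vocab = c("whole", "brain"))
  expect_identical(cand2$word, "whole")
  expect_identical(cand2$origin, "right_context")

  # no context, empty model -> global fallback over the vocabulary
  cand3 <- generate_candidates("brian", model = train_bigrams(list()),
                               vocab = "brain")
  expect_identical(cand3$origin, "global")
  expect_identical(cand3$word, "brain")

  # empty vocabulary -> empty candidate list
  expect_identical(nrow(generate_candidates("x", model = m,
                                            vocab = character())), 0L)
})

test_that("resolve_token selects by distance, then probability, then order", {
  # distance dominates probability
  m <- train_bigrams(c(replicate(9, c("ctx", "brain"), simplify = FALSE),
                       list(c("ctx", "supraclavicular"))))
  res <- resolve_token("brian", left = "ctx", model = m,
                       vocab = c("brain", "supraclavicular"),
                       config = resolver_config(max_distance = 4))
  expect_identical(res$status, "fuzzy")
  expect_identical(res$resolved_word, "brain")

  # equal distance: higher conditional probability wins
  m2 <- train_bigrams(c(replicate(9, c("ctx", "bed"), simplify = FALSE),
                        list(c("ctx", "bad"))))
  res2 <- resolve_token("bd", left = "ctx", model = m2,
                        vocab = c("bed", "bad"))
  expect_identical(res2$resolved_word, "bed")

  # equal distance and probability: lexicographic word order
  m3 <- train_bigrams(list(c("ctx", "bed"), c("ctx", "bad")))
  res3 <- resolve_token("bd", left = "ctx", model = m3,
                        vocab = c("bed", "bad"))
  expect_identical(res3$resolved_word, "bad")

  # probability-first ranking is available as a config switch
  res4 <- resolve_token("bde", left = "ctx", model = m2,
                        vocab = c("bed", "bad"),
                        config = resolver_config(
                          max_distance = 3, rank_order = "probability_first"
                        ))
  expect_identical(res4$resolved_word, "bed")

  # nothing within threshold -> unresolved
  res5 <- resolve_token("zzzzzz", left = "ctx", model = m,
                        vocab = c("brain", "supraclavicular"),
                        config = resolver_config(max_distance = 1))
  expect_identical(res5$status, "unresolved")
  expect_null(res5$resolved_word)

  expect_identical(
    resolve_token("x", model = m, vocab = character())$status,
    "unresolved"
  )
})

test_that("a zero-distance candidate always ranks first", {
  m <- get_fixture_model()
  vocab <- lexicon_vocab(get_fixture_lexicon(), words_only = TRUE)
  res <- resolve_token("breast", left = "left", model = m, vocab = vocab)
  expect_identical(res$resolved_word, "breast")
  expect_identical(res$candidate$distance, 0L)
})

test_that("resolution is deterministic", {
  m <- get_fixture_model()
  vocab <- lexicon_vocab(get_fixture_lexicon(), words_only = TRUE)
  r1 <- resolve_token("brest", left = "left", model = m, vocab = vocab)
  for (i in 1:5) {
    expect_identical(resolve_token("brest", left = "left", model = m,
                                   vocab = vocab), r1)
  }
})

test_that("one-edit corruptions recover their canonical token in context", {
  withr::local_seed(23)
  m <- get_fixture_model()
  vocab <- lexicon_vocab(get_fixture_lexicon(), words_only = TRUE)
  hits <- 0L; total <- 0L
  for (rep in 1:100) {
    corrupted <- one_edit("breast")
    res <- resolve_token(corrupted, left = "left", model = m, vocab = vocab)
    # in-context candidates after "left" are breast and chest
    d_breast <- levenshtein(corrupted, "breast")
    d_chest <- levenshtein(corrupted, "chest")
    total <- total + 1L
    if (d_breast < d_chest) {
      expect_identical(res$resolved_word, "breast", label = corrupted)
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 80L) # almost all single edits keep breast strictly closer
})
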