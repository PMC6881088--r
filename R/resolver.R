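#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b`. Vectorized with recycling of the shorter
#' argument; computed in C with a two-row dynamic programme.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
#' @examples
#' levenshtein("sclv", "sclav")
levenshtein <- function(a, b) {
  .Call(C_levenshtein, as.character(a), as.character(b))
}

#' Resolver configuration
#'
#' @param max_distance `"auto"` (per-candidate threshold
#'   `max(1, floor(nchar(candidate)/3))`: tolerates one edit on short
#'   abbreviations and scales for long words) or a fixed non-negative integer.
#' @param rank_order `"distance_first"` (closest word wins, bigram probability
#'   breaks ties) or `"probability_first"` (most probable word wins, distance
#'   breaks ties). The phrase "closest word having the highest probability"
#'   admits both readings; distance-first is the default because it preserves
#'   "closest" as the primary criterion.
#' @param english_words character vector used as the general-English fallback
#'   dictionary; words found there are accepted as known but produce no
#'   concept unless they are also lexicon tokens.
#' @return a list of class `rt_resolver_config`.
#' @export
resolver_config <- function(max_distance = "auto",
                            rank_order = c("distance_first", "probability_first"),
                            english_words = character()) {
  rank_order <- match.arg(rank_order)
  if (!identical(max_distance, "auto")) {
    max_distance <- as.integer(max_distance)
    stopifnot(length(max_distance) == 1L, !is.na(max_distance),
              max_distance >= 0L)
  }
  structure(
    list(max_distance = max_distance, rank_order = rank_order,
         english_words = tolower(as.character(english_words))),
    class = "rt_resolver_config"
  )
}

#' Train a bigram model over token sequences
#'
#' Counts every adjacent ordered token pair once per occurrence, along with
#' unigram counts. The model supplies in-context candidate words during
#' abbreviation resolution: tokens observed after a left neighbour or before a
#' right neighbour.
#'
#' @param sequences list of character vectors (token sequences); typically
#'   [lexicon_token_sequences()], optionally extended with tokenized
#'   development-set site names.
#' @return object of class `rt_bigrams` with elements `next_counts` /
#'   `prev_counts` (named lists of named integer count vectors), `unigrams`
#'   (named integer vector) and `total`.
#' @export
train_bigrams <- function(sequences) {
  stopifnot(is.list(sequences))
  sequences <- lapply(sequences, as.character)
  all_tokens <- unlist(sequences, use.names = FALSE)
  uni <- if (length(all_tokens)) {
    tab <- table(all_tokens)
    setNames(as.integer(tab), names(tab))
  } else {
    integer()
  }
  lefts <- character(); rights <- character()
  for (s in sequences) {
    if (length(s) >= 2L) {
      lefts <- c(lefts, s[-length(s)])
      rights <- c(rights, s[-1L])
    }
  }
  next_counts <- list(); prev_counts <- list()
  if (length(lefts)) {
    pair_tab <- table(paste(lefts, rights, sep = "\x1f"))
    pl <- strsplit(names(pair_tab), "\x1f", fixed = TRUE)
    l <- vapply(pl, `[`, "", 1L)
    r <- vapply(pl, `[`, "", 2L)
    cnt <- as.integer(pair_tab)
    next_counts <- lapply(split(seq_along(cnt), l),
                          function(ix) setNames(cnt[ix], r[ix]))
    prev_counts <- lapply(split(seq_along(cnt), r),
                          function(ix) setNames(cnt[ix], l[ix]))
  }
  structure(
    list(next_counts = next_counts, prev_counts = prev_counts,
         unigrams = uni, total = sum(uni)),
    class = "rt_bigrams"
  )
}

#' Generate fuzzy-resolution candidates for an unknown token
#'
#' Candidates are the vocabulary tokens observed after the resolved left
#' neighbour (origin `left_context`) united with those observed before the
#' resolved right neighbour (origin `right_context`). If both contexts are
#' absent, or neither yields a candidate, the full token vocabulary is the
#' fallback (origin `global`). Each candidate carries its Levenshtein distance
#' to the unknown token and a context probability: the conditional bigram
#' probability `count(left, w)/count(left)` (resp. `count(w, right)/count(right)`),
#' or the unigram relative frequency for the global fallback. A candidate
#' reachable from both contexts keeps its higher probability.
#'
#' @param unknown lowercased unknown token.
#' @param left,right resolved adjacent words, or `NULL` when absent.
#' @param model an `rt_bigrams` model.
#' @param vocab character vector of candidate vocabulary tokens.
#' @return data.frame with columns `word`, `distance`, `context_prob`,
#'   `origin`; zero rows when the vocabulary is empty.
#' @export
generate_candidates <- function(unknown, left = NULL, right = NULL, model,
                                vocab) {
  stopifnot(inherits(model, "rt_bigrams"))
  vocab <- as.character(vocab)
  empty <- data.frame(word = character(), distance = integer(),
                      context_prob = double(), origin = character(),
                      stringsAsFactors = FALSE)
  if (length(vocab) == 0L) {
    return(empty)
  }
  words <- character(); probs <- double(); origins <- character()
  if (!is.null(left) && !is.null(model$next_counts[[left]])) {
    nc <- model$next_counts[[left]]
    w <- intersect(names(nc), vocab)
    if (length(w)) {
      words <- c(words, w)
      probs <- c(probs, unname(nc[w]) / model$unigrams[[left]])
      origins <- c(origins, rep("left_context", length(w)))
    }
  }
  if (!is.null(right) && !is.null(model$prev_counts[[right]])) {
    pc <- model$prev_counts[[right]]
    w <- intersect(names(pc), vocab)
    if (length(w)) {
      words <- c(words, w)
      probs <- c(probs, unname(pc[w]) / model$unigrams[[right]])
      origins <- c(origins, rep("right_context", length(w)))
    }
  }
  if (length(words)) {
    # union of both contexts; keep the higher-probability duplicate
    ord <- order(words, -probs)
    words <- words[ord]; probs <- probs[ord]; origins <- origins[ord]
    keep <- !duplicated(words)
    words <- words[keep]; probs <- probs[keep]; origins <- origins[keep]
  } else {
    words <- vocab
    u <- model$unigrams[words]
    u[is.na(u)] <- 0L
    probs <- if (model$total > 0) unname(u) / model$total else rep(0, length(words))
    origins <- rep("global", length(words))
  }
  data.frame(
    word = words,
    distance = levenshtein(unknown, words),
    context_prob = probs,
    origin = origins,
    stringsAsFactors = FALSE
  )
}

#' Resolve an unknown token against the vocabulary
#'
#' Applies the distance threshold from `config`, then selects the minimum
#' distance candidate; ties are broken by maximum context probability, then
#' lexicographic word order (with `rank_order = "probability_first"` the first
#' two criteria swap). When no candidate qualifies the token stays
#' unresolved — a value, not an error.
#'
#' @inheritParams generate_candidates
#' @param config an [resolver_config()].
#' @return list of class `rt_resolution` with `status` (`"fuzzy"` or
#'   `"unresolved"`), and for fuzzy resolutions `resolved_word` and the
#'   winning `candidate` row.
#' @export
resolve_token <- function(unknown, left = NULL, right = NULL, model, vocab,
                          config = resolver_config()) {
  cands <- generate_candidates(unknown, left, right, model, vocab)
  if (nrow(cands)) {
    thr <- if (identical(config$max_distance, "auto")) {
      pmax(1L, as.integer(floor(nchar(cands$word) / 3)))
    } else {
      config$max_distance
    }
    cands <- cands[cands$distance <= thr, , drop = FALSE]
  }
  if (nrow(cands) == 0L) {
    return(structure(list(status = "unresolved"), class = "rt_resolution"))
  }
  ord <- if (config$rank_order == "distance_first") {
    order(cands$distance, -cands$context_prob, cands$word)
  } else {
    order(-cands$context_prob, cands$distance, cands$word)
  }
  best <- cands[ord[1L], , drop = FALSE]
  structure(
    list(status = "fuzzy", resolved_word = best$word,
         candidate = best),
    class = "rt_resolution"
  )
}
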