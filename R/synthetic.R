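# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Corruption configuration for synthetic site names
#'
#' Per-operation probabilities for the noise patterns observed in real
#' treatment-site entry: case mangling ("WHOLE BRAIN", "WHole Brain"),
#' substitution of a concept by one of its curated abbreviation surfaces
#' ("supraclavicular region" -> "SCV"), random single-character edits
#' (typos such as "wbxrt"), appended decorations ("2", "#2", "PCI", "RT",
#' "Retreat", "photons") and separator swaps ("whole brain-2"). The default
#' mix roughly follows the proportions of those variant classes among the
#' observed whole-brain spellings.
#'
#' @param p_case probability of mangling letter case.
#' @param p_abbrev probability of replacing one annotated concept with a
#'   known abbreviation surface.
#' @param p_edit per-word-token probability of random character edits.
#' @param max_edits maximum number of character edits per edited token.
#' @param p_decor probability of appending a decoration.
#' @param p_sep probability of swapping one space for `-` or `/`.
#' @param decorations candidate decoration strings.
#' @return list of class `rt_synth_config`.
#' @export
synth_config <- function(p_case = 0.4, p_abbrev = 0.15, p_edit = 0.05,
                         max_edits = 1L, p_decor = 0.3, p_sep = 0.1,
                         decorations = c("1", "2", "#1", "#2", "PCI", "RT",
                                         "Retreat", "photons")) {
  probs <- c(p_case, p_abbrev, p_edit, p_decor, p_sep)
  stopifnot(all(probs >= 0), all(probs <= 1), max_edits >= 1L)
  structure(
    list(p_case = p_case, p_abbrev = p_abbrev, p_edit = p_edit,
         max_edits = as.integer(max_edits), p_decor = p_decor, p_sep = p_sep,
         decorations = decorations),
    class = "rt_synth_config"
  )
}

# Apply a single recorded corruption operation; deterministic, so replaying
# the op log reproduces the corrupted string exactly.
apply_corruption_op <- function(s, op) {
  switch(op$op,
    abbrev = {
      pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1",
                                op$pattern), "\\b")
      sub(pat, op$replacement, s, ignore.case = TRUE)
    },
    sep = {
      # replace the op$which-th space with op$char
      pos <- gregexpr(" ", s, fixed = TRUE)[[1]]
      if (pos[1L] == -1L || length(pos) < op$which) return(s)
      p <- pos[op$which]
      paste0(substr(s, 1L, p - 1L), op$char, substr(s, p + 1L, nchar(s)))
    },
    edit = {
      toks <- tokenize(s)
      if (op$token > nrow(toks)) return(s)
      w <- toks$text[op$token]
      pos <- min(op$pos, nchar(w) + (op$type == "ins"))
      w2 <- switch(op$type,
        sub = paste0(substr(w, 1L, pos - 1L), op$char,
                     substr(w, pos + 1L, nchar(w))),
        ins = paste0(substr(w, 1L, pos - 1L), op$char,
                     substr(w, pos, nchar(w))),
        del = paste0(substr(w, 1L, pos - 1L), substr(w, pos + 1L, nchar(w)))
      )
      paste0(substr(s, 1L, toks$start[op$token] - 1L), w2,
             substr(s, toks$end[op$token] + 1L, nchar(s)))
    },
    decor = paste(s, op$text),
    case = switch(op$style,
      upper = toupper(s),
      lower = tolower(s),
      title = gsub("\\b([a-z])", "\\U\\1", tolower(s), perl = TRUE)
    ),
    stop("unknown corruption op: ", op$op)
  )
}

#' Replay a corruption log
#'
#' @param s canonical string.
#' @param ops list of operation records from [corrupt_site()].
#' @return the corrupted string.
#' @export
apply_corruption_ops <- function(s, ops) {
  for (op in ops) s <- apply_corruption_op(s, op)
  s
}

#' Corrupt one canonical site name
#'
#' Draws corruption operations under `config`, applies them in a fixed order
#' (abbreviation substitution, separator swap, character edits, decoration,
#' case mangling — case last so abbreviation surfaces get mangled too) and
#' records a complete, replayable operation log. Deterministic under
#' `(seed, config)`; all-zero probabilities return the canonical unchanged.
#'
#' Abbreviation substitution only replaces an expansion whose lookup key
#' equals a whole concept matched in the canonical's annotation, so the
#' corrupted string still denotes the same concept sequence.
#'
#' @param canonical clean site name (non-empty).
#' @param config an [synth_config()].
#' @param seed integer seed.
#' @param lexicon optional `rt_lexicon`; when supplied, the expected
#'   annotation of the canonical string is attached and drives the
#'   abbreviation substitution.
#' @param model optional pre-trained bigram model for the expected annotation.
#' @param abbreviations data.frame with columns `surface`, `expansion`
#'   (defaults to the bundled supplement).
#' @param expected a precomputed `rt_site_annotation` of `canonical`
#'   (overrides `lexicon`-based annotation; useful in loops).
#' @return object of class `rt_synthetic_case`: `canonical`, `corrupted`,
#'   `expected` (or `NULL`), `ops_applied`, `seed`.
#' @export
corrupt_site <- function(canonical, config = synth_config(), seed,
                         lexicon = NULL, model = NULL,
                         abbreviations = NULL, expected = NULL) {
  stopifnot(is.character(canonical), length(canonical) == 1L,
            nzchar(canonical))
  if (is.null(abbreviations)) {
    sup <- load_supplement(
      system.file("extdata", "supplement.tsv", package = "rtsites")
    )
    abbreviations <- data.frame(
      surface = vapply(sup, `[[`, "", "surface"),
      expansion = vapply(sup, `[[`, "", "expansion"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(expected) && !is.null(lexicon)) {
    expected <- annotate_site(canonical, lexicon, model)
  }
  concept_keys <- if (!is.null(expected)) {
    vapply(Filter(function(a) a$kind == "concept", expected$annotations),
           function(a) a$term, character(1))
  } else {
    character()
  }
  with_seed(seed, {
    ops <- list()
    s <- canonical
    push <- function(op) {
      ops[[length(ops) + 1L]] <<- op
      s <<- apply_corruption_op(s, op)
    }
    if (config$p_abbrev > 0 && stats::runif(1) < config$p_abbrev) {
      exp_keys <- vapply(abbreviations$expansion, term_key, character(1),
                         USE.NAMES = FALSE)
      eligible <- if (length(concept_keys)) {
        which(exp_keys %in% concept_keys)
      } else {
        # without an annotation, fall back to plain substring presence
        seq_len(nrow(abbreviations))
      }
      # substitute only expansions actually present in the string
      eligible <- eligible[vapply(eligible, function(i) {
        grepl(tolower(abbreviations$expansion[i]), tolower(s), fixed = TRUE)
      }, logical(1))]
      if (length(eligible)) {
        pick <- eligible[sample.int(length(eligible), 1L)]
        push(list(op = "abbrev",
                  pattern = abbreviations$expansion[pick],
                  replacement = abbreviations$surface[pick]))
      }
    }
    if (config$p_sep > 0 && stats::runif(1) < config$p_sep) {
      n_sp <- length(gregexpr(" ", s, fixed = TRUE)[[1]])
      if (substr(s, 1L, 1L) != " " && grepl(" ", s, fixed = TRUE)) {
        push(list(op = "sep",
                  which = sample.int(n_sp, 1L),
                  char = sample(c("-", "/"), 1L)))
      }
    }
    if (config$p_edit > 0) {
      toks <- tokenize(s)
      word_idx <- which(toks$kind == "word")
      for (ti in word_idx) {
        if (stats::runif(1) >= config$p_edit) next
        n_ed <- sample.int(config$max_edits, 1L)
        for (e in seq_len(n_ed)) {
          cur <- tokenize(s)
          if (ti > nrow(cur)) break
          w <- cur$text[ti]
          type <- sample(c("sub", "ins", "del"), 1L)
          if (type == "del" && nchar(w) <= 1L) type <- "sub"
          pos <- sample.int(nchar(w) + (type == "ins"), 1L)
          push(list(op = "edit", token = ti, type = type, pos = pos,
                    char = sample(letters, 1L)))
        }
      }
    }
    if (config$p_decor > 0 && stats::runif(1) < config$p_decor) {
      push(list(op = "decor", text = sample(config$decorations, 1L)))
    }
    if (config$p_case > 0 && stats::runif(1) < config$p_case) {
      push(list(op = "case", style = sample(c("upper", "lower", "title"), 1L)))
    }
    structure(
      list(canonical = canonical, corrupted = s, expected = expected,
           ops_applied = ops, seed = seed),
      class = "rt_synthetic_case"
    )
  })
}

#' Generate a labeled synthetic corpus
#'
#' Draws `n` canonical site names uniformly from `canonical_set`, corrupts
#' each independently and attaches the expected annotation computed from the
#' clean canonical string (so the gold labels are independent of any resolver
#' behaviour). Byte-reproducible under `(seed, config)`.
#'
#' @param canonical_set non-empty character vector of clean site names.
#' @param n number of cases (>= 1).
#' @param config an [synth_config()].
#' @param seed integer seed.
#' @param lexicon an `rt_lexicon` used for the expected annotations.
#' @param model optional pre-trained bigram model.
#' @return list of `rt_synthetic_case`.
#' @export
generate_corpus <- function(canonical_set, n, config = synth_config(), seed,
                            lexicon = build_fixture_lexicon(), model = NULL) {
  stopifnot(length(canonical_set) >= 1L, n >= 1L)
  if (is.null(model)) {
    model <- train_bigrams(lexicon_token_sequences(lexicon))
  }
  sup <- load_supplement(
    system.file("extdata", "supplement.tsv", package = "rtsites")
  )
  abbreviations <- data.frame(
    surface = vapply(sup, `[[`, "", "surface"),
    expansion = vapply(sup, `[[`, "", "expansion"),
    stringsAsFactors = FALSE
  )
  draws <- with_seed(seed, list(
    idx = sample.int(length(canonical_set), n, replace = TRUE),
    case_seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  expected_cache <- new.env(parent = emptyenv())
  lapply(seq_len(n), function(i) {
    canon <- canonical_set[draws$idx[i]]
    exp <- get0(canon, envir = expected_cache)
    if (is.null(exp)) {
      exp <- annotate_site(canon, lexicon, model)
      assign(canon, exp, envir = expected_cache)
    }
    corrupt_site(canon, config, draws$case_seeds[i],
                 abbreviations = abbreviations, expected = exp)
  })
}

#' Write a synthetic corpus, its gold file and a manifest
#'
#' The corpus TSV has columns `site`, `count` (all 1); the gold TSV has
#' columns `raw`, `gold` in the evaluation format; the optional manifest JSON
#' records the seed, configuration and per-case operation logs.
#'
#' @param cases list from [generate_corpus()].
#' @param corpus_path,gold_path,manifest_path output paths (`manifest_path`
#'   may be `NULL`).
#' @param seed,config recorded in the manifest.
#' @return invisibly, a list of the written paths.
#' @export
write_synthetic_corpus <- function(cases, corpus_path, gold_path,
                                   manifest_path = NULL, seed = NULL,
                                   config = NULL) {
  corrupted <- vapply(cases, `[[`, "", "corrupted")
  gold_cells <- vapply(cases, function(cs) {
    paste(site_concept_strings(cs$expected), collapse = ";")
  }, character(1))
  write.table(data.frame(site = corrupted, count = 1L),
              corpus_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(data.frame(raw = corrupted, gold = gold_cells),
              gold_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(manifest_path)) {
    manifest <- list(
      seed = seed,
      config = if (!is.null(config)) unclass(config),
      n = length(cases),
      cases = lapply(cases, function(cs) {
        list(canonical = cs$canonical, corrupted = cs$corrupted,
             seed = cs$seed, ops = cs$ops_applied)
      })
    )
    writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                             null = "null")),
               manifest_path)
  }
  invisible(list(corpus = corpus_path, gold = gold_path,
                 manifest = manifest_path))
}

#' @export
print.rt_synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic case> '%s' -> '%s' (%d op(s), seed %d)\n",
              x$canonical, x$corrupted, length(x$ops_applied), x$seed))
  invisible(x)
}
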