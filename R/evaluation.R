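#' Parse a bracket-style concept string
#'
#' Inverse of the display form `label [cui1,cui2:Ta,Tb]`; an empty CUI list
#' (`[:Ta]`) parses to a CUI-less concept, `[PUNC:T000]` to a punctuation
#' marker.
#'
#' @param x character vector of bracket-style cells.
#' @return list of concepts, each `list(label, cuis, semtypes, kind)`.
#' @export
parse_bracket_concept <- function(x) {
  lapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^(.*?)\\s*\\[([^]:]*):([^]]*)\\]$", s))[[1]]
    if (length(m) != 4L) {
      stop("not a bracket-style concept cell: '", s, "'")
    }
    split_list <- function(v) {
      out <- strsplit(v, ",", fixed = TRUE)[[1]]
      trimws(out[nzchar(trimws(out))])
    }
    cuis <- split_list(m[3L])
    kind <- if (identical(cuis, "PUNC")) "punctuation" else "concept"
    if (kind == "punctuation") cuis <- character()
    list(label = m[2L], cuis = cuis, semtypes = split_list(m[4L]), kind = kind)
  })
}

#' Read gold-standard annotations
#'
#' TSV with header columns `raw` and `gold`; `gold` holds semicolon-separated
#' bracket-style concepts and may be blank for a site with no mappable
#' concept. Punctuation cells are dropped (they are excluded from
#' concept-level evaluation).
#'
#' @param path TSV path.
#' @return list of records `list(raw, concepts)`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   quote = "", fileEncoding = "UTF-8")
  if (!all(c("raw", "gold") %in% names(df))) {
    stop("gold file must have columns raw, gold")
  }
  lapply(seq_len(nrow(df)), function(i) {
    cells <- strsplit(df$gold[i], ";", fixed = TRUE)[[1]]
    cells <- trimws(cells[nzchar(trimws(cells))])
    concepts <- parse_bracket_concept(cells)
    concepts <- concepts[vapply(concepts, function(co) co$kind == "concept",
                                logical(1))]
    list(raw = df$raw[i], concepts = concepts)
  })
}

# TRUE when a predicted and a gold concept denote the same thing: they share
# at least one CUI, with case-insensitive label equality as the fallback when
# either side is a CUI-less supplement concept.
concept_compatible <- function(pred, gold) {
  if (length(pred$cuis) && length(gold$cuis)) {
    return(length(intersect(pred$cuis, gold$cuis)) > 0L)
  }
  identical(tolower(trimws(pred$label)), tolower(trimws(gold$label)))
}

#' Match predicted against gold concepts for one site
#'
#' Punctuation and unmapped annotations are excluded from the prediction
#' before matching. Matching is a maximum bipartite matching (augmenting
#' paths, predictions processed in order so ties resolve deterministically):
#' each gold concept matches at most one prediction, matched pairs are TP,
#' remaining predictions FP, remaining gold FN.
#'
#' @param predicted an `rt_site_annotation`, or a list of concepts as from
#'   [parse_bracket_concept()].
#' @param gold a gold record (`list(raw, concepts)`) or a list of concepts.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_concepts <- function(predicted, gold) {
  pred <- if (inherits(predicted, "rt_site_annotation")) {
    keep <- vapply(predicted$annotations, function(a) a$kind == "concept",
                   logical(1))
    lapply(predicted$annotations[keep], function(a) {
      list(label = a$surface_label, cuis = a$cuis, semtypes = a$semtypes)
    })
  } else if (!is.null(predicted$concepts)) {
    predicted$concepts # a gold-style record is also accepted as prediction
  } else {
    predicted
  }
  gold_concepts <- if (!is.null(gold$concepts)) gold$concepts else gold
  np <- length(pred); ng <- length(gold_concepts)
  if (np == 0L || ng == 0L) {
    return(c(tp = 0L, fp = np, fn = ng))
  }
  compat <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      compat[i, j] <- concept_compatible(pred[[i]], gold_concepts[[j]])
    }
  }
  # Kuhn's augmenting-path maximum matching; gold j -> matched prediction
  match_of_gold <- integer(ng)
  try_augment <- function(i, seen) {
    for (j in which(compat[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_of_gold[j] == 0L ||
          Recall(match_of_gold[j], seen)$ok) {
        match_of_gold[j] <<- i
        return(list(ok = TRUE, seen = seen))
      }
    }
    list(ok = FALSE, seen = seen)
  }
  for (i in seq_len(np)) {
    try_augment(i, rep(FALSE, ng))
  }
  tp <- sum(match_of_gold > 0L)
  c(tp = tp, fp = np - tp, fn = ng - tp)
}

#' Evaluate a corpus of predictions against gold records
#'
#' Pools per-site TP/FP/FN counts (concept-level micro-averaging — a single
#' corpus-level recall and precision) and computes recall `TP/(TP+FN)` and
#' precision `TP/(TP+FP)`. A zero denominator yields `NA` (printed as "n/a"),
#' never a division failure.
#'
#' @param predictions list of `rt_site_annotation` (or concept lists), aligned
#'   with `golds`.
#' @param golds list of gold records as from [read_gold()].
#' @return object of class `rt_eval_result` with `tp`, `fp`, `fn`, `recall`,
#'   `precision`, `n_sites`.
#' @export
evaluate_corpus <- function(predictions, golds) {
  if (length(predictions) != length(golds)) {
    stop("predictions and golds differ in length (",
         length(predictions), " vs ", length(golds), ")")
  }
  pred_raws <- vapply(predictions, function(p) {
    if (!is.null(p$raw)) p$raw else NA_character_
  }, character(1))
  gold_raws <- vapply(golds, function(g) g$raw, character(1))
  if (!anyNA(pred_raws) && !identical(pred_raws, gold_raws)) {
    # permit reordering when raws are unique on both sides
    if (!anyDuplicated(pred_raws) && !anyDuplicated(gold_raws) &&
        setequal(pred_raws, gold_raws)) {
      golds <- golds[match(pred_raws, gold_raws)]
    } else {
      bad <- unique(c(setdiff(pred_raws, gold_raws),
                      setdiff(gold_raws, pred_raws)))
      stop("predictions and golds are not aligned by raw string: ",
           paste(utils::head(bad, 5L), collapse = " | "))
    }
  }
  counts <- c(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(predictions)) {
    counts <- counts + match_concepts(predictions[[i]], golds[[i]])
  }
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  structure(
    list(tp = tp, fp = fp, fn = fn,
         recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
         n_sites = length(predictions)),
    class = "rt_eval_result"
  )
}

#' Format an evaluation result
#'
#' @param x an `rt_eval_result`.
#' @param style `"text"` or `"tsv"`.
#' @return character vector of report lines.
#' @export
format_eval_report <- function(x, style = c("text", "tsv")) {
  style <- match.arg(style)
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f", v)
  if (style == "tsv") {
    c("tp\tfp\tfn\trecall\tprecision",
      sprintf("%d\t%d\t%d\t%s\t%s", x$tp, x$fp, x$fn,
              fmt(x$recall), fmt(x$precision)))
  } else {
    c(sprintf("sites evaluated: %d", x$n_sites),
      sprintf("TP: %d  FP: %d  FN: %d", x$tp, x$fp, x$fn),
      sprintf("recall TP/(TP+FN): %s", fmt(x$recall)),
      sprintf("precision TP/(TP+FP): %s", fmt(x$precision)))
  }
}

#' @export
print.rt_eval_result <- function(x, ...) {
  cat(format_eval_report(x, "text"), sep = "\n")
  invisible(x)
}
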