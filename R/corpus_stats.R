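#' Build a frequency table of raw site names
#'
#' Exact, case-sensitive string counting ("Whole Brain", "whole brain" and
#' "WHole Brain" are distinct rows — annotation is case-insensitive but usage
#' statistics are not). Rows are sorted by count descending with ties kept in
#' first-occurrence order.
#'
#' @param corpus a character vector of raw strings (each counted once) or a
#'   data.frame with columns `site` and optionally `count`.
#' @return data.frame of class `rt_freq_table` with columns `site`, `count`
#'   and attributes `total_entries` and `n_unique`.
#' @export
build_frequency_table <- function(corpus) {
  if (is.data.frame(corpus)) {
    stopifnot("site" %in% names(corpus))
    site <- as.character(corpus$site)
    count <- if ("count" %in% names(corpus)) {
      as.integer(corpus$count)
    } else {
      rep(1L, nrow(corpus))
    }
  } else {
    site <- as.character(corpus)
    count <- rep(1L, length(site))
  }
  stopifnot(all(!is.na(count)), all(count >= 1L) || length(count) == 0L)
  u <- unique(site)
  agg <- vapply(split(count, factor(site, levels = u)), sum, integer(1))
  ord <- order(-agg, seq_along(u))
  out <- data.frame(site = u[ord], count = unname(agg[ord]),
                    stringsAsFactors = FALSE)
  structure(out, total_entries = sum(out$count), n_unique = nrow(out),
            class = c("rt_freq_table", "data.frame"))
}

#' @rdname build_frequency_table
#' @export
total_entries <- function(table) attr(table, "total_entries")

#' @rdname build_frequency_table
#' @export
n_unique <- function(table) attr(table, "n_unique")

#' Usage mass of the k most frequent sites
#'
#' Sums the counts of the top `k` rows and expresses them as a percentage of
#' `denominator` (one decimal). The denominator defaults to the table's
#' `total_entries`; pass the unique-label count of the full corpus to obtain
#' the share of usage that the top labels represent relative to corpus size —
#' the basis is an explicit argument because either convention is defensible.
#'
#' @param table an `rt_freq_table`.
#' @param k number of top rows (`k > n_unique` uses all rows with a warning).
#' @param denominator denominator for the share; default `total_entries(table)`.
#' @return list with `count` (sum of top-k counts), `share` (percentage, one
#'   decimal) and `denominator`.
#' @export
top_k_share <- function(table, k, denominator = NULL) {
  stopifnot(inherits(table, "rt_freq_table"), k >= 1L)
  if (k > nrow(table)) {
    warning("k = ", k, " exceeds the ", nrow(table),
            " unique rows; using all rows", call. = FALSE)
    k <- nrow(table)
  }
  s <- sum(table$count[seq_len(k)])
  denom <- if (is.null(denominator)) total_entries(table) else denominator
  list(count = s, share = round(100 * s / denom, 1), denominator = denom)
}

#' Mean number of uses per unique site name
#'
#' `total_entries / n_unique`, reported to two decimals. Either pass a
#' frequency table or the two corpus-level counts directly.
#'
#' @param table an `rt_freq_table`, or `NULL` when totals are given.
#' @param total,n_uniq corpus totals overriding the table's attributes.
#' @return numeric scalar; `NA` for an empty table.
#' @export
mean_uses_per_unique <- function(table = NULL, total = NULL, n_uniq = NULL) {
  if (!is.null(table)) {
    total <- total %||% total_entries(table)
    n_uniq <- n_uniq %||% n_unique(table)
  }
  if (is.null(total) || is.null(n_uniq) || n_uniq == 0L) {
    return(NA_real_)
  }
  round(total / n_uniq, 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sub-table of site names annotating to a target concept
#'
#' Annotates each row's site name through the full pipeline and keeps the
#' rows whose annotation contains the target concept (given as CUIs and/or
#' labels; labels compare case-insensitively). Counts and ordering are
#' preserved.
#'
#' @param table an `rt_freq_table`.
#' @param lexicon an `rt_lexicon`.
#' @param target character vector of CUIs or preferred labels.
#' @param model optional pre-trained bigram model.
#' @param config resolver configuration.
#' @return an `rt_freq_table` sub-table; empty, with a warning, when the
#'   target matches nothing in the lexicon.
#' @export
variant_group <- function(table, lexicon, target, model = NULL,
                          config = resolver_config()) {
  stopifnot(inherits(table, "rt_freq_table"), length(target) >= 1L)
  if (is.null(model)) {
    model <- train_bigrams(lexicon_token_sequences(lexicon))
  }
  target_l <- tolower(target)
  known <- FALSE
  for (tm in lexicon_terms(lexicon)) {
    for (e in lexicon_lookup(lexicon, tm)) {
      if (any(e$cuis %in% target) ||
          tolower(e$preferred_label) %in% target_l) {
        known <- TRUE
        break
      }
    }
    if (known) break
  }
  if (!known) {
    warning("target concept not found in lexicon: ",
            paste(target, collapse = ", "), call. = FALSE)
    return(build_frequency_table(data.frame(site = character(),
                                            count = integer())))
  }
  keep <- vapply(table$site, function(s) {
    sa <- annotate_site(s, lexicon, model, config)
    for (a in sa$annotations) {
      if (a$kind != "concept") next
      if (any(a$cuis %in% target) ||
          tolower(a$surface_label) %in% target_l) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total_entries = sum(out$count), n_unique = nrow(out),
            class = c("rt_freq_table", "data.frame"))
}

#' Read a site-name corpus file
#'
#' TSV or CSV (by extension) with a `site` column and optional `count`
#' column; a headerless file is read as one raw site name per line.
#'
#' @param path input path.
#' @return data.frame with columns `site` and `count`.
#' @export
read_site_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    return(data.frame(site = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (grepl("(^|[\t,])site([\t,]|$)", first)) {
    df <- read.delim(path, sep = sep, header = TRUE,
                     colClasses = "character", quote = "",
                     fileEncoding = "UTF-8")
    count <- if ("count" %in% names(df)) as.integer(df$count) else
      rep(1L, nrow(df))
    return(data.frame(site = df$site, count = count, stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  data.frame(site = lines, count = rep(1L, length(lines)),
             stringsAsFactors = FALSE)
}
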