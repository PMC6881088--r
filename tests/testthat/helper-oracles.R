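# Independent oracles used by the property tests. These deliberately use
# naive algorithms (recursion, exhaustive enumeration) so they share no code
# with the implementation they check.

# Memoized recursive Levenshtein distance.
lev_oracle <- local({
  memo <- new.env(parent = emptyenv())
  function(a, b) {
    key <- paste(a, b, sep = "\x1f")
    hit <- get0(key, envir = memo)
    if (!is.null(hit)) return(hit)
    res <- if (nchar(a) == 0L) {
      nchar(b)
    } else if (nchar(b) == 0L) {
      nchar(a)
    } else {
      cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
      min(
        lev_oracle(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost,
        lev_oracle(substr(a, 2, nchar(a)), b) + 1L,
        lev_oracle(a, substr(b, 2, nchar(b))) + 1L
      )
    }
    assign(key, res, envir = memo)
    res
  }
})

# All strings of length 0..maxlen over an alphabet.
all_strings <- function(alphabet, maxlen) {
  out <- ""
  level <- ""
  for (l in seq_len(maxlen)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# Exhaustive leftmost-longest segmentation of a token sequence against a set
# of (space-joined) terms. Enumerates every tiling with single-token gaps,
# then selects the maximum under the leftmost-longest order: compare the
# per-position match-length vectors lexicographically.
segment_oracle <- function(norms, term_set) {
  n <- length(norms)
  if (n == 0L) return(list())
  tilings <- function(i) {
    if (i > n) return(list(list()))
    out <- list()
    for (rest in tilings(i + 1L)) {
      out[[length(out) + 1L]] <- c(list(list(start = i, len = 0L)), rest)
    }
    for (j in i:n) {
      key <- paste(norms[i:j], collapse = " ")
      if (key %in% term_set) {
        for (rest in tilings(j + 1L)) {
          out[[length(out) + 1L]] <-
            c(list(list(start = i, len = j - i + 1L, term = key)), rest)
        }
      }
    }
    out
  }
  score <- function(tiling) {
    v <- integer(n)
    for (seg in tiling) if (seg$len > 0L) v[seg$start] <- seg$len
    v
  }
  best <- NULL
  best_score <- NULL
  for (tl in tilings(1L)) {
    sc <- score(tl)
    if (is.null(best) ||
        {
          cmp <- sc - best_score
          nz <- which(cmp != 0L)
          length(nz) > 0L && cmp[nz[1L]] > 0L
        }) {
      best <- tl
      best_score <- sc
    }
  }
  Filter(function(seg) seg$len > 0L, best)
}

# Brute-force maximum bipartite matching size over a compatibility matrix.
max_matching_oracle <- function(compat) {
  np <- nrow(compat)
  ng <- ncol(compat)
  if (np == 0L || ng == 0L) return(0L)
  best <- 0L
  recurse <- function(i, used) {
    if (i > np) return(0L)
    b <- recurse(i + 1L, used) # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!used[j] && compat[i, j]) {
        used2 <- used
        used2[j] <- TRUE
        b <- max(b, 1L + recurse(i + 1L, used2))
      }
    }
    b
  }
  recurse(1L, rep(FALSE, ng))
}

# Brute-force case-sensitive frequency count.
freq_oracle <- function(strings) {
  counts <- list()
  order_seen <- character()
  for (s in strings) {
    if (is.null(counts[[s]])) {
      counts[[s]] <- 0L
      order_seen <- c(order_seen, s)
    }
    counts[[s]] <- counts[[s]] + 1L
  }
  df <- data.frame(site = order_seen,
                   count = vapply(order_seen, function(s) counts[[s]],
                                  integer(1)),
                   stringsAsFactors = FALSE)
  df[order(-df$count, seq_len(nrow(df))), , drop = FALSE]
}
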