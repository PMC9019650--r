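#' Built-in target-term lexicon
#'
#' The default node terms whose collocational profiles are measured, split
#' into two framing categories: age-based terms that mark a person by age,
#' and role-based terms that mark a person by family role. Multiword terms
#' are matched as token sequences.
#'
#' @return A tibble with columns `term` (lowercase) and `framing`
#'   (`"age_based"` or `"role_based"`).
#' @export
target_terms <- function() {
  tibble(
    term = c(
      "aged", "elderly", "old people", "senior citizen", "older adult",
      "golden ager",
      "grandparent", "grandparents", "grandfather", "grandmother",
      "grandpa", "grandma", "granddad", "granny"
    ),
    framing = c(rep("age_based", 6), rep("role_based", 8))
  )
}

#' Read a target-term lexicon from TSV
#'
#' Expects columns `term` and `framing`; terms are lowercased. A term
#' assigned to both framings is an error.
#'
#' @param path TSV file with a header row.
#' @return Tibble with columns `term`, `framing`.
#' @export
read_target_lexicon <- function(path) {
  lex <- readr::read_tsv(path, col_types = readr::cols(
    term = readr::col_character(), framing = readr::col_character()
  ), progress = FALSE)
  lex$term <- tolower(lex$term)
  dup <- lex %>% distinct(.data$term, .data$framing) %>%
    count(.data$term) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Term(s) assigned to both framings: ",
                 paste(dup$term, collapse = ", ")))
  }
  distinct(as_tibble(lex))
}

#' Collocation window configuration
#'
#' @param span Content-token distance on each side of the target (default 6).
#'   Excluded articles do not consume this budget.
#' @param excluded_articles Words skipped without consuming span budget and
#'   never returned as collocates.
#' @param cross_sentence If `TRUE` (default) the window crosses sentence
#'   boundaries, except that a sentence-initial target contributes no tokens
#'   from the preceding sentence. If `FALSE` the window is confined to the
#'   target's sentence.
#' @param mi_threshold Minimum Mutual Information, inclusive (default 3).
#' @param min_cooccurrence Minimum raw co-occurrence count (default 1).
#' @return A list of class `window_config`.
#' @export
window_config <- function(span = 6L, excluded_articles = c("a", "an", "the"),
                          cross_sentence = TRUE, mi_threshold = 3,
                          min_cooccurrence = 1L) {
  stopifnot(span >= 1, is.finite(mi_threshold), min_cooccurrence >= 1)
  structure(list(
    span = as.integer(span),
    excluded_articles = tolower(excluded_articles),
    cross_sentence = isTRUE(cross_sentence),
    mi_threshold = mi_threshold,
    min_cooccurrence = as.integer(min_cooccurrence)
  ), class = "window_config")
}

#' Locate target-term occurrences in a tokenized corpus
#'
#' Finds every occurrence of the lexicon's terms. Overlapping candidates are
#' resolved longest-match-first, then left-to-right; each token position
#' contributes to at most one occurrence.
#'
#' @param tokens Token tibble from [tokenize_corpus()].
#' @param lexicon Tibble with columns `term`, `framing` (see
#'   [target_terms()]).
#' @return One row per occurrence: `doc_id`, `decade`, `genre`,
#'   `sentence_id`, `token_id` (first token of the match), `pos` (flat
#'   position within the document), `term`, `framing`, `term_len`, and
#'   `sentence_initial`.
#' @export
find_target_occurrences <- function(tokens, lexicon) {
  if (nrow(lexicon) == 0) abort("Empty target lexicon.")
  tokens <- tokens %>%
    arrange(.data$doc_id, .data$sentence_id, .data$token_id) %>%
    group_by(.data$doc_id) %>%
    mutate(pos = dplyr::row_number()) %>%
    ungroup()

  tok <- tokens$token
  docf <- as.integer(factor(tokens$doc_id, levels = unique(tokens$doc_id)))
  sent <- tokens$sentence_id
  n <- length(tok)
  used <- logical(n)

  term_toks <- stringr::str_split(tolower(lexicon$term), stringr::fixed(" "))

  # all candidate matches, then greedy longest-match-first, left-to-right
  cands <- vector("list", length(term_toks))
  for (i in seq_along(term_toks)) {
    tt <- term_toks[[i]]
    L <- length(tt)
    cand <- which(tok == tt[1])
    if (L > 1) {
      cand <- cand[cand + L - 1 <= n]
      for (j in 2:L) {
        cand <- cand[tok[cand + j - 1] == tt[j] &
                       docf[cand + j - 1] == docf[cand] &
                       sent[cand + j - 1] == sent[cand]]
      }
    }
    if (length(cand) > 0) {
      cands[[i]] <- tibble(row = cand, lex_i = i, term_len = L)
    }
  }
  cands <- bind_rows(cands)
  hits <- NULL
  if (!is.null(cands) && nrow(cands) > 0) {
    cands <- cands[order(-cands$term_len, cands$row, cands$lex_i), ]
    keep <- logical(nrow(cands))
    for (j in seq_len(nrow(cands))) {
      ii <- cands$row[j]:(cands$row[j] + cands$term_len[j] - 1L)
      if (!any(used[ii])) {
        used[ii] <- TRUE
        keep[j] <- TRUE
      }
    }
    cands <- cands[keep, ]
    hits <- tibble(row = cands$row, term = lexicon$term[cands$lex_i],
                   framing = lexicon$framing[cands$lex_i],
                   term_len = cands$term_len)
  }
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(doc_id = character(), decade = integer(),
                  genre = character(), sentence_id = integer(),
                  token_id = integer(), pos = integer(), term = character(),
                  framing = character(), term_len = integer(),
                  sentence_initial = logical()))
  }
  tibble(
    doc_id = tokens$doc_id[hits$row],
    decade = tokens$decade[hits$row],
    genre = tokens$genre[hits$row],
    sentence_id = tokens$sentence_id[hits$row],
    token_id = tokens$token_id[hits$row],
    pos = tokens$pos[hits$row],
    term = hits$term,
    framing = hits$framing,
    term_len = hits$term_len,
    sentence_initial = tokens$token_id[hits$row] == 1L
  ) %>% arrange(.data$doc_id, .data$pos)
}

# Window for one occurrence over a single document's flat token/sentence
# vectors. Articles are skipped without consuming span budget; tokens equal
# to the target's own words are dropped from the returned bag.
window_one <- function(tok, sent, pos, term_len, sentence_initial, cfg) {
  n <- length(tok)
  is_art <- tok %in% cfg$excluded_articles
  s0 <- sent[pos]

  take_side <- function(idx) {
    if (length(idx) == 0) return(character(0))
    idx <- idx[!is_art[idx]]
    head(tok[idx], cfg$span)
  }

  left_idx <- if (pos > 1) (pos - 1):1 else integer(0)
  if (length(left_idx) > 0) {
    if (sentence_initial || !cfg$cross_sentence) {
      left_idx <- left_idx[sent[left_idx] == s0]
    }
  }
  right_start <- pos + term_len
  right_idx <- if (right_start <= n) right_start:n else integer(0)
  if (length(right_idx) > 0 && !cfg$cross_sentence) {
    right_idx <- right_idx[sent[right_idx] == s0]
  }

  w <- c(take_side(left_idx), take_side(right_idx))
  own <- tok[pos:(pos + term_len - 1)]
  w[!(w %in% own)]
}

#' Extract the collocate window around one target occurrence
#'
#' Returns up to `span` non-article tokens on each side of the occurrence.
#' Articles are skipped and do not consume the span budget; the target's own
#' tokens never appear in the bag; a sentence-initial target takes no tokens
#' from the preceding sentence.
#'
#' @param doc_tokens Token tibble for a single document.
#' @param site One row of [find_target_occurrences()] output (or a list with
#'   `pos`, `term_len`, `sentence_initial`).
#' @param cfg A [window_config()].
#' @return Character vector of collocate tokens (a bag; duplicates kept).
#' @export
extract_window <- function(doc_tokens, site, cfg = window_config()) {
  doc_tokens <- arrange(doc_tokens, .data$sentence_id, .data$token_id)
  window_one(doc_tokens$token, doc_tokens$sentence_id,
             pos = site$pos, term_len = site$term_len,
             sentence_initial = isTRUE(site$sentence_initial), cfg = cfg)
}

#' Collocate windows for every occurrence
#'
#' Applies [extract_window()] to each occurrence and returns the result in
#' long form.
#'
#' @inheritParams extract_window
#' @param tokens Token tibble for the whole corpus.
#' @param occurrences Output of [find_target_occurrences()].
#' @return Long tibble: occurrence metadata plus one row per collocate token.
#' @export
collocate_windows <- function(tokens, occurrences, cfg = window_config()) {
  tokens <- arrange(tokens, .data$doc_id, .data$sentence_id, .data$token_id)
  tok_by_doc <- split(tokens$token, tokens$doc_id)
  sent_by_doc <- split(tokens$sentence_id, tokens$doc_id)

  bags <- vector("list", nrow(occurrences))
  for (i in seq_len(nrow(occurrences))) {
    d <- occurrences$doc_id[i]
    bags[[i]] <- window_one(
      tok_by_doc[[d]], sent_by_doc[[d]],
      pos = occurrences$pos[i], term_len = occurrences$term_len[i],
      sentence_initial = occurrences$sentence_initial[i], cfg = cfg
    )
  }
  nb <- lengths(bags)
  occurrences[rep.int(seq_len(nrow(occurrences)), nb),
              c("doc_id", "decade", "genre", "term", "framing")] %>%
    mutate(collocate = unlist(bags, use.names = FALSE)) %>%
    as_tibble()
}

#' Count target-collocate co-occurrences per stratum
#'
#' @param windows Long window tibble from [collocate_windows()].
#' @param by Stratum columns, a subset of `c("decade", "genre")`.
#' @return Tibble (`term`, `framing`, strata, `collocate`,
#'   `cooccurrence_count`).
#' @export
count_collocates <- function(windows, by = "decade") {
  windows %>%
    count(.data$term, .data$framing, across(all_of(by)), .data$collocate,
          name = "cooccurrence_count")
}

#' Mutual Information of a target-collocate pair
#'
#' Computes the corpus-linguistics MI score in bits,
#' `log2(cooccurrence_count * N / (target_freq * collocate_freq * W))` with
#' window size `W = 2 * span`. MI is 0 when the observed co-occurrence equals
#' its expectation under independence given the window size; MI of 3 or more
#' is the conventional "semantic bonding" threshold.
#'
#' @param cooccurrence_count Times the collocate appeared in-window with the
#'   target in the stratum.
#' @param target_freq,collocate_freq Marginal frequencies in the stratum.
#' @param stratum_N Total tokens in the stratum.
#' @param span Window half-width (default 6).
#' @return MI in bits (vectorized).
#' @export
compute_mi <- function(cooccurrence_count, target_freq, collocate_freq,
                       stratum_N, span = 6L) {
  if (any(cooccurrence_count < 1) || any(target_freq < 1) ||
      any(collocate_freq < 1) || any(stratum_N < 1)) {
    abort("All counts must be >= 1 to compute MI.")
  }
  W <- 2 * span
  log2((cooccurrence_count * stratum_N) /
         (target_freq * collocate_freq * W))
}

#' Full collocate extraction pipeline
#'
#' Runs occurrence finding, window extraction, co-occurrence counting, and
#' MI scoring over a tokenized corpus, stratified by decade (optionally also
#' genre). Target frequency is the number of occurrences of the term in the
#' stratum (which handles multiword terms); collocate frequency and `N` come
#' from [corpus_frequencies()].
#'
#' @param tokens Token tibble from [tokenize_corpus()].
#' @param lexicon Target lexicon (see [target_terms()]).
#' @param cfg A [window_config()].
#' @param by Stratum columns, a subset of `c("decade", "genre")`.
#' @return Collocate records: `term`, `framing`, strata, `collocate`,
#'   `cooccurrence_count`, `target_freq`, `collocate_freq`, `N`, `mi`.
#' @export
extract_collocates <- function(tokens, lexicon, cfg = window_config(),
                               by = "decade") {
  occ <- find_target_occurrences(tokens, lexicon)
  if (nrow(occ) == 0) {
    return(tibble(term = character(), framing = character(),
                  decade = integer(), collocate = character(),
                  cooccurrence_count = integer(), target_freq = integer(),
                  collocate_freq = integer(), N = integer(), mi = double()))
  }
  windows <- collocate_windows(tokens, occ, cfg)
  counts <- count_collocates(windows, by = by)
  tfreq <- occ %>% count(.data$term, across(all_of(by)), name = "target_freq")
  stats <- corpus_frequencies(tokens, by = by) %>%
    rename(collocate = "word", collocate_freq = "freq")
  counts %>%
    left_join(tfreq, by = c("term", by)) %>%
    left_join(stats, by = c("collocate", by)) %>%
    mutate(mi = compute_mi(.data$cooccurrence_count, .data$target_freq,
                           .data$collocate_freq, .data$N, span = cfg$span))
}

#' Filter collocate records by MI, count, and exclusion list
#'
#' Keeps a record iff `mi >= mi_threshold` (inclusive, per the "3 and above"
#' convention), `cooccurrence_count >= min_cooccurrence`, and the collocate
#' is not excluded. The exclusion list stands in for a human relevance
#' screen; it may be a character vector (global) or a tibble with columns
#' `term`, `collocate` (per-target).
#'
#' @param records Collocate records from [extract_collocates()].
#' @param cfg A [window_config()] providing the thresholds.
#' @param exclusion `NULL`, a character vector, or a tibble
#'   (`term`, `collocate`).
#' @return The retained records. Idempotent.
#' @export
filter_collocates <- function(records, cfg = window_config(),
                              exclusion = NULL) {
  out <- records %>%
    filter(.data$mi >= cfg$mi_threshold,
           .data$cooccurrence_count >= cfg$min_cooccurrence)
  if (is.null(exclusion)) return(out)
  if (is.character(exclusion)) {
    out %>% filter(!(.data$collocate %in% tolower(exclusion)))
  } else {
    anti_join(out, mutate(exclusion, collocate = tolower(.data$collocate)),
              by = c("term", "collocate"))
  }
}

#' Read an exclusion list
#'
#' One word per line (global list), or a TSV with columns `term`,
#' `collocate` for per-target exclusions.
#'
#' @param path File path.
#' @param per_target If `TRUE`, parse as TSV (`term`, `collocate`).
#' @return Character vector or tibble, to pass to [filter_collocates()].
#' @export
read_exclusion_list <- function(path, per_target = FALSE) {
  if (per_target) {
    readr::read_tsv(path, col_types = readr::cols(
      term = readr::col_character(), collocate = readr::col_character()
    ), progress = FALSE)
  } else {
    x <- readLines(path, warn = FALSE, encoding = "UTF-8")
    tolower(trimws(x[nzchar(trimws(x))]))
  }
}
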