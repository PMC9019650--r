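#' Decade bin of a calendar year
#'
#' Maps a year to its decade bin label, `floor(year / 10) * 10`, so that
#' 1810--1819 map to 1810 and 2010--2019 map to 2010. The default corpus
#' range 1810--2019 yields 21 bins.
#'
#' @param year Integer vector of calendar years.
#' @return Integer vector of decade labels.
#' @examples
#' decade_of(c(1815, 2019))
#' @export
decade_of <- function(year) {
  as.integer(floor(year / 10) * 10)
}

default_year_range <- c(1810L, 2019L)

#' Abbreviations that do not end a sentence
#'
#' Lowercased tokens (with trailing period) treated as abbreviations by the
#' tokenizer: they keep their period and never trigger a sentence break.
#' Single-letter initials ("j.") are always guarded in addition to this list.
#'
#' @return Character vector of abbreviation tokens.
#' @export
default_abbreviations <- function() {
  c(
    "mr.", "mrs.", "ms.", "dr.", "st.", "jr.", "sr.", "prof.", "rev.",
    "gen.", "col.", "capt.", "lt.", "sgt.", "hon.", "vs.", "etc.",
    "e.g.", "i.e.", "no.", "vol.", "ch.", "fig.", "dept.", "inc.", "co."
  )
}

validate_documents <- function(docs, year_range = default_year_range,
                               action = c("warn", "error")) {
  action <- match.arg(action)
  docs <- as_tibble(docs)
  required <- c("doc_id", "year", "genre", "text")
  missing_cols <- setdiff(required, names(docs))
  if (length(missing_cols) > 0) {
    abort(paste0("Corpus is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  year <- suppressWarnings(as.integer(docs$year))
  text_norm <- stringr::str_squish(as.character(docs$text))
  genre <- as.character(docs$genre)
  bad <- is.na(year) | year < year_range[1] | year > year_range[2] |
    is.na(genre) | genre == "" | is.na(text_norm) | text_norm == ""
  n_bad <- sum(bad)
  if (n_bad > 0) {
    msg <- paste0(n_bad, " malformed record(s) (missing/out-of-range year, ",
                  "empty genre, or empty text)")
    if (action == "error") abort(msg) else warn(paste0(msg, "; skipped."))
  }
  out <- tibble(
    doc_id = as.character(docs$doc_id),
    year = year,
    genre = genre,
    text = as.character(docs$text)
  )[!bad, ]
  attr(out, "n_skipped") <- n_bad
  out
}

#' Read a decade-stamped corpus
#'
#' Reads a corpus of documents, each carrying a document id, a calendar year,
#' a genre label, and raw text. Three dialects are supported: JSON Lines (one
#' object per line with keys `doc_id`, `year`, `genre`, `text`; the canonical
#' format), tab-separated values with those four columns and a header row,
#' and a read-only word-per-line dialect in which a line starting with `@@`
#' introduces a document as `@@doc_id<TAB>year<TAB>genre` and each following
#' line holds one token.
#'
#' Malformed records (missing or out-of-range year, empty genre or text) are
#' skipped with a single warning; the number skipped is attached as the
#' `n_skipped` attribute.
#'
#' @param path Path to the corpus file.
#' @param dialect One of `"jsonl"`, `"tsv"`, `"wordline"`.
#' @param year_range Inclusive year bounds; records outside are skipped.
#' @return A tibble with columns `doc_id`, `year`, `genre`, `text`.
#' @export
read_corpus <- function(path, dialect = c("jsonl", "tsv", "wordline"),
                        year_range = default_year_range) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("Corpus file not found: ", path))
  raw <- switch(dialect,
    jsonl = read_corpus_jsonl(path),
    tsv = read_corpus_tsv(path),
    wordline = read_corpus_wordline(path)
  )
  n_parse_skipped <- attr(raw, "n_skipped") %||% 0L
  out <- validate_documents(raw, year_range = year_range, action = "warn")
  attr(out, "n_skipped") <- n_parse_skipped + (attr(out, "n_skipped") %||% 0L)
  out
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble(doc_id = character(), year = integer(),
                  genre = character(), text = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  recs <- lapply(lines, function(l) {
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
  })
  n_bad <- sum(vapply(recs, is.null, logical(1)))
  if (n_bad > 0) warn(paste0(n_bad, " unparseable JSON line(s) skipped."))
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- purrr::map_dfr(recs, function(r) {
    tibble(
      doc_id = as.character(r$doc_id %||% NA_character_),
      year = as.integer(r$year %||% NA_integer_),
      genre = as.character(r$genre %||% NA_character_),
      text = as.character(r$text %||% NA_character_)
    )
  })
  attr(out, "n_skipped") <- n_bad
  out
}

read_corpus_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    doc_id = readr::col_character(),
    year = readr::col_integer(),
    genre = readr::col_character(),
    text = readr::col_character()
  ), progress = FALSE)
  attr(out, "n_skipped") <- 0L
  out
}

read_corpus_wordline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_header <- startsWith(lines, "@@")
  if (!any(is_header)) {
    abort("wordline corpus has no '@@' document headers")
  }
  doc_idx <- cumsum(is_header)
  headers <- lines[is_header]
  parts <- stringr::str_split_fixed(sub("^@@", "", headers), "\t", 3)
  body <- split(lines[!is_header & nzchar(lines)],
                doc_idx[!is_header & nzchar(lines)])
  texts <- vapply(seq_len(nrow(parts)), function(i) {
    toks <- body[[as.character(i)]] %||% character()
    paste(toks, collapse = " ")
  }, character(1))
  out <- tibble(
    doc_id = parts[, 1],
    year = suppressWarnings(as.integer(parts[, 2])),
    genre = parts[, 3],
    text = texts
  )
  attr(out, "n_skipped") <- 0L
  out
}

#' Write a corpus
#'
#' Inverse of [read_corpus()] for the `jsonl` and `tsv` dialects;
#' `read_corpus(write_corpus(x))` preserves all fields of well-formed records.
#'
#' @param docs Tibble with columns `doc_id`, `year`, `genre`, `text`.
#' @param path Output file path.
#' @param dialect `"jsonl"` (canonical) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path, dialect = c("jsonl", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    readr::write_tsv(docs[, c("doc_id", "year", "genre", "text")], path)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(docs))) {
      writeLines(jsonlite::toJSON(list(
        doc_id = docs$doc_id[i], year = docs$year[i],
        genre = docs$genre[i], text = docs$text[i]
      ), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Tokenize and sentence-segment a corpus
#'
#' Splits each document into sentences and lowercased tokens and bins it into
#' a decade. Tokens are whitespace-delimited with leading/trailing punctuation
#' stripped (internal hyphens and apostrophes kept). Sentences end at tokens
#' with terminal punctuation (`.`, `!`, `?`, possibly followed by closing
#' quotes/brackets) unless the token is a guarded abbreviation or a
#' single-letter initial, which also keep their period.
#'
#' @param docs Tibble of documents as returned by [read_corpus()].
#' @param year_range Inclusive year bounds; a document outside them is an
#'   error.
#' @param abbreviations Lowercased abbreviation tokens (with period) that
#'   never end a sentence.
#' @return One row per token: `doc_id`, `decade`, `genre`, `sentence_id`
#'   (1-based within document), `token_id` (1-based within sentence), `token`.
#' @examples
#' docs <- tibble::tibble(doc_id = "d1", year = 1900, genre = "fiction",
#'                        text = "Old Mr. Jones smiled. He left.")
#' tokenize_corpus(docs)
#' @export
tokenize_corpus <- function(docs, year_range = default_year_range,
                            abbreviations = default_abbreviations()) {
  docs <- validate_documents(docs, year_range = year_range, action = "error")
  if (nrow(docs) == 0) abort("No documents to tokenize.")

  raw_list <- stringr::str_split(docs$text, "[ \t\r\n]+")
  n_raw <- lengths(raw_list)
  raw <- unlist(raw_list, use.names = FALSE)
  doc_row <- rep.int(seq_len(nrow(docs)), n_raw)

  lead <- sub("^[^[:alnum:]]+", "", raw)
  low <- tolower(lead)
  guarded <- low %in% tolower(abbreviations) | grepl("^[a-z]\\.$", low)
  terminal <- grepl("[.!?][]\"')]*$", lead) & !guarded
  clean <- ifelse(guarded, low, tolower(sub("[^[:alnum:]]+$", "", lead)))

  # sentence index: a terminal token closes its sentence; breaks reset per doc
  brk <- c(FALSE, terminal[-length(terminal)])
  new_doc <- c(TRUE, doc_row[-1] != doc_row[-length(doc_row)])
  brk[new_doc] <- FALSE
  sent_raw <- stats::ave(as.integer(brk), doc_row, FUN = cumsum) + 1L

  keep <- nzchar(clean)
  tok <- tibble(
    doc_row = doc_row[keep],
    sent_raw = sent_raw[keep],
    token = clean[keep]
  )
  # renumber sentences compactly (all-punctuation sentences may have vanished)
  tok <- tok %>%
    group_by(.data$doc_row) %>%
    mutate(sentence_id = match(.data$sent_raw, unique(.data$sent_raw))) %>%
    group_by(.data$doc_row, .data$sentence_id) %>%
    mutate(token_id = dplyr::row_number()) %>%
    ungroup()

  tibble(
    doc_id = docs$doc_id[tok$doc_row],
    decade = decade_of(docs$year[tok$doc_row]),
    genre = docs$genre[tok$doc_row],
    sentence_id = tok$sentence_id,
    token_id = tok$token_id,
    token = tok$token
  )
}

#' Per-stratum token totals and word marginal frequencies
#'
#' Counts, within each stratum (by default the decade; optionally decade and
#' genre), the total number of tokens `N` and the marginal frequency of every
#' word. These marginals feed the Mutual Information score.
#'
#' @param tokens Token tibble from [tokenize_corpus()].
#' @param by Stratum columns, a subset of `c("decade", "genre")`.
#' @return A tibble with the stratum columns, `word`, `freq`, and the stratum
#'   total `N`.
#' @export
corpus_frequencies <- function(tokens, by = "decade") {
  if (nrow(tokens) == 0) abort("Empty token stream: no strata to count.")
  stopifnot(all(by %in% c("decade", "genre")))
  marg <- tokens %>%
    count(across(all_of(by)), word = .data$token, name = "freq")
  totals <- marg %>%
    group_by(across(all_of(by))) %>%
    summarise(N = sum(.data$freq), .groups = "drop")
  marg %>% left_join(totals, by = by)
}
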