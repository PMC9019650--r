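toy_tokens <- function(text, year = 1900, doc_id = "d1", genre = "g") {
  tokenize_corpus(tibble::tibble(doc_id = doc_id, year = year,
                                 genre = genre, text = text))
}

test_that("multiword terms win by longest match", {
  tok <- toy_tokens("the senior citizen spoke")
  lex <- tibble::tibble(term = c("senior citizen", "citizen"),
                        framing = "age_based")
  occ <- find_target_occurrences(tok, lex)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$term, "senior citizen")
  expect_equal(occ$term_len, 2L)
})

test_that("no target present yields an empty occurrence table", {
  occ <- find_target_occurrences(toy_tokens("nothing to see here"),
                                 target_terms())
  expect_equal(nrow(occ), 0)
})

test_that("sentence-initial occurrences are flagged", {
  tok <- toy_tokens("old people marched. the old people waved")
  occ <- find_target_occurrences(
    tok, tibble::tibble(term = "old people", framing = "age_based"))
  expect_equal(nrow(occ), 2)
  expect_equal(occ$sentence_initial, c(TRUE, FALSE))
  expect_equal(occ$token_id[1], 1L)
})

test_that("articles are skipped without consuming span budget", {
  tok <- toy_tokens("the kind elderly man")
  lex <- tibble::tibble(term = "elderly", framing = "age_based")
  occ <- find_target_occurrences(tok, lex)
  w <- extract_window(tok, occ[1, ], window_config())
  expect_setequal(w, c("kind", "man"))

  # budget boundary: 7 non-article tokens to the right -> exactly 6 kept
  tok2 <- toy_tokens("elderly w1 w2 w3 w4 w5 w6 w7")
  occ2 <- find_target_occurrences(tok2, lex)
  w2 <- extract_window(tok2, occ2[1, ], window_config())
  expect_equal(w2, paste0("w", 1:6))

  # stuffing articles between target and collocates changes nothing
  tok3 <- toy_tokens("elderly the a w1 an w2 the the w3 a w4 w5 an w6 w7")
  occ3 <- find_target_occurrences(tok3, lex)
  w3 <- extract_window(tok3, occ3[1, ], window_config())
  expect_equal(w3, paste0("w", 1:6))
})

test_that("sentence-initial targets exclude the preceding sentence", {
  tok <- toy_tokens("some words before. elderly man smiled")
  lex <- tibble::tibble(term = "elderly", framing = "age_based")
  occ <- find_target_occurrences(tok, lex)
  expect_true(occ$sentence_initial)
  w <- extract_window(tok, occ[1, ], window_config())
  expect_setequal(w, c("man", "smiled"))

  # a mid-sentence target does cross the boundary
  tok2 <- toy_tokens("some words before. the elderly man smiled")
  occ2 <- find_target_occurrences(tok2, lex)
  w2 <- extract_window(tok2, occ2[1, ], window_config())
  expect_setequal(w2, c("some", "words", "before", "man", "smiled"))

  # strict within-sentence mode confines both sides
  w3 <- extract_window(tok2, occ2[1, ], window_config(cross_sentence = FALSE))
  expect_setequal(w3, c("man", "smiled"))
})

test_that("co-occurrence counting is additive over windows and strata", {
  docs <- tibble::tibble(
    doc_id = c("a", "b"),
    year = c(1850L, 1950L),
    genre = "g",
    text = c("frail elderly frail man", "elderly frail")
  )
  tok <- tokenize_corpus(docs)
  lex <- tibble::tibble(term = "elderly", framing = "age_based")
  occ <- find_target_occurrences(tok, lex)
  win <- collocate_windows(tok, occ, window_config())
  counts <- count_collocates(win)
  expect_equal(
    counts$cooccurrence_count[counts$collocate == "frail" &
                                counts$decade == 1850], 2L)
  expect_equal(
    counts$cooccurrence_count[counts$collocate == "frail" &
                                counts$decade == 1950], 1L)
})

test_that("MI matches the formula and its limiting laws", {
  # independence point: observed = expected -> 0 bits
  expect_equal(compute_mi(12, 10, 100, 1000, span = 6), 0)
  # hand arithmetic
  expect_equal(compute_mi(8, 10, 20, 10000, span = 6),
               log2(8 * 10000 / (10 * 20 * 12)))
  expect_equal(compute_mi(8, 10, 20, 10000, span = 6), 5.0589, tolerance = 1e-4)
  # doubling N adds exactly one bit
  expect_equal(compute_mi(8, 10, 20, 20000) - compute_mi(8, 10, 20, 10000), 1)
  # monotonicity in co-occurrence at fixed marginals
  mis <- compute_mi(1:10, 20, 30, 5000)
  expect_true(all(diff(mis) > 0))
  expect_error(compute_mi(0, 1, 1, 10), ">= 1")
})

test_that("filtering is inclusive at the MI threshold and idempotent", {
  cfg <- window_config(mi_threshold = 3)
  rec <- tibble::tibble(
    term = "elderly", framing = "age_based", decade = 1900L,
    collocate = c("at", "below", "above", "banned"),
    cooccurrence_count = c(5L, 5L, 5L, 5L),
    target_freq = 10L, collocate_freq = 10L, N = 1000L,
    mi = c(3.0, 2.999, 8, 8)
  )
  kept <- filter_collocates(rec, cfg, exclusion = "banned")
  expect_setequal(kept$collocate, c("at", "above"))
  expect_identical(filter_collocates(kept, cfg, exclusion = "banned"), kept)

  # per-target exclusion only hits the named pair
  kept2 <- filter_collocates(
    rec, cfg,
    exclusion = tibble::tibble(term = "other", collocate = "above"))
  expect_true("above" %in% kept2$collocate)
})

test_that("pipeline equals the brute-force oracle on random corpora", {
  cfg <- window_config()
  for (s in 1:4) {
    tok <- tokenize_corpus(make_random_corpus(s, n_docs = 8))
    imp <- sort_records(extract_collocates(tok, oracle_lexicon(), cfg))
    ora <- sort_records(naive_collocates(tok, oracle_lexicon(), cfg))
    expect_equal(as.data.frame(imp), as.data.frame(ora), tolerance = 1e-12)
  }
})

test_that("article invariance: injected articles never evict a collocate", {
  cfg <- window_config()
  base <- "w1 w2 elderly w3 w4"
  stuffed <- "the w1 a w2 an the elderly a a w3 the w4 an"
  lex <- tibble::tibble(term = "elderly", framing = "age_based")
  for (txt in c(base, stuffed)) {
    tok <- toy_tokens(txt)
    occ <- find_target_occurrences(tok, lex)
    expect_setequal(extract_window(tok, occ[1, ], cfg),
                    c("w1", "w2", "w3", "w4"))
  }
})
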