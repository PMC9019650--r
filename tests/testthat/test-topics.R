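test_that("century mapping covers the two-century contrast only", {
  expect_equal(century_of(c(1810, 1890, 1900, 1990)),
               c("1800s", "1800s", "1900s", "1900s"))
  expect_true(all(is.na(century_of(c(2000, 2010)))))
})

fake_record <- function(term, decade, collocate, count, framing = "age_based",
                        genre = "g") {
  tibble::tibble(term = term, framing = framing, decade = decade,
                 genre = genre, collocate = collocate,
                 cooccurrence_count = count, target_freq = 1L,
                 collocate_freq = 1L, N = 100L, mi = 5)
}

test_that("topic documents are synonym-decade multisets within strata", {
  rec <- dplyr::bind_rows(
    fake_record("elderly", 1850L, "frail", 3L),
    fake_record("elderly", 1850L, "wise", 1L),
    fake_record("elderly", 1950L, "sick", 2L),
    fake_record("granny", 1850L, "kind", 1L, framing = "role_based"),
    fake_record("elderly", 2010L, "modern", 9L)
  )
  bags <- build_topic_documents(rec)
  # hand-built expectation: 2000s record dropped; counts preserved
  expect_setequal(unique(bags$century), c("1800s", "1900s"))
  expect_equal(bags$count[bags$word == "frail"], 3L)
  expect_equal(sort(unique(bags$doc)),
               c("elderly:1850", "elderly:1950", "granny:1850"))
  one_decade <- build_topic_documents(fake_record("elderly", 1850L, "x", 1L))
  expect_equal(unique(one_decade$century), "1800s")
})

test_that("LDA is deterministic under a seed and properly normalized", {
  mix <- tibble::tibble(framing = "age_based", century = "1800s",
                        n_topics = 3L, n_positive = 2L)
  tc <- generate_topic_corpus(mix, seed = 5)
  spec <- topic_model_spec(n_topics = 3, seed = 11, n_iter = 100)
  f1 <- fit_lda(tc$bags, spec)
  f2 <- fit_lda(tc$bags, spec)
  expect_identical(f1$topics, f2$topics)
  expect_identical(f1$phi, f2$phi)
  for (phi in f1$phi) {
    expect_equal(rowSums(phi), rep(1, nrow(phi)), tolerance = 1e-8)
  }
})

test_that("a vocabulary smaller than n_topics is a configuration error", {
  bags <- tibble::tibble(framing = "a", century = "1800s",
                         doc = c("d1", "d2"), word = c("w1", "w2"),
                         count = 1L)
  expect_error(fit_lda(bags, topic_model_spec(n_topics = 5)), "vocabulary")
})

test_that("disjoint planted topics are recovered with high purity", {
  mix <- tibble::tibble(framing = "age_based", century = "1800s",
                        n_topics = 2L, n_positive = 1L)
  tc <- generate_topic_corpus(mix, docs_per_topic = 30, seed = 8)
  fit <- fit_lda(tc$bags, topic_model_spec(n_topics = 2, seed = 3))
  purity <- topic_purity(fit$phi[[1]],
                         tc$planted[["age_based|1800s"]]$vocabs)
  expect_gt(purity, 0.9)
})

test_that("topic valence classification uses the strict-below-neutral rule", {
  topics <- tibble::tibble(
    framing = "a", century = "1800s",
    topic_id = rep(1:3, each = 2), rank = rep(1:2, 3),
    word = c("g1", "g2", "b1", "b2", "n1", "n2"),
    prob = 1 / 6
  )
  lex <- tibble::tibble(
    word = c("g1", "g2", "b1", "b2", "n1", "n2"),
    merged_rating = c(5, 5, 2.4, 2.4, 3, 3)
  )
  lab <- classify_topic_valence(topics, lex)
  expect_equal(lab$label[lab$topic_id == 1], "positive_neutral")
  expect_equal(lab$label[lab$topic_id == 2], "negative")
  expect_equal(lab$mean_top_valence[lab$topic_id == 2], 2.4)
  # the boundary mean of exactly 3.0 is positive/neutral
  expect_equal(lab$label[lab$topic_id == 3], "positive_neutral")
})

test_that("raising every top word's rating never flips a topic negative", {
  set.seed(44)
  words <- paste0("w", 1:10)
  topics <- tibble::tibble(framing = "a", century = "1800s", topic_id = 1L,
                           rank = 1:10, word = words, prob = 0.1)
  base <- runif(10, 1, 4.5)
  lex1 <- tibble::tibble(word = words, merged_rating = base)
  lex2 <- tibble::tibble(word = words,
                         merged_rating = pmin(base + runif(10, 0, 0.5), 5))
  l1 <- classify_topic_valence(topics, lex1)
  l2 <- classify_topic_valence(topics, lex2)
  if (l1$label == "positive_neutral") {
    expect_equal(l2$label, "positive_neutral")
  }
  expect_gte(l2$mean_top_valence, l1$mean_top_valence)
})

test_that("unrated top words are dropped; unclassifiable topics error", {
  topics <- tibble::tibble(framing = "a", century = "1800s", topic_id = 1L,
                           rank = 1:2, word = c("known", "unknown"),
                           prob = 0.5)
  lex <- tibble::tibble(word = "known", merged_rating = 4)
  expect_warning(lab <- classify_topic_valence(topics, lex), "unrated")
  expect_equal(lab$mean_top_valence, 4)
  expect_error(
    suppressWarnings(classify_topic_valence(
      topics, tibble::tibble(word = "zzz", merged_rating = 1))),
    "no rated")
})

test_that("positivity proportions count topics per cell", {
  lab <- tibble::tibble(
    framing = "role_based", century = "1900s", topic_id = 1:9,
    mean_top_valence = c(rep(4, 8), 2),
    label = c(rep("positive_neutral", 8), "negative")
  )
  s <- positivity_proportions(lab)
  expect_equal(s$n_topics_total, 9L)
  expect_equal(s$n_positive_neutral, 8L)
  expect_equal(round(100 * s$proportion_positive_neutral), 89)
  # ordering invariance
  s2 <- positivity_proportions(lab[sample(9), ])
  expect_equal(s, s2)
  # all-negative cell
  lab$label <- "negative"
  expect_equal(positivity_proportions(lab)$proportion_positive_neutral, 0)
})
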