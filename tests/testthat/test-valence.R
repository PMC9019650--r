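test_that("cronbach alpha matches the closed form and its fixture", {
  # perfect agreement
  r <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(r)$alpha, 1)

  # hand-verified fixture (independently cross-checked numerically):
  # alpha = 2 * (1 - (2.5 + 1.7) / 8.2) = 0.975609756...
  a <- cronbach_alpha(cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 5)))
  expect_equal(a$alpha, 0.975609756097561, tolerance = 1e-12)
  # Feldt bounds frozen from the same independent computation
  expect_equal(a$ci_low, 0.765743173543, tolerance = 1e-9)
  expect_equal(a$ci_high, 0.997460547867, tolerance = 1e-9)
  expect_true(a$ci_low <= a$alpha && a$alpha <= a$ci_high)
})

test_that("independent raters give alpha near zero at large n", {
  set.seed(42)
  r <- cbind(rnorm(5000), rnorm(5000))
  expect_lt(abs(cronbach_alpha(r)$alpha), 0.1)
})

test_that("alpha is invariant to shifting one rater by a constant", {
  set.seed(7)
  r1 <- sample(1:5, 50, replace = TRUE)
  r2 <- pmin(pmax(r1 + sample(-1:1, 50, replace = TRUE), 1), 5)
  a0 <- cronbach_alpha(cbind(r1, r2))$alpha
  a1 <- cronbach_alpha(cbind(r1, r2 + 10))$alpha
  expect_equal(a0, a1, tolerance = 1e-12)
})

test_that("degenerate rating tables are rejected", {
  expect_error(cronbach_alpha(cbind(c(3, 3, 3), c(3, 3, 3))), "variance")
  expect_error(cronbach_alpha(cbind(1:2, 2:1)), "3 rated items")
})

test_that("rater merging averages and flags large divergences", {
  lex <- tibble::tibble(word = c("x", "y"), rater1 = c(1, 2),
                        rater2 = c(5, 3))
  expect_warning(m <- merge_raters(lex), "divergence")
  expect_equal(m$merged_rating, c(3, 2.5))
  expect_error(merge_raters(tibble::tibble(word = "z", rater1 = 0,
                                           rater2 = 3)), "1, 5")
})

fake_records <- function(collocates, counts, decade = 1900L,
                         term = "elderly") {
  tibble::tibble(
    term = term, framing = "age_based", decade = decade,
    collocate = collocates, cooccurrence_count = counts,
    target_freq = 10L, collocate_freq = 5L, N = 1000L, mi = 5
  )
}

test_that("synonym-decade means are count-weighted merged ratings", {
  lex <- tibble::tibble(word = c("p", "q"), rater1 = c(2, 4),
                        rater2 = c(2, 4), merged_rating = c(2, 4))
  # single collocate: mean equals its rating whatever the count
  m1 <- synonym_decade_means(fake_records("p", 7L), lex)
  expect_equal(m1$mean_valence, 2)
  # ratings 2 and 4 with counts 1 and 3 -> 3.5
  m2 <- synonym_decade_means(fake_records(c("p", "q"), c(1L, 3L)), lex)
  expect_equal(m2$mean_valence, 3.5)
  # unweighted mode
  m3 <- synonym_decade_means(fake_records(c("p", "q"), c(1L, 3L)), lex,
                             weighted = FALSE)
  expect_equal(m3$mean_valence, 3)
  # all-neutral corpus pins the mean at 3
  lex3 <- tibble::tibble(word = c("p", "q"), merged_rating = c(3, 3))
  m4 <- synonym_decade_means(fake_records(c("p", "q"), c(2L, 9L)), lex3)
  expect_equal(m4$mean_valence, 3)
})

test_that("unrated collocates follow the configured policy", {
  lex <- tibble::tibble(word = "p", merged_rating = 3)
  rec <- fake_records(c("p", "mystery"), c(1L, 1L))
  expect_error(synonym_decade_means(rec, lex), "mystery")
  expect_warning(m <- synonym_decade_means(rec, lex, on_missing = "skip"),
                 "skipped")
  expect_equal(m$mean_valence, 3)
})

test_that("the narrative score is the frequency-weighted convex combination", {
  means <- tibble::tibble(
    term = c("elderly", "aged"), framing = "age_based",
    decade = 1900L, mean_valence = c(2, 4), n_collocates = 1L
  )
  freqs <- tibble::tibble(term = c("elderly", "aged"), decade = 1900L,
                          synonym_freq = c(1L, 3L))
  s <- cumulative_narrative_score(means, freqs)
  expect_equal(s$cans, 3.5)
  expect_equal(s$total_freq, 4L)

  # single synonym: CANS equals its mean
  s1 <- cumulative_narrative_score(means[1, ], freqs[1, ])
  expect_equal(s1$cans, 2)

  # equal means are weight-invariant; scaling weights changes nothing
  means$mean_valence <- c(3.3, 3.3)
  expect_equal(cumulative_narrative_score(means, freqs)$cans, 3.3)
  freqs2 <- dplyr::mutate(freqs, synonym_freq = synonym_freq * 17L)
  means$mean_valence <- c(2, 4)
  expect_equal(cumulative_narrative_score(means, freqs2)$cans, 3.5)
})

test_that("CANS stays between the contributing synonym means", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    means <- tibble::tibble(
      term = paste0("t", 1:k), framing = "age_based", decade = 1900L,
      mean_valence = runif(k, 1, 5), n_collocates = 1L
    )
    freqs <- tibble::tibble(term = paste0("t", 1:k), decade = 1900L,
                            synonym_freq = sample(1:50, k, replace = TRUE))
    s <- cumulative_narrative_score(means, freqs)
    expect_gte(s$cans, min(means$mean_valence))
    expect_lte(s$cans, max(means$mean_valence))
    expect_true(s$cans >= 1 && s$cans <= 5)
  }
})
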