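# Evaluate code under a temporary RNG state so generators are pure
# functions of (spec, seed) and never disturb the caller's stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-corpus specification
#'
#' Describes a decade-binned corpus in which each document carries one
#' occurrence of a target term embedded in a sentence whose surrounding
#' window words are drawn from valence-stratified word pools. The expected
#' mean rating of the in-window words follows a linear per-decade trajectory
#' with a separate intercept and slope per framing, so the planted slopes are
#' recoverable by the full collocation-valence-trend pipeline. Articles are
#' interleaved at a configurable rate to exercise the span rule, and a
#' fraction of targets are placed sentence-initially to exercise the
#' preceding-sentence exclusion.
#'
#' Defaults plant the study conditions: 21 decade bins, four genres, and
#' trajectories with intercepts 3.04 (age-based) and 3.13 (role-based) and
#' per-decade slopes -0.023 and -0.0067.
#'
#' @param seed Random seed (mandatory).
#' @param decades Decade bins (default the 21 bins 1810--2010).
#' @param genres Genre labels.
#' @param docs_per_cell Documents per decade-genre cell (default 24; each
#'   document carries one target occurrence).
#' @param trajectories Tibble `framing`, `intercept`, `slope` of the mean
#'   in-window valence per decade index.
#' @param lexicon Target lexicon (default [target_terms()]).
#' @param span Window half-width the sentences are built for (default 6).
#' @param pool_size Words per integer rating bin (default 40).
#' @param filler_vocab_size Filler vocabulary size (default 500).
#' @param article_rate Probability of inserting an article before each
#'   window word (default 0.25).
#' @param sentence_initial_rate Fraction of targets placed at sentence start
#'   (default 0.1).
#' @param tokens_per_doc Approximate document length in tokens (default 200).
#' @param mean_sentence_len Mean filler sentence length (default 8).
#' @return A list of class `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(seed,
                                  decades = seq(1810L, 2010L, by = 10L),
                                  genres = c("newspapers", "magazines",
                                             "fiction", "nonfiction"),
                                  docs_per_cell = 24L,
                                  trajectories = tibble(
                                    framing = c("age_based", "role_based"),
                                    intercept = c(3.04, 3.13),
                                    slope = c(-0.023, -0.0067)
                                  ),
                                  lexicon = target_terms(),
                                  span = 6L,
                                  pool_size = 40L,
                                  filler_vocab_size = 500L,
                                  article_rate = 0.25,
                                  sentence_initial_rate = 0.1,
                                  tokens_per_doc = 200L,
                                  mean_sentence_len = 8) {
  if (missing(seed)) abort("A seed is mandatory for the corpus generator.")
  t_idx <- (decades - min(decades)) / 10
  mu <- outer(trajectories$slope, t_idx) + trajectories$intercept
  if (any(mu < 1 | mu > 5)) {
    abort("Infeasible trajectory: mean valence leaves [1, 5] within the span.")
  }
  stopifnot(pool_size >= 1, docs_per_cell >= 1, span >= 1)
  structure(list(
    seed = as.integer(seed), decades = as.integer(decades), genres = genres,
    docs_per_cell = as.integer(docs_per_cell), trajectories = trajectories,
    lexicon = lexicon, span = as.integer(span),
    pool_size = as.integer(pool_size),
    filler_vocab_size = as.integer(filler_vocab_size),
    article_rate = article_rate,
    sentence_initial_rate = sentence_initial_rate,
    tokens_per_doc = as.integer(tokens_per_doc),
    mean_sentence_len = mean_sentence_len
  ), class = "synthetic_corpus_spec")
}

valence_pools <- function(pool_size) {
  lapply(setNames(1:5, paste0("bin", 1:5)), function(b) {
    sprintf("val%d_w%03d", b, seq_len(pool_size))
  })
}

# Draw n words whose expected rating is mu by mixing the two adjacent
# integer-rating pools.
draw_valence_words <- function(n, mu, pool_size) {
  lo <- pmin(floor(mu), 4)
  frac <- mu - lo
  bins <- lo + rbinom(n, 1L, frac)
  idx <- sample.int(pool_size, n, replace = TRUE)
  sprintf("val%d_w%03d", bins, idx)
}

interleave_articles <- function(words, rate) {
  if (length(words) == 0) return(words)
  arts <- c("the", "a", "an")
  ins <- runif(length(words)) < rate
  out <- vector("list", length(words))
  art_pick <- sample(arts, length(words), replace = TRUE)
  for (i in seq_along(words)) {
    out[[i]] <- if (ins[i]) c(art_pick[i], words[i]) else words[i]
  }
  unlist(out, use.names = FALSE)
}

#' Generate a synthetic corpus with known ground truth
#'
#' Builds documents according to a [synthetic_corpus_spec()]: each document
#' contains one target sentence (the target term surrounded by exactly
#' `span` valence-pool words on each side, or on the right only when
#' sentence-initial, with articles interleaved) plus neutral filler
#' sentences drawn from a disjoint filler vocabulary. Pool words appear only
#' inside target windows, so their mutual information with the targets is
#' high and the downstream MI filter retains them without valence bias.
#' Deterministic for a given spec (same seed, byte-identical corpus).
#'
#' @param spec A [synthetic_corpus_spec()].
#' @return A list with `documents` (a corpus tibble for [tokenize_corpus()])
#'   and `ground_truth` (planted trajectories, true word ratings, the spec).
#' @export
generate_corpus <- function(spec) {
  with_local_seed(spec$seed, {
    cells <- tidyr::expand_grid(decade = spec$decades, genre = spec$genres)
    framings <- spec$trajectories$framing
    lex_by_framing <- split(spec$lexicon$term, spec$lexicon$framing)

    docs <- tidyr::expand_grid(cells, slot = seq_len(spec$docs_per_cell)) %>%
      mutate(
        framing = framings[(.data$slot - 1L) %% length(framings) + 1L],
        doc_id = sprintf("d%05d", dplyr::row_number())
      )
    # cycle each framing's terms so every synonym occurs in every cell block
    docs <- docs %>%
      group_by(.data$decade, .data$genre, .data$framing) %>%
      mutate(term = {
        terms <- lex_by_framing[[.data$framing[1]]]
        terms[(seq_len(dplyr::n()) - 1L) %% length(terms) + 1L]
      }) %>%
      ungroup()

    t_idx <- (docs$decade - min(spec$decades)) / 10
    traj <- spec$trajectories
    mu <- traj$intercept[match(docs$framing, traj$framing)] +
      traj$slope[match(docs$framing, traj$framing)] * t_idx

    filler <- sprintf("flr_w%04d", seq_len(spec$filler_vocab_size))
    sent_initial <- runif(nrow(docs)) < spec$sentence_initial_rate

    texts <- character(nrow(docs))
    for (i in seq_len(nrow(docs))) {
      n_side <- spec$span
      target_toks <- strsplit(docs$term[i], " ", fixed = TRUE)[[1]]
      if (sent_initial[i]) {
        right <- draw_valence_words(n_side, mu[i], spec$pool_size)
        sent <- c(target_toks, interleave_articles(right, spec$article_rate))
      } else {
        w <- draw_valence_words(2 * n_side, mu[i], spec$pool_size)
        sent <- c(interleave_articles(w[seq_len(n_side)], spec$article_rate),
                  target_toks,
                  interleave_articles(w[(n_side + 1):(2 * n_side)],
                                      spec$article_rate))
      }
      sent[length(sent)] <- paste0(sent[length(sent)], ".")

      n_fill <- max(0L, spec$tokens_per_doc - length(sent))
      fill_sents <- list()
      while (n_fill > 0) {
        len <- min(n_fill, rpois(1, spec$mean_sentence_len) + 2L)
        fs <- sample(filler, len, replace = TRUE)
        fs[len] <- paste0(fs[len], ".")
        fill_sents[[length(fill_sents) + 1L]] <- fs
        n_fill <- n_fill - len
      }
      n_s <- length(fill_sents)
      pos <- if (n_s == 0) 1L
             else if (sent_initial[i]) sample(2:(n_s + 1L), 1L)
             else sample.int(n_s + 1L, 1L)
      parts <- append(fill_sents, list(sent), after = pos - 1L)
      texts[i] <- paste(unlist(parts, use.names = FALSE), collapse = " ")
    }

    documents <- tibble(
      doc_id = docs$doc_id,
      year = docs$decade + sample.int(10, nrow(docs), replace = TRUE) - 1L,
      genre = docs$genre,
      text = texts
    )
    # candidate = a potential collocate (valence-pool word); filler words are
    # rated neutral but never land inside a target window
    word_ratings <- bind_rows(
      tibble(word = unlist(valence_pools(spec$pool_size), use.names = FALSE),
             rating = rep(1:5, each = spec$pool_size), is_candidate = TRUE),
      tibble(word = filler, rating = 3L, is_candidate = FALSE)
    )
    list(
      documents = documents,
      ground_truth = list(
        trajectories = spec$trajectories,
        word_ratings = word_ratings,
        sentence_initial = sum(sent_initial),
        spec = spec
      )
    )
  })
}

#' Generate a two-rater valence lexicon from true ratings
#'
#' Rater 1 reports the true integer rating; rater 2 adds rounded Gaussian
#' noise, clipped to \[1, 5\]. With `rater_noise_sd = 0`, the raters are
#' identical and Cronbach's alpha is 1. The default noise level (sd 0.4)
#' puts the interrater reliability of a uniformly valence-spread lexicon in
#' the alpha-near-0.97 regime.
#'
#' @param word_ratings Tibble `word`, `rating` (true integer ratings, e.g.
#'   from [generate_corpus()] ground truth).
#' @param rater_noise_sd Standard deviation of rater 2's pre-rounding noise.
#' @param seed Random seed.
#' @return A valence lexicon tibble (`word`, `rater1`, `rater2`,
#'   `merged_rating`).
#' @export
generate_lexicon <- function(word_ratings, rater_noise_sd = 0.4, seed = 1L) {
  stopifnot(rater_noise_sd >= 0)
  with_local_seed(seed, {
    r1 <- word_ratings$rating
    noise <- round(rnorm(length(r1), 0, rater_noise_sd))
    r2 <- pmin(pmax(r1 + noise, 1), 5)
    suppressWarnings(merge_raters(tibble(
      word = word_ratings$word, rater1 = as.numeric(r1),
      rater2 = as.numeric(r2)
    )))
  })
}

#' Generate collocate bags from planted topic mixtures
#'
#' For each framing-by-century stratum, plants `n_topics` topics with
#' disjoint vocabularies; the first `n_positive` are positive (true word
#' ratings 4--5), the rest negative (ratings 1--2). Documents are drawn from
#' a single planted topic each, giving a corpus whose topic structure and
#' positivity proportions are known exactly.
#'
#' @param mixtures Tibble `framing`, `century`, `n_topics`, `n_positive`.
#' @param docs_per_topic Documents per planted topic (default 20).
#' @param words_per_doc Tokens per document (default 40).
#' @param vocab_per_topic Vocabulary size per planted topic (default 25).
#' @param seed Random seed.
#' @return A list: `bags` (stratum bag tibble for [fit_lda()]),
#'   `word_ratings` (true ratings for [generate_lexicon()]), `planted`
#'   (per-stratum list of topic vocabularies and `n_positive`).
#' @export
generate_topic_corpus <- function(mixtures, docs_per_topic = 20L,
                                  words_per_doc = 40L, vocab_per_topic = 25L,
                                  seed = 1L) {
  stopifnot(all(mixtures$n_positive <= mixtures$n_topics),
            all(mixtures$n_topics >= 1))
  with_local_seed(seed, {
    bags <- list()
    ratings <- list()
    planted <- list()
    for (i in seq_len(nrow(mixtures))) {
      fr <- mixtures$framing[i]
      ce <- mixtures$century[i]
      K <- mixtures$n_topics[i]
      npos <- mixtures$n_positive[i]
      key <- paste(fr, ce, sep = "|")
      vocabs <- lapply(seq_len(K), function(k) {
        sprintf("s%02d_t%02d_w%03d", i, k, seq_len(vocab_per_topic))
      })
      is_pos <- seq_len(K) <= npos
      ratings[[i]] <- tibble(
        word = unlist(vocabs, use.names = FALSE),
        rating = unlist(lapply(seq_len(K), function(k) {
          if (is_pos[k]) sample(4:5, vocab_per_topic, replace = TRUE)
          else sample(1:2, vocab_per_topic, replace = TRUE)
        }), use.names = FALSE)
      )
      rows <- list()
      for (k in seq_len(K)) {
        for (dnum in seq_len(docs_per_topic)) {
          words <- sample(vocabs[[k]], words_per_doc, replace = TRUE)
          tb <- table(words)
          rows[[length(rows) + 1L]] <- tibble(
            framing = fr, century = ce,
            doc = sprintf("s%02d_k%02d_d%03d", i, k, dnum),
            word = names(tb), count = as.integer(tb)
          )
        }
      }
      bags[[i]] <- bind_rows(rows)
      planted[[key]] <- list(vocabs = setNames(vocabs,
                                               sprintf("planted%02d",
                                                       seq_len(K))),
                             n_positive = npos, n_topics = K)
    }
    list(bags = bind_rows(bags), word_ratings = bind_rows(ratings),
         planted = planted)
  })
}

#' Default planted topic mixtures
#'
#' The framing-by-century positivity regime the generator plants by default:
#' role-based positivity rising across centuries, age-based positivity
#' falling sharply, with per-stratum topic counts in the single digits to
#' low teens.
#'
#' @return Tibble `framing`, `century`, `n_topics`, `n_positive`.
#' @export
default_topic_mixtures <- function() {
  tibble(
    framing = c("age_based", "age_based", "role_based", "role_based"),
    century = c("1800s", "1900s", "1800s", "1900s"),
    n_topics = c(11L, 13L, 7L, 9L),
    n_positive = c(9L, 5L, 5L, 8L)
  )
}
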