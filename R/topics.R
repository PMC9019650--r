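#' Century bin of a decade
#'
#' Decade bins 1800--1890 map to `"1800s"`, 1900--1990 to `"1900s"`; other
#' decades (the 2000s and 2010s bins) map to `NA` and are excluded from the
#' century contrast.
#'
#' @param decade Integer decade labels.
#' @return Character vector (`"1800s"`, `"1900s"`, or `NA`).
#' @export
century_of <- function(decade) {
  dplyr::case_when(
    decade >= 1800 & decade <= 1890 ~ "1800s",
    decade >= 1900 & decade <= 1990 ~ "1900s",
    TRUE ~ NA_character_
  )
}

#' Topic-model configuration
#'
#' @param n_topics Topics per stratum (default 4, echoing typical per-genre
#'   narrative counts of 2--6).
#' @param alpha Symmetric document-topic concentration (default 1.0).
#' @param beta Symmetric topic-word concentration (default 0.1).
#' @param top_k Top words used to label a topic (default 10).
#' @param n_iter Gibbs sweeps (default 200).
#' @param threshold Valence below which a topic is labelled negative
#'   (default 3, the neutral anchor; the comparison is strict `<`).
#' @param seed Random seed; recorded in all outputs.
#' @return A list of class `topic_model_spec`.
#' @export
topic_model_spec <- function(n_topics = 4L, alpha = 1.0, beta = 0.1,
                             top_k = 10L, n_iter = 200L, threshold = 3,
                             seed = 1L) {
  stopifnot(n_topics >= 2, top_k >= 1, alpha > 0, beta > 0, n_iter >= 1)
  structure(list(n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
                 top_k = as.integer(top_k), n_iter = as.integer(n_iter),
                 threshold = threshold, seed = as.integer(seed)),
            class = "topic_model_spec")
}

#' Build per-stratum collocate bags for topic modeling
#'
#' Each document is the multiset of one synonym-decade's retained collocates
#' (co-occurrence counts preserved), grouped into framing-by-century
#' (optionally by genre) strata. Decades outside the two-century contrast
#' are dropped.
#'
#' @param records Retained collocate records (see [filter_collocates()]).
#' @param by_genre Also stratify by genre (requires a `genre` column).
#' @return Long tibble: stratum columns (`framing`, `century`, optionally
#'   `genre`), `doc` (synonym-decade id), `word`, `count`. Strata with fewer
#'   documents than typical topic counts are listed in the
#'   `flagged_strata` attribute.
#' @export
build_topic_documents <- function(records, by_genre = FALSE) {
  strata <- c("framing", "century", if (by_genre) "genre")
  if (by_genre && !"genre" %in% names(records)) {
    abort("by_genre = TRUE but records have no genre column.")
  }
  out <- records %>%
    mutate(century = century_of(.data$decade)) %>%
    filter(!is.na(.data$century)) %>%
    mutate(doc = paste(.data$term, .data$decade, sep = ":")) %>%
    group_by(across(all_of(strata)), .data$doc, word = .data$collocate) %>%
    summarise(count = sum(.data$cooccurrence_count), .groups = "drop")
  if (nrow(out) == 0) warn("No records fall inside the century contrast.")
  flagged <- out %>%
    group_by(across(all_of(strata))) %>%
    summarise(n_docs = n_distinct(.data$doc), .groups = "drop") %>%
    filter(.data$n_docs < 2)
  attr(out, "flagged_strata") <- flagged
  out
}

#' Fit seeded LDA topic models per stratum
#'
#' Latent Dirichlet Allocation by collapsed Gibbs sampling (fixed sweep
#' count), fitted independently within each stratum of the bag tibble. Runs
#' are deterministic for a given spec seed: each stratum's sampler seed is
#' derived from the spec seed and the stratum's position in sorted order.
#'
#' @param bags Output of [build_topic_documents()].
#' @param spec A [topic_model_spec()].
#' @return An `lda_topics` object: `$topics` (stratum columns, `topic_id`,
#'   `rank`, `word`, `prob` for the top `top_k` words), `$phi` (named list of
#'   topic-word probability matrices, vocabulary in columns), `$spec`.
#' @export
fit_lda <- function(bags, spec = topic_model_spec()) {
  strata_cols <- intersect(c("framing", "century", "genre"), names(bags))
  key <- do.call(paste, c(bags[strata_cols], sep = "|"))
  groups <- split(bags, key)
  groups <- groups[order(names(groups))]

  topics <- vector("list", length(groups))
  phis <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    vocab <- sort(unique(g$word))
    if (length(vocab) < spec$n_topics) {
      abort(paste0("Stratum '", names(groups)[i], "' vocabulary (",
                   length(vocab), ") smaller than n_topics (",
                   spec$n_topics, ")."))
    }
    docs <- sort(unique(g$doc))
    doc_id <- rep.int(match(g$doc, docs), g$count) - 1L
    word_id <- rep.int(match(g$word, vocab), g$count) - 1L
    sub_seed <- (spec$seed + 7919L * i) %% 2147483647L
    fit <- lda_gibbs_cpp(doc_id, word_id, length(docs), length(vocab),
                         spec$n_topics, spec$alpha, spec$beta,
                         spec$n_iter, sub_seed)
    phi <- fit$phi
    colnames(phi) <- vocab
    phis[[i]] <- phi
    top <- purrr::map_dfr(seq_len(nrow(phi)), function(k) {
      ord <- order(phi[k, ], decreasing = TRUE)[seq_len(min(spec$top_k,
                                                            ncol(phi)))]
      tibble(topic_id = k, rank = seq_along(ord),
             word = vocab[ord], prob = phi[k, ord])
    })
    topics[[i]] <- dplyr::bind_cols(
      g[rep(1, nrow(top)), strata_cols, drop = FALSE], top
    )
  }
  names(phis) <- names(groups)
  structure(list(topics = bind_rows(topics), phi = phis, spec = spec,
                 strata_cols = strata_cols),
            class = "lda_topics")
}

#' @export
print.lda_topics <- function(x, ...) {
  cat(sprintf("LDA topics: %d strata x %d topics (seed %d)\n",
              length(x$phi), x$spec$n_topics, x$spec$seed))
  print(x$topics)
  invisible(x)
}

#' @export
tidy.lda_topics <- function(x, ...) x$topics

#' Classify topics as positive/neutral or negative
#'
#' A topic's valence is the mean merged rating of its top words; it is
#' labelled `"negative"` iff that mean is strictly below the threshold
#' (default 3, the neutral anchor), else `"positive_neutral"`. Unrated top
#' words are dropped from the mean with a warning; a topic with no rated top
#' word is an error.
#'
#' @param topics An `lda_topics` object from [fit_lda()], or its `$topics`
#'   tibble.
#' @param lexicon Valence lexicon with `word`, `merged_rating`.
#' @param threshold Neutral threshold (default taken from the fitted spec,
#'   else 3).
#' @return Tibble: stratum columns, `topic_id`, `mean_top_valence`, `label`.
#' @export
classify_topic_valence <- function(topics, lexicon, threshold = NULL) {
  if (inherits(topics, "lda_topics")) {
    threshold <- threshold %||% topics$spec$threshold
    strata_cols <- topics$strata_cols
    topics <- topics$topics
  } else {
    threshold <- threshold %||% 3
    strata_cols <- intersect(c("framing", "century", "genre"), names(topics))
  }
  joined <- topics %>%
    left_join(select(lexicon, word = "word", merged_rating = "merged_rating"),
              by = "word")
  n_unrated <- sum(is.na(joined$merged_rating))
  if (n_unrated > 0) {
    warn(paste0(n_unrated, " unrated top word(s) dropped from topic means."))
  }
  out <- joined %>%
    group_by(across(all_of(c(strata_cols, "topic_id")))) %>%
    summarise(
      mean_top_valence = mean(.data$merged_rating, na.rm = TRUE),
      n_rated = sum(!is.na(.data$merged_rating)),
      .groups = "drop"
    )
  if (any(out$n_rated == 0)) abort("A topic has no rated top words.")
  out %>%
    mutate(label = ifelse(.data$mean_top_valence < threshold,
                          "negative", "positive_neutral")) %>%
    select(-"n_rated")
}

#' Positive/neutral topic proportions per cell
#'
#' @param labels Output of [classify_topic_valence()].
#' @param by Cell columns (default framing by century, pooling genres).
#' @return Tibble: cells, `n_topics_total`, `n_positive_neutral`,
#'   `proportion_positive_neutral`.
#' @export
positivity_proportions <- function(labels, by = c("framing", "century")) {
  labels %>%
    group_by(across(all_of(by))) %>%
    summarise(
      n_topics_total = dplyr::n(),
      n_positive_neutral = sum(.data$label == "positive_neutral"),
      proportion_positive_neutral = .data$n_positive_neutral /
        .data$n_topics_total,
      .groups = "drop"
    )
}

#' Purity of fitted topics against planted vocabularies
#'
#' For validation on synthetic corpora with known topic vocabularies: each
#' fitted topic's purity is the largest share of its probability mass (over
#' words belonging to any planted topic) that falls on a single planted
#' topic's vocabulary; the result is the mean over fitted topics.
#'
#' @param phi Topic-word probability matrix (topics in rows, named columns).
#' @param planted Named list of character vectors: planted topic
#'   vocabularies.
#' @return Purity in \[0, 1\].
#' @export
topic_purity <- function(phi, planted) {
  shares <- vapply(seq_len(nrow(phi)), function(k) {
    mass <- vapply(planted, function(v) {
      sum(phi[k, colnames(phi) %in% v])
    }, double(1))
    if (sum(mass) == 0) return(NA_real_)
    max(mass) / sum(mass)
  }, double(1))
  mean(shares, na.rm = TRUE)
}

#' Plot positivity proportions across centuries
#'
#' Grouped bar chart of the percentage of positive/neutral topics per
#' framing and century.
#'
#' @param summary Output of [positivity_proportions()].
#' @return A ggplot object.
#' @export
plot_positivity <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$century, y = 100 * .data$proportion_positive_neutral,
    fill = .data$framing
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Century", y = "Positive/neutral topics (%)",
                  fill = "Framing") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
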