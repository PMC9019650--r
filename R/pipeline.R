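#' Pipeline configuration
#'
#' Collects the paths and options every pipeline stage needs. Either build
#' it directly or read it from a YAML/JSON file with [read_pipeline_config()].
#'
#' @param corpus Corpus file path, or an in-memory corpus tibble.
#' @param corpus_dialect Corpus file dialect (see [read_corpus()]).
#' @param target_lexicon Target-lexicon TSV path or tibble (default
#'   [target_terms()]).
#' @param valence_lexicon Valence-lexicon TSV path or tibble with a
#'   `merged_rating` column.
#' @param exclusion Optional exclusion list (path, character vector, or
#'   tibble; see [filter_collocates()]).
#' @param window A [window_config()].
#' @param topics A [topic_model_spec()].
#' @param origin Decade index origin for trend fits (default 1810).
#' @param weighted Count-weighted synonym means (default TRUE).
#' @param by_genre Stratify topic models by genre (default FALSE).
#' @param out_dir Optional output directory; when set, stage CSVs are
#'   written there with provenance headers.
#' @param seed Seed recorded in provenance metadata and used for topic
#'   modeling if `topics` carries no explicit seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, corpus_dialect = "jsonl",
                            target_lexicon = target_terms(),
                            valence_lexicon, exclusion = NULL,
                            window = window_config(),
                            topics = topic_model_spec(),
                            origin = 1810L, weighted = TRUE,
                            by_genre = FALSE, out_dir = NULL, seed = 1L) {
  structure(list(
    corpus = corpus, corpus_dialect = corpus_dialect,
    target_lexicon = target_lexicon, valence_lexicon = valence_lexicon,
    exclusion = exclusion, window = window, topics = topics,
    origin = as.integer(origin), weighted = isTRUE(weighted),
    by_genre = isTRUE(by_genre), out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with top-level keys matching the
#' arguments of [pipeline_config()]; `window` and `topics` are nested maps
#' passed to [window_config()] and [topic_model_spec()].
#'
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  win <- do.call(window_config, y$window %||% list())
  top <- do.call(topic_model_spec, y$topics %||% list())
  pipeline_config(
    corpus = y$corpus, corpus_dialect = y$corpus_dialect %||% "jsonl",
    target_lexicon = y$target_lexicon %||% target_terms(),
    valence_lexicon = y$valence_lexicon,
    exclusion = y$exclusion,
    window = win, topics = top,
    origin = y$origin %||% 1810L,
    weighted = y$weighted %||% TRUE,
    by_genre = y$by_genre %||% FALSE,
    out_dir = y$out_dir, seed = y$seed %||% 1L
  )
}

resolve_corpus <- function(config) {
  if (is.character(config$corpus)) {
    read_corpus(config$corpus, dialect = config$corpus_dialect)
  } else {
    as_tibble(config$corpus)
  }
}

resolve_target_lexicon <- function(config) {
  if (is.character(config$target_lexicon)) {
    read_target_lexicon(config$target_lexicon)
  } else {
    as_tibble(config$target_lexicon)
  }
}

resolve_valence_lexicon <- function(config) {
  lex <- config$valence_lexicon
  if (is.character(lex)) lex <- read_valence_lexicon(lex)
  lex <- as_tibble(lex)
  if (!"merged_rating" %in% names(lex)) lex <- merge_raters(lex)
  lex
}

resolve_exclusion <- function(config) {
  ex <- config$exclusion
  if (is.character(ex) && length(ex) == 1 && file.exists(ex)) {
    ex <- read_exclusion_list(ex)
  }
  ex
}

write_stage_csv <- function(x, name, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, paste0(name, ".csv"))
  hash <- substr(rlang::hash(config[c("window", "topics", "origin",
                                      "weighted", "by_genre", "seed")]),
                 1, 12)
  header <- sprintf("# agenarr %s | seed %d | config %s",
                    as.character(utils::packageVersion("agenarr")),
                    config$seed, hash)
  writeLines(header, path)
  suppressWarnings(readr::write_csv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Run the trend analysis end to end
#'
#' Reads or takes the corpus, tokenizes it, extracts and filters collocates
#' per decade, scores synonym-decade valences, builds the per-framing
#' narrative-score series, fits the per-framing decade trends, and tests the
#' slope difference. Stage record counts are reported via messages so an
#' audit line (documents read, occurrences found, collocates retained and
#' dropped) can be reproduced on any input.
#'
#' @param config A [pipeline_config()].
#' @return A list: `collocates` (retained records), `scores` (the
#'   narrative-score series), `trend` (a `trend_fit`), `comparison` (a
#'   `slope_comparison`), `audit` (named counts).
#' @export
run_h1 <- function(config) {
  docs <- resolve_corpus(config)
  lexicon <- resolve_target_lexicon(config)
  vlex <- resolve_valence_lexicon(config)
  tokens <- tokenize_corpus(docs)
  occ <- find_target_occurrences(tokens, lexicon)
  if (nrow(occ) == 0) abort("No target occurrences found in the corpus.")
  records <- extract_collocates(tokens, lexicon, cfg = config$window,
                                by = "decade")
  retained <- filter_collocates(records, cfg = config$window,
                                exclusion = resolve_exclusion(config))
  syn_means <- synonym_decade_means(retained, vlex,
                                    weighted = config$weighted)
  syn_freqs <- synonym_frequencies(occ)
  scores <- cumulative_narrative_score(syn_means, syn_freqs)
  trend <- fit_decade_trend(scores, origin = config$origin)
  comparison <- compare_slopes(scores, origin = config$origin)
  audit <- c(
    documents = nrow(docs), tokens = nrow(tokens), occurrences = nrow(occ),
    collocate_records = nrow(records), retained = nrow(retained),
    dropped = nrow(records) - nrow(retained)
  )
  inform(paste0("h1 audit: ", paste(names(audit), audit, sep = "=",
                                    collapse = ", ")))
  write_stage_csv(retained, "collocates", config)
  write_stage_csv(scores, "scores", config)
  write_stage_csv(tidy(trend), "trend_report", config)
  write_stage_csv(as_tibble(comparison), "comparison", config)
  list(collocates = retained, scores = scores, trend = trend,
       comparison = comparison, audit = audit)
}

#' Run the topic-valence analysis end to end
#'
#' Builds per-stratum collocate bags for the two-century contrast, fits
#' seeded LDA per stratum, classifies topic valence with the merged lexicon,
#' summarises positivity proportions, and runs the two-way mixed ANOVA on
#' topic positivity. The ANOVA unit is a topic slot paired across centuries
#' within a framing (slots beyond the smaller century's topic count are
#' dropped); see the package vignette for why this pairing is a documented
#' choice rather than a reconstruction.
#'
#' @param config A [pipeline_config()].
#' @param collocates Optional retained collocate records (from [run_h1()]);
#'   when omitted, the collocation stages are run in-line.
#' @return A list: `topics` (an `lda_topics`), `labels`, `summary`
#'   (positivity proportions), `anova_table` (the long-format unit table),
#'   `anova` (a `mixed_anova`).
#' @export
run_h2 <- function(config, collocates = NULL) {
  vlex <- resolve_valence_lexicon(config)
  if (is.null(collocates)) {
    docs <- resolve_corpus(config)
    lexicon <- resolve_target_lexicon(config)
    tokens <- tokenize_corpus(docs)
    by <- c("decade", if (config$by_genre) "genre")
    records <- extract_collocates(tokens, lexicon, cfg = config$window,
                                  by = by)
    collocates <- filter_collocates(records, cfg = config$window,
                                    exclusion = resolve_exclusion(config))
  }
  bags <- build_topic_documents(collocates, by_genre = config$by_genre)
  if (nrow(bags) == 0) abort("No collocates inside the century contrast.")
  spec <- config$topics
  spec$seed <- spec$seed %||% config$seed
  topics <- fit_lda(bags, spec)
  labels <- classify_topic_valence(topics, vlex)
  summary <- positivity_proportions(labels)
  anova_table <- pair_topics_across_centuries(labels)
  anova <- two_way_mixed_anova(anova_table)
  write_stage_csv(topics$topics, "topics", config)
  write_stage_csv(labels, "labels", config)
  write_stage_csv(summary, "summary", config)
  write_stage_csv(tidy(anova), "anova", config)
  list(topics = topics, labels = labels, summary = summary,
       anova_table = anova_table, anova = anova)
}

#' Pair topic positivity across centuries into a mixed-design table
#'
#' Builds the long-format unit table for [two_way_mixed_anova()]: within
#' each framing (and genre, if present), the i-th topic of the 1800s is
#' paired with the i-th topic of the 1900s; unpaired surplus topics are
#' dropped. The response is binary topic positivity (1 = positive/neutral).
#'
#' @param labels Output of [classify_topic_valence()].
#' @return Long tibble `unit_id`, `framing`, `century`, `response`.
#' @export
pair_topics_across_centuries <- function(labels) {
  gcols <- intersect(c("framing", "genre"), names(labels))
  labels %>%
    group_by(across(all_of(c(gcols, "century")))) %>%
    mutate(slot = dplyr::row_number()) %>%
    ungroup() %>%
    group_by(across(all_of(c(gcols, "slot")))) %>%
    filter(dplyr::n() == 2) %>%
    ungroup() %>%
    mutate(
      unit_id = do.call(paste, c(dplyr::pick(all_of(c(gcols, "slot"))),
                                 sep = ":")),
      response = as.integer(.data$label == "positive_neutral")
    ) %>%
    select("unit_id", "framing", "century", "response")
}
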