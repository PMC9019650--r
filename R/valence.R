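#' Read a two-rater valence lexicon
#'
#' TSV with header columns `word`, `rater1`, `rater2`; ratings on the 1
#' (very negative) to 5 (very positive) stereotype-valence scale, integers or
#' halves. The merged rating is the mean of the two raters.
#'
#' @param path TSV file path.
#' @param audit_threshold Absolute rater divergence above which a word is
#'   reported in a warning (audit aid; nothing is dropped).
#' @return Tibble `word`, `rater1`, `rater2`, `merged_rating`.
#' @export
read_valence_lexicon <- function(path, audit_threshold = 2) {
  lex <- readr::read_tsv(path, col_types = readr::cols(
    word = readr::col_character(),
    rater1 = readr::col_double(),
    rater2 = readr::col_double()
  ), progress = FALSE)
  merge_raters(as_tibble(lex), audit_threshold = audit_threshold)
}

#' Merge two raters' valence ratings
#'
#' @param lexicon Tibble with `word`, `rater1`, `rater2` in \[1, 5\].
#' @inheritParams read_valence_lexicon
#' @return The lexicon with a `merged_rating` column (mean of the raters).
#' @export
merge_raters <- function(lexicon, audit_threshold = 2) {
  stopifnot(all(c("word", "rater1", "rater2") %in% names(lexicon)))
  r <- cbind(lexicon$rater1, lexicon$rater2)
  if (any(r < 1 | r > 5, na.rm = TRUE)) {
    abort("Ratings must lie in [1, 5].")
  }
  div <- abs(lexicon$rater1 - lexicon$rater2)
  big <- which(div > audit_threshold)
  if (length(big) > 0) {
    warn(paste0(length(big), " word(s) with rater divergence > ",
                audit_threshold, ": ",
                paste(head(lexicon$word[big], 10), collapse = ", ")))
  }
  mutate(lexicon, merged_rating = (.data$rater1 + .data$rater2) / 2)
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' Interrater (internal-consistency) reliability for an items-by-raters
#' table: `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` using sample
#' variances of each rater's scores over items and of the item total scores.
#' The 95% confidence interval uses Feldt's method: bounds
#' `1 - (1 - alpha) * qf(p, n - 1, (n - 1)(k - 1))` at p = 0.975 and 0.025.
#'
#' @param ratings Matrix or data frame, one row per rated item, one column
#'   per rater (at least 3 items and 2 raters).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `reliability` with elements `alpha`, `ci_low`,
#'   `ci_high`, `n_items`, `k_raters`, `conf_level`.
#' @examples
#' cronbach_alpha(cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(2, 3, 4, 5, 5)))
#' @export
cronbach_alpha <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) abort("Need at least 3 rated items.")
  if (k < 2) abort("Need at least 2 raters.")
  v_tot <- var(rowSums(m))
  if (v_tot <= 0) abort("Zero total-score variance: alpha undefined.")
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / v_tot)
  p <- 1 - (1 - conf_level) / 2
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci <- 1 - (1 - alpha) * qf(c(p, 1 - p), df1, df2)
  structure(list(
    alpha = alpha, ci_low = ci[1], ci_high = ci[2],
    n_items = n, k_raters = k, conf_level = conf_level
  ), class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d%% CI: %.3f, %.3f), %d items, %d raters\n",
              x$alpha, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_items, x$k_raters))
  invisible(x)
}

#' @export
tidy.reliability <- function(x, ...) {
  tibble(alpha = x$alpha, ci_low = x$ci_low, ci_high = x$ci_high,
         n_items = x$n_items, k_raters = x$k_raters)
}

#' @export
glance.reliability <- function(x, ...) tidy.reliability(x)

#' Per-synonym, per-decade mean collocate valence
#'
#' Joins retained collocate records to the merged valence lexicon and
#' averages, for each target synonym in each decade, the merged ratings of
#' its collocates. By default the mean is weighted by co-occurrence count
#' (repeated association weighs more); an unweighted mode is available.
#'
#' @param records Retained collocate records (see [filter_collocates()]).
#' @param lexicon Valence lexicon with `word` and `merged_rating` (see
#'   [merge_raters()]).
#' @param weighted Weight collocates by `cooccurrence_count` (default TRUE).
#' @param on_missing What to do with collocates absent from the lexicon:
#'   `"error"` (default, lists the missing words) or `"skip"` (drop with a
#'   warning).
#' @return Tibble `term`, `framing`, `decade`, `mean_valence`,
#'   `n_collocates`.
#' @export
synonym_decade_means <- function(records, lexicon, weighted = TRUE,
                                 on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  joined <- records %>%
    left_join(select(lexicon, word = "word", merged_rating = "merged_rating"),
              by = c(collocate = "word"))
  miss <- joined %>% filter(is.na(.data$merged_rating))
  if (nrow(miss) > 0) {
    words <- sort(unique(miss$collocate))
    msg <- paste0(length(words), " collocate(s) missing from the valence ",
                  "lexicon: ", paste(head(words, 20), collapse = ", "))
    if (on_missing == "error") abort(msg)
    warn(paste0(msg, "; skipped."))
    joined <- filter(joined, !is.na(.data$merged_rating))
  }
  joined %>%
    mutate(w = if (weighted) .data$cooccurrence_count else 1) %>%
    group_by(.data$term, .data$framing, .data$decade) %>%
    summarise(
      mean_valence = sum(.data$w * .data$merged_rating) / sum(.data$w),
      n_collocates = dplyr::n(),
      .groups = "drop"
    )
}

#' Synonym frequencies per decade
#'
#' Occurrence counts of each target synonym per stratum; the weights of the
#' cumulative narrative score.
#'
#' @param occurrences Output of [find_target_occurrences()].
#' @param by Stratum columns (default `"decade"`).
#' @return Tibble `term`, strata, `synonym_freq`.
#' @export
synonym_frequencies <- function(occurrences, by = "decade") {
  occurrences %>%
    count(.data$term, across(all_of(by)), name = "synonym_freq")
}

#' Cumulative narrative score per framing and decade
#'
#' The frequency-weighted mean, over a framing's synonyms, of the per-synonym
#' mean collocate valences: the weight of each synonym is how often it
#' appeared in that decade. The result is a convex combination of synonym
#' means and therefore always stays within \[1, 5\]. Decades with no scored
#' synonym are absent, not zero.
#'
#' @param syn_means Output of [synonym_decade_means()].
#' @param syn_freqs Output of [synonym_frequencies()].
#' @return Tibble `framing`, `decade`, `cans`, `n_synonyms`, `total_freq`,
#'   ordered by framing and decade.
#' @export
cumulative_narrative_score <- function(syn_means, syn_freqs) {
  joined <- syn_means %>%
    inner_join(syn_freqs, by = c("term", "decade"))
  if (nrow(joined) == 0) abort("No synonym with both a mean and a frequency.")
  out <- joined %>%
    group_by(.data$framing, .data$decade) %>%
    summarise(
      cans = sum(.data$synonym_freq * .data$mean_valence) /
        sum(.data$synonym_freq),
      n_synonyms = dplyr::n(),
      total_freq = sum(.data$synonym_freq),
      .groups = "drop"
    ) %>%
    arrange(.data$framing, .data$decade)
  missing_framing <- setdiff(unique(syn_means$framing), unique(out$framing))
  if (length(missing_framing) > 0) {
    abort(paste0("Framing(s) with no scorable synonyms: ",
                 paste(missing_framing, collapse = ", ")))
  }
  out
}
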