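`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force collocation oracle.
#
# Occurrence matching: per-position greedy scan, longest term first.
# Window membership: closed-form pairwise test -- a non-article token q is in
# the window of an occurrence at p iff the number of non-article tokens
# between q and the occurrence (inclusive of q) is at most `span`, subject to
# the sentence rules. This is a different formulation from the package's
# outward walk.
naive_collocates <- function(tokens, lexicon, cfg, by = "decade") {
  tokens <- tokens[order(tokens$doc_id, tokens$sentence_id, tokens$token_id), ]
  term_toks <- strsplit(tolower(lexicon$term), " ", fixed = TRUE)
  ord <- order(lengths(term_toks), decreasing = TRUE)

  all_rows <- list()
  occ_rows <- list()
  for (d in unique(tokens$doc_id)) {
    td <- tokens[tokens$doc_id == d, ]
    tok <- td$token
    sent <- td$sentence_id
    n <- length(tok)
    art <- tok %in% cfg$excluded_articles
    nonart_cum <- cumsum(!art)

    # greedy left-to-right occurrence scan
    occ <- list()
    p <- 1L
    while (p <= n) {
      matched <- FALSE
      for (i in ord) {
        tt <- term_toks[[i]]
        L <- length(tt)
        if (p + L - 1L <= n && all(tok[p:(p + L - 1L)] == tt) &&
            all(sent[p:(p + L - 1L)] == sent[p])) {
          occ[[length(occ) + 1L]] <- list(p = p, L = L, i = i)
          p <- p + L
          matched <- TRUE
          break
        }
      }
      if (!matched) p <- p + 1L
    }

    for (o in occ) {
      p0 <- o$p
      L <- o$L
      own <- tok[p0:(p0 + L - 1L)]
      initial <- td$token_id[p0] == 1L
      q <- seq_len(n)
      left <- q < p0
      right <- q > p0 + L - 1L
      dist <- rep(NA_real_, n)
      dist[left] <- nonart_cum[p0 - 1L] -
        c(0, nonart_cum)[q[left]]  # non-articles in q..p0-1, incl. q
      if (any(right)) {
        dist[right] <- nonart_cum[q[right]] - nonart_cum[p0 + L - 1L]
      }
      inw <- !art & ((left & dist <= cfg$span) | (right & dist <= cfg$span))
      if (initial) inw[left & sent < sent[p0]] <- FALSE
      if (!cfg$cross_sentence) inw[sent != sent[p0]] <- FALSE
      inw[q >= p0 & q <= p0 + L - 1L] <- FALSE
      bag <- tok[inw]
      bag <- bag[!(bag %in% own)]
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        term = lexicon$term[o$i], decade = td$decade[1], genre = td$genre[1],
        stringsAsFactors = FALSE
      )
      if (length(bag) > 0) {
        all_rows[[length(all_rows) + 1L]] <- data.frame(
          term = lexicon$term[o$i], framing = lexicon$framing[o$i],
          decade = td$decade[1], genre = td$genre[1], collocate = bag,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(all_rows) == 0) return(NULL)
  long <- do.call(rbind, all_rows)
  agg <- stats::aggregate(
    list(cooccurrence_count = rep(1L, nrow(long))),
    by = long[, c("term", "framing", by, "collocate")], FUN = sum
  )

  # marginals by plain table()
  key <- do.call(paste, c(tokens[, by, drop = FALSE], sep = "|"))
  agg_key <- do.call(paste, c(agg[, by, drop = FALSE], sep = "|"))
  Ns <- table(key)
  agg$N <- as.integer(Ns[agg_key])
  wf <- table(paste(key, tokens$token, sep = "|"))
  agg$collocate_freq <- as.integer(wf[paste(agg_key, agg$collocate, sep = "|")])

  # target frequency = occurrence count in stratum, from the oracle's scan
  occ_all <- do.call(rbind, occ_rows)
  tf <- stats::aggregate(list(target_freq = rep(1L, nrow(occ_all))),
                         by = occ_all[, c("term", by), drop = FALSE],
                         FUN = sum)
  agg <- merge(agg, tf, by = c("term", by))
  agg$mi <- log2(agg$cooccurrence_count * agg$N /
                   (agg$target_freq * agg$collocate_freq * 2 * cfg$span))
  tibble::as_tibble(agg)
}

# random messy corpus with articles, multiword targets, abbreviations and
# punctuation, for oracle-equivalence checks
make_random_corpus <- function(seed, n_docs = 12, mean_len = 120) {
  set.seed(seed)
  vocab <- c("kind", "frail", "wise", "man", "woman", "sick", "dear",
             "poor", "happy", "home", "walked", "slowly", "said", "smiled",
             "old", "people", "senior", "care")
  arts <- c("the", "a", "an")
  targets <- c("elderly", "old people", "granny", "senior citizen")
  docs <- lapply(seq_len(n_docs), function(i) {
    len <- rpois(1, mean_len) + 20
    words <- character(0)
    while (length(words) < len) {
      r <- runif(1)
      nxt <- if (r < 0.12) {
        strsplit(sample(targets, 1), " ")[[1]]
      } else if (r < 0.30) {
        sample(arts, 1)
      } else if (r < 0.33) {
        "mr."
      } else {
        sample(vocab, 1)
      }
      words <- c(words, nxt)
    }
    end <- runif(length(words)) < 0.12
    words[end] <- paste0(words[end], sample(c(".", "!", "?"),
                                            sum(end), replace = TRUE))
    tibble::tibble(
      doc_id = sprintf("rd%02d", i),
      year = sample(1810:2019, 1),
      genre = sample(c("fiction", "newspapers"), 1),
      text = paste(words, collapse = " ")
    )
  })
  dplyr::bind_rows(docs)
}

oracle_lexicon <- function() {
  tibble::tibble(
    term = c("elderly", "old people", "granny", "senior citizen"),
    framing = c("age_based", "age_based", "role_based", "age_based")
  )
}

sort_records <- function(x, by = "decade") {
  x <- x[, c("term", "framing", by, "collocate", "cooccurrence_count",
             "target_freq", "collocate_freq", "N", "mi")]
  x[do.call(order, as.list(x[, c("term", by, "collocate")])), ]
}
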