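---
title: "Measuring diachronic framing of older adults: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diachronic framing of older adults: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`agenarr` quantifies how the framing of older adults — age-based terms
(*elderly*, *aged*, *senior citizen*) versus role-based terms
(*grandmother*, *grandpa*, *granny*) — associates with stereotype valence
across decades of a historical corpus. This vignette explains the model
behind each stage, the tunable parameters and their defaults, the choices
made where the method is genuinely underdetermined, and what the
synthetic-data validation does and does not establish.

## Corpus model and tokenization

A corpus is a set of documents, each with an identifier, a calendar year
(default range 1810–2019, giving 21 decade bins via `floor(year/10)·10`),
a genre label, and raw text. The tokenizer is deliberately simple and
deterministic: whitespace splitting, lowercasing, stripping of leading and
trailing punctuation (internal hyphens and apostrophes are kept), and
sentence boundaries at tokens ending in `.`, `!`, or `?` unless the token
is a guarded abbreviation (`mr.`, `dr.`, …) or a single-letter initial.
Because no tokenizer or case policy is canonical for this kind of
analysis, these rules are explicit substitutes, not reconstructions of any
particular toolchain; collocates are surface forms, not lemmas. A
lemmatizer could be slotted in upstream of `tokenize_corpus()`, but none
is shipped: surface forms keep the pipeline free of model dependencies and
make every downstream count reproducible by hand.

## Collocate windows

The collocation stage follows the concordance conventions of large
English corpora:

* **Span.** Up to 6 content tokens on each side of the target
  (`window_config(span = 6)`).
* **Articles.** The words `a`, `an`, `the` are skipped *without consuming
  span budget* and are never collocates. The set is configuration, not a
  hard-coded closed class, because "articles such as …" is inherently
  open-ended; only the three English articles are excluded by default.
* **Sentence rule.** Windows may cross sentence boundaries (a strict
  within-sentence mode is available), with one exception: a target that
  is the first word of its sentence takes nothing from the preceding
  sentence. The single stated exception implies crossing is otherwise
  intended.
* **Self-exclusion.** The target's own tokens are never collocates of
  that occurrence; other in-window tokens equal to the target's words are
  dropped from the bag but do consume span budget like any other content
  token.
* **Overlaps.** Multiword targets are matched longest-first, then
  left-to-right; each token position feeds at most one occurrence.

Mutual information uses the window-size convention
`MI = log2(f(w,c)·N / (f(w)·f(c)·W))` with `W = 2·span`, computed per
decade stratum (genres pooled) for the trend pipeline and optionally per
decade × genre for the topic pipeline; whether genre pooling is the right
stratification is not decidable from first principles, so both modes
exist and pooling is the default. The retention rule is inclusive
(`MI ≥ 3`), with a configurable minimum co-occurrence count (default 1).
Target frequency is the occurrence count of the (possibly multiword) term
in the stratum, which a single-token marginal table cannot supply.

An exclusion list (global or per-target) stands in for the human check
that a collocate genuinely refers to an older person; nothing in the
package attempts that judgement automatically.

## Valence scoring and the narrative score

Two raters score each collocate 1 (very negative) to 5 (very positive);
integers or halves are accepted. Raters are merged by simple mean —
nothing in the measurement design privileges either rater — and
divergences above 2 points are logged for audit. Reliability is
Cronbach's α over the items × raters table with a Feldt 95% interval
(`1 − (1−α)·F_p(n−1, (n−1)(k−1))` at p = .975/.025); the Feldt method is
the standard closed-form interval for α when no method is otherwise
specified.

Per synonym and decade, the mean collocate valence is **count-weighted**
by default: a collocate seen 30 times in a decade shapes the narrative
more than one seen once, which is the priming rationale for measuring
repeated association in the first place. An unweighted mode exists
because a plain "mean score" reading is also defensible. The cumulative
narrative score per framing and decade then weights each synonym's mean
by the synonym's occurrence frequency in that decade. Decades with no
scored synonym are absent rather than zero — a zero would be a valence,
and a fabricated one.

## Trend fitting and slope comparison

Each framing's score series is fitted by OLS on the decade index with
origin 1810, so the intercept reads as the 1810 level. Percent decline
over a span of `D` decade bins is `100·(−β)·(D−1)/intercept`: a 21-bin
span contains 20 decade intervals, which is the only reading under which
the percent-decline arithmetic is internally consistent with the fitted
coefficients. The slope difference between framings is tested by pooling
both series into `cans ~ group * index` under a homoscedastic error; the
interaction's squared *t* is the *F* statistic with df (1, N − 4) — for
two complete 21-decade series, (1, 38). No autocorrelation-robust or
Welch-style variant is offered: the method under study fits straight
lines with pooled error, and matching its degrees-of-freedom structure is
part of the contract.

## Topic modeling and the century contrast

The topic stage contrasts the 1800s (decade bins 1810–1890) with the
1900s (1900–1990); the 2000 and 2010 bins fall outside a two-century
contrast and are excluded from it. Documents are per-synonym-per-decade
collocate bags (counts preserved) within framing × century (optionally
× genre) strata.

LDA is fitted by a collapsed Gibbs sampler written in C++ with a fixed
sweep count and its own RNG, so a run is a pure function of the data and
the seed (each stratum's sampler seed derives from the spec seed and the
stratum's sorted position). Defaults: `n_topics = 4` per stratum (typical
per-genre narrative counts run roughly 2–6), symmetric concentrations 1.0
(document–topic) and 0.1 (topic–word, favouring concentrated topics),
200 sweeps, top 10 words per topic. None of these is identified by the
measurement design itself; all sit in `topic_model_spec()`.

A topic is *negative* iff the mean merged valence of its top words is
strictly below 3, the scale's neutral anchor; a mean of exactly 3 is
positive/neutral. Unrated top words are dropped from the mean with a
warning; a topic with no rated top word is an error, not a guess.

## Mixed ANOVA on topic positivity

Topic positivity (binary: positive/neutral = 1) is analysed with a
two-way mixed ANOVA: framing between units, century within units. The
implementation uses the exact mean/difference-score decomposition for a
two-level within factor — between effects from unit means against
units-within-groups error, within and interaction effects from unit
difference scores against their residual error — which reduces to the
classical sums of squares when balanced and to Type III-equivalent
(unweighted-means) partitioning when group sizes differ. With two groups
and N complete units, every effect has df (1, N − 2). Only two within
levels are supported: that is the design under study, and with two levels
sphericity is vacuous. Effect sizes are partial η² =
SS_effect / (SS_effect + SS_error-for-that-effect). Analysing a binary
response with ANOVA mirrors common ANOVA-on-proportions practice; a
logistic model would be a reasonable alternative but is not what the
contrast under study computes.

**The repeated-measures unit is a documented choice, not a
reconstruction.** A paired design needs an entity observed in both
centuries, but topics are fitted per century and carry no intrinsic
identity across centuries. `pair_topics_across_centuries()` pairs the
i-th topic of a framing (and genre, when present) in one century with the
i-th in the other and drops the surplus; with per-stratum topic counts
(11, 13) and (7, 9) this yields 18 paired units, hence df (1, 16) in the
default acceptance run. Any long-format unit table can be supplied
directly to `two_way_mixed_anova()` instead.

## What the synthetic generator emulates

`generate_corpus()` plants the statistical structure the pipeline is
meant to recover:

* 21 decade bins × 4 genres; each document carries exactly one target
  occurrence inside a sentence whose window words are drawn from
  valence-stratified pools. Pools use integer rating bins 1–5; a target
  mean of, say, 2.7 is achieved by mixing the 2- and 3-pools, giving
  exact expected means without fractional word ratings.
* Per-framing linear valence trajectories, by default intercepts 3.04
  (age-based) and 3.13 (role-based) with slopes −0.023 and −0.0067 per
  decade — trajectories that stay inside [1, 5] across the span (checked
  at spec time).
* Articles interleaved at rate 0.25 and 10% of targets placed
  sentence-initially, so the span and sentence rules are exercised, not
  idle.
* Filler sentences from a disjoint vocabulary, so pool words occur only
  inside target windows; their MI with the targets is then high and the
  MI filter cannot selectively discard valence information.
* A second rater as the first plus rounded Gaussian noise clipped to
  [1, 5]. The default sd of 0.4 was set analytically before any testing:
  for a lexicon spread uniformly over the five bins, rounded noise has
  variance ≈ 0.21 and α ≈ 8/(8 + 0.21·…) ≈ 0.97, the reliability regime
  of careful human raters.
* `generate_topic_corpus()` plants disjoint-vocabulary topics per
  framing × century stratum with known positive/negative composition
  (default mixtures: 9/11 and 5/13 positive for age-based 1800s/1900s,
  5/7 and 8/9 for role-based).

The generator does **not** emulate real English syntax, genre style,
lexical ambiguity (every pool word has one true valence), thesaurus-based
target discovery, or the human relevance screen. Passing the validation
battery therefore shows the *machinery* is correct — extraction matches a
brute-force oracle, estimators are unbiased and correctly sized, planted
structure is recovered — not that any particular substantive finding
about real corpora is reproduced. Real-corpus results additionally depend
on licensed data and human ratings that cannot ship with code.

## Validation problem sizes and numerical notes

The test suite and acceptance script use deliberately modest sizes, chosen
as the smallest that make each property sharp: oracle-equivalence checks
on 20 random corpora of roughly 1–2 thousand tokens each (exact equality,
tolerance 1e−12 on MI); slope recovery on 100 replicates of a
single-genre, 8-documents-per-cell corpus (~34k tokens each), requiring
95% CI coverage of both planted slopes in at least 90 of 100; size
calibration of the slope-difference test and all three ANOVA effects on
1,000 null replicates each (acceptance band 3–7% at nominal 5%);
closed-form fixtures for OLS, the interaction F, α, and the ANOVA
decomposition at tolerance 1e−10; and topic recovery requiring purity
> 0.9 on disjoint two-topic corpora and positivity counts within ±1 topic
of the planted mixtures. The default acceptance run generates the
full-scale default corpus (2,016 documents, ~400k tokens).

Numerical conventions worth knowing: MI requires all counts ≥ 1 (a
zero-count record simply does not exist); filtering is idempotent;
constant-response ANOVA inputs have their numerically-zero sums of squares
snapped to exact zeros so F = 0, p = 1, η² = 0 rather than 0/0; a perfect
collinear trend fit returns exact coefficients with zero residuals;
degenerate inputs (fewer than 3 decades, zero rating variance, duplicate
unit rows, vocabularies smaller than the topic count) raise errors rather
than propagating NaN.

## Known limitations

* Surface-form collocates conflate inflections (*frail*/*frailer*).
* The MI filter interacts with word frequency: very common collocates
  need proportionally high co-occurrence to clear the threshold.
* The ANOVA pairing of topic slots across centuries is arbitrary up to
  topic order; conclusions that depend on which slot pairs with which
  should use a design with genuine repeated units.
* The Gibbs sampler uses a fixed sweep count rather than a convergence
  diagnostic; for the small collocate-bag corpora this is ample, but very
  large corpora may want more sweeps.
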