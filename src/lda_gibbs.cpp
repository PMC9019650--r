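#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for Latent Dirichlet Allocation.
// doc, word: 0-based ids per token instance; symmetric priors alpha (doc-topic)
// and beta (topic-word). Own RNG so runs are reproducible for a given seed
// irrespective of R's RNG state.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word, int n_docs,
                   int n_vocab, int n_topics, double alpha, double beta,
                   int n_iter, int seed) {
  const int n_tokens = doc.size();
  if (word.size() != n_tokens) stop("doc and word lengths differ");

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(n_tokens);
  IntegerMatrix n_dk(n_docs, n_topics);
  IntegerMatrix n_kw(n_topics, n_vocab);
  std::vector<int> n_k(n_topics, 0);

  for (int i = 0; i < n_tokens; ++i) {
    int t = static_cast<int>(unif(rng) * n_topics);
    if (t == n_topics) t = n_topics - 1;
    z[i] = t;
    n_dk(doc[i], t)++;
    n_kw(t, word[i])++;
    n_k[t]++;
  }

  std::vector<double> p(n_topics);
  const double vbeta = n_vocab * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_tokens; ++i) {
      const int d = doc[i], w = word[i], old = z[i];
      n_dk(d, old)--;
      n_kw(old, w)--;
      n_k[old]--;
      double tot = 0.0;
      for (int k = 0; k < n_topics; ++k) {
        p[k] = (n_dk(d, k) + alpha) * (n_kw(k, w) + beta) / (n_k[k] + vbeta);
        tot += p[k];
      }
      double u = unif(rng) * tot;
      int k = 0;
      double cum = p[0];
      while (u > cum && k < n_topics - 1) {
        ++k;
        cum += p[k];
      }
      z[i] = k;
      n_dk(d, k)++;
      n_kw(k, w)++;
      n_k[k]++;
    }
  }

  NumericMatrix phi(n_topics, n_vocab);
  for (int k = 0; k < n_topics; ++k)
    for (int w = 0; w < n_vocab; ++w)
      phi(k, w) = (n_kw(k, w) + beta) / (n_k[k] + vbeta);

  NumericMatrix theta(n_docs, n_topics);
  for (int d = 0; d < n_docs; ++d) {
    double nd = 0.0;
    for (int k = 0; k < n_topics; ++k) nd += n_dk(d, k);
    for (int k = 0; k < n_topics; ++k)
      theta(d, k) = (n_dk(d, k) + alpha) / (nd + n_topics * alpha);
  }

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["z"] = IntegerVector(z.begin(), z.end()));
}
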