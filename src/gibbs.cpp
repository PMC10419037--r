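#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// word, doc: parallel 0-based token streams; z_init: initial topic per token.
// Topic k is resampled for each token with probability proportional to
//   (n_mk^- + alpha) * (n_kw^- + beta) / (n_k^- + V*beta),
// the standard collapsed conditional with the token's own count removed.
// Uses R's RNG (unif_rand) so a set.seed() upstream fixes the whole chain.
//
// trace_every > 0 stores the assignment vector every trace_every-th sweep;
// meant for tiny corpora where the chain is compared with the exactly
// enumerated collapsed posterior.
// [[Rcpp::export]]
List gibbs_lda_cpp(const IntegerVector& word, const IntegerVector& doc,
                   int V, int M, int K, double alpha, double beta,
                   int n_iter, const IntegerVector& z_init, int trace_every) {
  const int N = word.size();
  IntegerVector z = clone(z_init);
  IntegerMatrix nmk(M, K), nkw(K, V);
  IntegerVector nk(K), nm(M);
  for (int n = 0; n < N; ++n) {
    nmk(doc[n], z[n])++;
    nkw(z[n], word[n])++;
    nk[z[n]]++;
    nm[doc[n]]++;
  }

  const double Vb = V * beta;
  std::vector<double> p(K);
  const int n_trace = (trace_every > 0) ? n_iter / trace_every : 0;
  IntegerMatrix trace(n_trace, N);
  int t_row = 0;

  for (int it = 0; it < n_iter; ++it) {
    for (int n = 0; n < N; ++n) {
      const int w = word[n], d = doc[n];
      int k = z[n];
      nmk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (nmk(d, j) + alpha) * (nkw(j, w) + beta) / (nk[j] + Vb);
        tot += p[j];
      }
      const double u = unif_rand() * tot;
      double cum = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += p[j];
        if (u < cum) { k = j; break; }
      }
      z[n] = k;
      nmk(d, k)++; nkw(k, w)++; nk[k]++;
    }
    if (trace_every > 0 && ((it + 1) % trace_every == 0)) {
      for (int n = 0; n < N; ++n) trace(t_row, n) = z[n];
      ++t_row;
    }
  }

  // smoothed point estimates from the final state
  NumericMatrix phi(K, V), theta(M, K);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      phi(k, w) = (nkw(k, w) + beta) / (nk[k] + Vb);
  const double Ka = K * alpha;
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < K; ++k)
      theta(m, k) = (nmk(m, k) + alpha) / (nm[m] + Ka);

  return List::create(_["phi"] = phi, _["theta"] = theta, _["z"] = z,
                      _["nmk"] = nmk, _["nkw"] = nkw, _["nk"] = nk,
                      _["trace"] = trace);
}

// Fold-in Gibbs for held-out documents: the topic-word distribution phi is
// frozen and only the per-document topic counts are resampled, giving a
// smoothed theta estimate for unseen text.
// [[Rcpp::export]]
NumericMatrix fold_in_cpp(const IntegerVector& word, const IntegerVector& doc,
                          int M, const NumericMatrix& phi, double alpha,
                          int n_sweeps, const IntegerVector& z_init) {
  const int N = word.size(), K = phi.nrow();
  IntegerVector z = clone(z_init);
  IntegerMatrix nmk(M, K);
  IntegerVector nm(M);
  for (int n = 0; n < N; ++n) {
    nmk(doc[n], z[n])++;
    nm[doc[n]]++;
  }
  std::vector<double> p(K);
  for (int it = 0; it < n_sweeps; ++it) {
    for (int n = 0; n < N; ++n) {
      const int w = word[n], d = doc[n];
      int k = z[n];
      nmk(d, k)--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (nmk(d, j) + alpha) * phi(j, w);
        tot += p[j];
      }
      const double u = unif_rand() * tot;
      double cum = 0.0;
      k = K - 1;
      for (int j = 0; j < K; ++j) {
        cum += p[j];
        if (u < cum) { k = j; break; }
      }
      z[n] = k;
      nmk(d, k)++;
    }
  }
  NumericMatrix theta(M, K);
  const double Ka = K * alpha;
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < K; ++k)
      theta(m, k) = (nmk(m, k) + alpha) / (nm[m] + Ka);
  return theta;
}
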