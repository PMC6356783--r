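#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps over every token of every document.
//
// State is mutated in place: z (per-doc 1-based topic assignments), Ndt
// (D x T doc-topic counts), Ntw (T x W topic-word counts), Nt (topic
// totals).  aL is alpha * Lambda, so inactive labels carry exactly 0 and
// never receive probability mass (Ndt is 0 there by invariant).  Draws use
// R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
void cgs_sweeps_cpp(List tokens, List z, IntegerMatrix Ndt,
                    IntegerMatrix Ntw, IntegerVector Nt,
                    NumericMatrix aL, NumericVector lambda,
                    int nsweeps) {
  const int D = tokens.size();
  const int T = Ndt.ncol();
  double lambda_sum = 0.0;
  for (int w = 0; w < lambda.size(); ++w) lambda_sum += lambda[w];
  std::vector<double> p(T);
  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int d = 0; d < D; ++d) {
      IntegerVector wd = tokens[d];
      IntegerVector zd = z[d];
      const int Ndoc = wd.size();
      for (int n = 0; n < Ndoc; ++n) {
        const int w = wd[n] - 1;
        const int told = zd[n] - 1;
        // remove the token from the counts
        Ndt(d, told) -= 1;
        Ntw(told, w) -= 1;
        Nt[told] -= 1;
        double total = 0.0;
        for (int t = 0; t < T; ++t) {
          const double a = aL(d, t);
          double pt = 0.0;
          if (a > 0.0) {
            pt = (a + Ndt(d, t)) * (lambda[w] + Ntw(t, w)) /
                 (lambda_sum + Nt[t]);
          }
          total += pt;
          p[t] = total;
        }
        if (!(total > 0.0)) stop("zero normalization mass in Gibbs sweep");
        const double u = unif_rand() * total;
        int tnew = 0;
        while (tnew < T - 1 && p[tnew] < u) ++tnew;
        zd[n] = tnew + 1;
        Ndt(d, tnew) += 1;
        Ntw(tnew, w) += 1;
        Nt[tnew] += 1;
      }
    }
  }
}

// Fold-in Gibbs sweeps for test documents with the topic-word
// distributions held fixed: p(t) ~ (aL + Ndt^{\dn}) * theta[t, w].
// [[Rcpp::export]]
void cgs_foldin_cpp(List tokens, List z, IntegerMatrix Ndt,
                    NumericMatrix aL, NumericMatrix theta, int nsweeps) {
  const int D = tokens.size();
  const int T = Ndt.ncol();
  std::vector<double> p(T);
  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int d = 0; d < D; ++d) {
      IntegerVector wd = tokens[d];
      IntegerVector zd = z[d];
      const int Ndoc = wd.size();
      for (int n = 0; n < Ndoc; ++n) {
        const int w = wd[n] - 1;
        const int told = zd[n] - 1;
        Ndt(d, told) -= 1;
        double total = 0.0;
        for (int t = 0; t < T; ++t) {
          const double a = aL(d, t);
          double pt = 0.0;
          if (a > 0.0) pt = (a + Ndt(d, t)) * theta(t, w);
          total += pt;
          p[t] = total;
        }
        if (!(total > 0.0)) stop("zero normalization mass in fold-in sweep");
        const double u = unif_rand() * total;
        int tnew = 0;
        while (tnew < T - 1 && p[tnew] < u) ++tnew;
        zd[n] = tnew + 1;
        Ndt(d, tnew) += 1;
      }
    }
  }
}

// Zero-order collapsed-variational local loop for one document.
//
// B is the Wd x T matrix of word factors (lambda_w + mu_tw) / (sum lambda
// + mu_t) evaluated with this document's statistics excluded; adt is the
// label-masked prior row (0 on inactive labels); ndw the word-type
// multiplicities.  Iterates eta(w,t) ~ (adt + gamma_t) * B(w,t), gamma_t =
// sum_w (ndw - 1) eta(w,t), until the mean absolute gamma change per token
// drops below tol or max_iter is hit.
// [[Rcpp::export]]
List cvb0_local_cpp(NumericVector ndw, NumericMatrix B, NumericVector adt,
                    double tol, int max_iter, double Nd) {
  const int Wd = ndw.size();
  const int T = adt.size();
  NumericMatrix eta(Wd, T);
  // constant (uniform over active labels) initialization
  int n_active = 0;
  for (int t = 0; t < T; ++t) if (adt[t] > 0.0) ++n_active;
  if (n_active == 0) stop("document has no active labels");
  for (int w = 0; w < Wd; ++w)
    for (int t = 0; t < T; ++t)
      eta(w, t) = adt[t] > 0.0 ? 1.0 / n_active : 0.0;

  std::vector<double> gamma(T, 0.0), gamma_new(T);
  for (int t = 0; t < T; ++t)
    for (int w = 0; w < Wd; ++w)
      gamma[t] += (ndw[w] - 1.0) * eta(w, t);

  int iter = 0;
  bool converged = false;
  while (iter < max_iter && !converged) {
    ++iter;
    for (int w = 0; w < Wd; ++w) {
      double total = 0.0;
      for (int t = 0; t < T; ++t) {
        double e = 0.0;
        if (adt[t] > 0.0) e = (adt[t] + gamma[t]) * B(w, t);
        eta(w, t) = e;
        total += e;
      }
      if (!(total > 0.0)) stop("zero normalization mass in CVB0 update");
      for (int t = 0; t < T; ++t) eta(w, t) /= total;
    }
    double diff = 0.0;
    for (int t = 0; t < T; ++t) {
      gamma_new[t] = 0.0;
      for (int w = 0; w < Wd; ++w)
        gamma_new[t] += (ndw[w] - 1.0) * eta(w, t);
      diff += std::fabs(gamma_new[t] - gamma[t]);
      gamma[t] = gamma_new[t];
    }
    if (diff / Nd < tol) converged = true;
  }
  return List::create(_["eta"] = eta,
                      _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
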