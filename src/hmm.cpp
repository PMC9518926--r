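#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over an integer emission index sequence.
// d: 0-based emission column per locus; A: S x S row-stochastic transition
// matrix; B: S x D emission matrix; Pi: initial distribution. Returns the
// log-likelihood, expected transition counts (S x S), expected emission
// counts (S x D), the posterior of the initial state, and optionally the
// full posterior state marginals (L x S).
// [[Rcpp::export]]
List fb_naive_cpp(IntegerVector d, NumericMatrix A, NumericMatrix B,
                  NumericVector Pi, bool posterior = false) {
  const int L = d.size(), S = A.nrow(), D = B.ncol();
  NumericMatrix alpha(L, S);
  NumericVector scale(L);
  // forward
  double c0 = 0.0;
  for (int i = 0; i < S; ++i) {
    alpha(0, i) = Pi[i] * B(i, d[0]);
    c0 += alpha(0, i);
  }
  if (c0 <= 0) stop("zero emission probability at locus 1");
  for (int i = 0; i < S; ++i) alpha(0, i) /= c0;
  scale[0] = c0;
  for (int l = 1; l < L; ++l) {
    double cl = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) s += alpha(l - 1, i) * A(i, j);
      double v = s * B(j, d[l]);
      alpha(l, j) = v;
      cl += v;
    }
    if (cl <= 0) stop("zero emission probability at locus %d", l + 1);
    for (int j = 0; j < S; ++j) alpha(l, j) /= cl;
    scale[l] = cl;
  }
  double loglik = 0.0;
  for (int l = 0; l < L; ++l) loglik += std::log(scale[l]);
  // backward with on-the-fly expected counts
  NumericVector beta(S, 1.0), beta_new(S);
  NumericMatrix xi(S, S), emis(S, D);
  NumericMatrix post;
  if (posterior) post = NumericMatrix(L, S);
  for (int i = 0; i < S; ++i) emis(i, d[L - 1]) += alpha(L - 1, i);
  if (posterior)
    for (int i = 0; i < S; ++i) post(L - 1, i) = alpha(L - 1, i);
  for (int l = L - 2; l >= 0; --l) {
    // xi contributions for transition l -> l+1 and gamma at locus l
    double cl1 = scale[l + 1];
    for (int i = 0; i < S; ++i) {
      double bi = 0.0;
      for (int j = 0; j < S; ++j) {
        double term = alpha(l, i) * A(i, j) * B(j, d[l + 1]) * beta[j] / cl1;
        xi(i, j) += term;
        bi += A(i, j) * B(j, d[l + 1]) * beta[j];
      }
      beta_new[i] = bi / cl1;
    }
    for (int i = 0; i < S; ++i) beta[i] = beta_new[i];
    for (int i = 0; i < S; ++i) {
      double g = alpha(l, i) * beta[i];
      emis(i, d[l]) += g;
      if (posterior) post(l, i) = g;
    }
  }
  NumericVector init(S);
  for (int i = 0; i < S; ++i) init[i] = alpha(0, i) * beta[i];
  List out = List::create(_["loglik"] = loglik, _["trans"] = xi,
                          _["emis"] = emis, _["init"] = init);
  if (posterior) out["posterior"] = post;
  return out;
}

// Exact within-run accumulation for a homogeneous run of m loci with
// emission vector b (per state): given the forward vector x0 at the locus
// preceding the run and the backward vector ym at the last locus of the
// run (both may carry arbitrary positive scalings), computes the expected
// transition counts over the m steps entering and inside the run, the
// expected state occupancies over the run's loci (both posterior-
// normalized), and the forward vector after the run (max-normalized, with
// its log scale). Fallback for the spectral run computation.
// [[Rcpp::export]]
List fb_run_exact_cpp(NumericVector x0, NumericVector ym, NumericMatrix A,
                      NumericVector b, int m) {
  const int S = A.nrow();
  // ys(u, ) ~ M^(m-u) ym up to scale, yscale[u] the log of that scale
  NumericMatrix ys(m + 1, S);
  NumericVector yscale(m + 1);
  for (int i = 0; i < S; ++i) ys(m, i) = ym[i];
  yscale[m] = 0.0;
  for (int u = m - 1; u >= 0; --u) {
    double mx = 0.0;
    for (int i = 0; i < S; ++i) {
      double s = 0.0;
      for (int j = 0; j < S; ++j) s += A(i, j) * b[j] * ys(u + 1, j);
      ys(u, i) = s;
      if (s > mx) mx = s;
    }
    if (mx <= 0) stop("zero mass in run backward recursion");
    for (int i = 0; i < S; ++i) ys(u, i) /= mx;
    yscale[u] = yscale[u + 1] + std::log(mx);
  }
  NumericVector x(clone(x0));
  double xlog = 0.0;
  // Zlog: log of x0 M^m ym under the current scalings
  double z0 = 0.0;
  for (int i = 0; i < S; ++i) z0 += x[i] * ys(0, i);
  if (z0 <= 0) stop("zero posterior mass in run");
  const double Zlog = std::log(z0) + yscale[0];
  NumericMatrix Etr(S, S);
  NumericVector Y(S);
  for (int u = 0; u < m; ++u) {
    // transitions at step u (x = x0 M^u): P(i -> j) propto
    // x[i] A(i,j) b[j] ys(u+1, j)
    double w = std::exp(xlog + yscale[u + 1] - Zlog);
    for (int i = 0; i < S; ++i) {
      if (x[i] == 0.0) continue;
      for (int j = 0; j < S; ++j) {
        Etr(i, j) += w * x[i] * A(i, j) * b[j] * ys(u + 1, j);
      }
    }
    // advance x one step and record occupancy at run locus u+1
    NumericVector xn(S);
    double mx = 0.0;
    for (int j = 0; j < S; ++j) {
      double s = 0.0;
      for (int i = 0; i < S; ++i) s += x[i] * A(i, j);
      double v = s * b[j];
      xn[j] = v;
      if (v > mx) mx = v;
    }
    if (mx <= 0) stop("zero mass in run forward recursion");
    for (int j = 0; j < S; ++j) x[j] = xn[j] / mx;
    xlog += std::log(mx);
    double w2 = std::exp(xlog + yscale[u + 1] - Zlog);
    for (int j = 0; j < S; ++j) Y[j] += w2 * x[j] * ys(u + 1, j);
  }
  return List::create(_["trans"] = Etr, _["emis_occ"] = Y, _["x_out"] = x,
                      _["x_log"] = xlog);
}

// Sample a hidden path and emissions from (Pi, A, B) using R's RNG.
// Returns the 0-based emission index per locus.
// [[Rcpp::export]]
IntegerVector sample_hmm_cpp(NumericMatrix A, NumericMatrix B,
                             NumericVector Pi, int L) {
  const int S = A.nrow(), D = B.ncol();
  IntegerVector d(L);
  RNGScope scope;
  auto draw = [](const double *p, int k) {
    double u = unif_rand(), c = 0.0;
    for (int i = 0; i < k; ++i) {
      c += p[i];
      if (u <= c) return i;
    }
    return k - 1;
  };
  std::vector<double> row(S);
  int s = draw(REAL(Pi), S);
  for (int l = 0; l < L; ++l) {
    if (l > 0) {
      for (int j = 0; j < S; ++j) row[j] = A(s, j);
      s = draw(row.data(), S);
    }
    std::vector<double> erow(D);
    for (int k = 0; k < D; ++k) erow[k] = B(s, k);
    d[l] = draw(erow.data(), D);
  }
  return d;
}
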