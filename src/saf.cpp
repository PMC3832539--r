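#include <Rcpp.h>
using namespace Rcpp;

// Sample-allele-frequency (SAF) likelihood via the individual-by-individual
// dynamic programming over the number of derived chromosomes.
//
// gl0, gl1, gl2: sites x N matrices of per-genotype likelihoods on the
// linear scale (per-cell normalisation is irrelevant; rows are rescaled).
//
// The state after individual i is q_j ∝ P(reads of individuals 1..i | j of
// their 2i chromosomes are derived), with the derived chromosomes assigned
// to individuals as an exchangeable (hypergeometric) draw. Adding individual
// i multiplies in its genotype likelihoods with the hypergeometric weights
//   P(g of the j derived chromosomes in individual i) =
//     C(2,g) C(2i-2, j-g) / C(2i, j),
// i.e. proportionally (2i-j)(2i-j-1) L(0), 2 j (2i-j) L(1), j (j-1) L(2).
// Working in this normalised-count space keeps the spread across j equal to
// the true likelihood profile (no combinatorial blow-up), so per-step
// max-rescaling suffices for N = 1000 at 1X. States below 1e-290 of the row
// maximum are flushed to exact zero (they are dead weight numerically and
// would otherwise drag the loop through denormal arithmetic); the active
// band [lo, hi] of non-zero states is tracked and shrinks sharply at high
// depth. Rows are returned normalised to sum to one: relative likelihood
// P(data | j), j = 0..2N.
// [[Rcpp::export]]
NumericMatrix saf_dp_cpp(NumericMatrix gl0, NumericMatrix gl1, NumericMatrix gl2) {
  const int M = gl0.nrow(), N = gl0.ncol();
  if (gl1.nrow() != M || gl2.nrow() != M || gl1.ncol() != N || gl2.ncol() != N)
    stop("genotype-likelihood matrices must share dimensions");
  const int K = 2 * N + 1;
  const double tiny = 1e-290;
  NumericMatrix out(M, K);
  std::vector<double> h(K), hn(K);
  for (int s = 0; s < M; ++s) {
    std::fill(h.begin(), h.end(), 0.0);
    h[0] = 1.0;
    int lo = 0, hi = 0;
    for (int i = 1; i <= N; ++i) {
      const double l0 = gl0(s, i - 1), l1 = gl1(s, i - 1), l2 = gl2(s, i - 1);
      const int jmax = 2 * i;
      const int nlo = lo, nhi = std::min(hi + 2, jmax);
      double mx = 0.0;
      for (int j = nlo; j <= nhi; ++j) {
        const double a = (double)(jmax - j);
        double v = a * (a - 1.0) * l0 * h[j];
        if (j >= 1) v += 2.0 * j * a * l1 * h[j - 1];
        if (j >= 2) v += (double)j * (j - 1.0) * l2 * h[j - 2];
        hn[j] = v;
        if (v > mx) mx = v;
      }
      if (mx <= 0.0)
        stop("all-zero likelihood row at site %d: degenerate input", s + 1);
      lo = -1;
      for (int j = nlo; j <= nhi; ++j) {
        double v = hn[j] / mx;
        if (v < tiny) v = 0.0; else if (lo < 0) lo = j;
        h[j] = v;
        if (v > 0.0) hi = j;
      }
      // clear the two cells above the old band that the next step may read
      if (nhi + 1 < K) h[nhi + 1] = 0.0;
      if (nhi + 2 < K) h[nhi + 2] = 0.0;
    }
    double tot = 0.0;
    for (int j = lo; j <= hi; ++j) tot += h[j];
    for (int j = lo; j <= hi; ++j) out(s, j) = h[j] / tot;
  }
  return out;
}

// Maximum-likelihood global site frequency spectrum by EM: the prior
// p over j = 0..2N maximising sum_s log sum_j p_j L_sj for a matrix of
// per-site SAF likelihoods (rows need not be normalised).
// [[Rcpp::export]]
NumericVector sfs_em_cpp(NumericMatrix lik, NumericVector p_start,
                         double tol, int max_iter) {
  const int M = lik.nrow(), K = lik.ncol();
  if (p_start.size() != K) stop("p_start length must equal ncol(lik)");
  std::vector<double> p(p_start.begin(), p_start.end()), pn(K);
  for (int it = 0; it < max_iter; ++it) {
    std::fill(pn.begin(), pn.end(), 0.0);
    for (int s = 0; s < M; ++s) {
      double tot = 0.0;
      for (int j = 0; j < K; ++j) tot += p[j] * lik(s, j);
      if (tot <= 0.0) stop("site %d has zero likelihood under the current SFS", s + 1);
      for (int j = 0; j < K; ++j) {
        const double v = p[j] * lik(s, j);
        if (v > 0.0) pn[j] += v / tot;
      }
    }
    double delta = 0.0;
    for (int j = 0; j < K; ++j) {
      pn[j] /= M;
      delta = std::max(delta, std::fabs(pn[j] - p[j]));
      p[j] = pn[j];
    }
    if (delta < tol) break;
  }
  return NumericVector(p.begin(), p.end());
}

// Per-site maximum-likelihood allele frequency under Hardy-Weinberg genotype
// proportions, by EM. f_start: per-site initial value in [0, 1].
// Sites whose per-cell likelihoods are flat (no reads anywhere) stay at the
// fixed point of the update, i.e. their starting value.
// [[Rcpp::export]]
NumericVector em_freq_cpp(NumericMatrix gl0, NumericMatrix gl1, NumericMatrix gl2,
                          NumericVector f_start, double tol, int max_iter) {
  const int M = gl0.nrow(), N = gl0.ncol();
  if (f_start.size() != M) stop("f_start length must equal the number of sites");
  NumericVector f(M);
  for (int s = 0; s < M; ++s) {
    double fc = f_start[s];
    if (fc < 0.0 || fc > 1.0) stop("starting frequency outside [0, 1]");
    for (int it = 0; it < max_iter; ++it) {
      const double p0 = (1.0 - fc) * (1.0 - fc);
      const double p1 = 2.0 * fc * (1.0 - fc);
      const double p2 = fc * fc;
      double acc = 0.0;
      for (int i = 0; i < N; ++i) {
        const double d0 = gl0(s, i) * p0;
        const double d1 = gl1(s, i) * p1;
        const double d2 = gl2(s, i) * p2;
        const double t = d0 + d1 + d2;
        if (t > 0.0) acc += (d1 + 2.0 * d2) / t;
      }
      const double fn = acc / (2.0 * N);
      const double delta = std::fabs(fn - fc);
      fc = fn;
      if (delta < tol) break;
    }
    f[s] = fc;
  }
  return f;
}
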