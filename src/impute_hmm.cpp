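#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haploid haplotype-copying (Li-Stephens-style) forward-backward.
//
// The hidden state is which reference haplotype the target copies.
// Between adjacent typed sites the chain stays put with probability
// 1 - switchRate and jumps to a uniformly chosen haplotype with
// probability switchRate; emission mismatch probability is errorRate.
// Untyped variants take the posterior-weighted average of reference
// alleles, using the state posterior at the nearest typed site (ties
// to the left).
//
// panel:  K x V reference haplotypes (0/1, complete)
// target: N x V target calls (0/1, NA = untyped/missing)
// leaveOneOut: exclude panel row i from the copying states of target
//   row i (requires K == N and row alignment), for masking
//   cross-validation.
// [[Rcpp::export(name = ".lsImputeCpp")]]
NumericMatrix lsImputeCpp(IntegerMatrix panel, IntegerMatrix target,
                          double switchRate, double errorRate,
                          bool leaveOneOut) {
  const int K = panel.nrow(), V = panel.ncol(), N = target.nrow();
  if (target.ncol() != V) stop("panel/target variant mismatch");
  if (leaveOneOut && K != N) stop("leave-one-out needs K == N");
  NumericMatrix doses(N, V);
  const int *P = INTEGER(panel);
  const int *Tg = INTEGER(target);
  std::vector<int> typed(V);
  std::vector<double> F((size_t)V * K), b(K), bnew(K), gamma(K),
      alive(K, 1.0);
  const double e1 = 1.0 - errorRate, e0 = errorRate, de = e1 - e0;

  for (int i = 0; i < N; ++i) {
    int T = 0;
    for (int v = 0; v < V; ++v)
      if (Tg[(size_t)v * N + i] != NA_INTEGER) typed[T++] = v;
    const int skip = leaveOneOut ? i : -1;
    const int Keff = (skip >= 0) ? K - 1 : K;
    if (Keff <= 0) stop("empty reference panel");
    if (skip >= 0) alive[skip] = 0.0;

    if (T == 0) {            // uniform posterior over the panel
      for (int v = 0; v < V; ++v) {
        const int *pc = P + (size_t)v * K;
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += alive[k] * pc[k];
        doses(i, v) = s / Keff;
      }
      if (skip >= 0) alive[skip] = 1.0;
      continue;
    }

    // forward pass (normalized each step; a dead `alive` entry keeps
    // the left-out haplotype at probability zero throughout)
    for (int t = 0; t < T; ++t) {
      const int v = typed[t];
      const int obs = Tg[(size_t)v * N + i];
      const int *pc = P + (size_t)v * K;
      double *f = &F[(size_t)t * K];
      double sum = 0.0;
      if (t == 0) {
        const double init = 1.0 / Keff;
        for (int k = 0; k < K; ++k) {
          f[k] = init * alive[k] * (e0 + de * (pc[k] == obs));
          sum += f[k];
        }
      } else {
        const double *fp = &F[(size_t)(t - 1) * K];
        const double stay = 1.0 - switchRate;
        const double jump = switchRate / Keff;   // fp sums to 1
        for (int k = 0; k < K; ++k) {
          f[k] = (stay * fp[k] + jump) * alive[k] *
                 (e0 + de * (pc[k] == obs));
          sum += f[k];
        }
      }
      if (sum <= 0.0) stop("forward pass underflow");
      const double inv = 1.0 / sum;
      for (int k = 0; k < K; ++k) f[k] *= inv;
    }

    // backward pass; doses filled per typed-site neighborhood
    for (int k = 0; k < K; ++k) b[k] = alive[k];
    for (int t = T - 1; t >= 0; --t) {
      const double *f = &F[(size_t)t * K];
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) {
        gamma[k] = f[k] * b[k];
        gsum += gamma[k];
      }
      if (gsum <= 0.0) stop("backward pass underflow");
      const double ginv = 1.0 / gsum;
      for (int k = 0; k < K; ++k) gamma[k] *= ginv;

      int lo = (t == 0) ? 0 : (typed[t - 1] + typed[t]) / 2 + 1;
      int hi = (t == T - 1) ? V - 1 : (typed[t] + typed[t + 1]) / 2;
      for (int v = lo; v <= hi; ++v) {
        const int obsv = Tg[(size_t)v * N + i];
        if (obsv != NA_INTEGER) { doses(i, v) = obsv; continue; }
        const int *pc = P + (size_t)v * K;
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += gamma[k] * pc[k];
        doses(i, v) = s;
      }

      if (t > 0) {
        const int v = typed[t];
        const int obs = Tg[(size_t)v * N + i];
        const int *pc = P + (size_t)v * K;
        double mix = 0.0;
        for (int k = 0; k < K; ++k) {
          bnew[k] = (e0 + de * (pc[k] == obs)) * b[k];
          mix += bnew[k];
        }
        mix /= Keff;
        const double stay = 1.0 - switchRate;
        double bsum = 0.0;
        for (int k = 0; k < K; ++k) {
          b[k] = (stay * bnew[k] + switchRate * mix) * alive[k];
          bsum += b[k];
        }
        if (bsum <= 0.0) stop("backward pass underflow");
        const double binv = 1.0 / bsum;
        for (int k = 0; k < K; ++k) b[k] *= binv;
      }
    }
    if (skip >= 0) alive[skip] = 1.0;
  }
  return doses;
}

// State posteriors at every typed site for a single target haplotype
// (used to assert forward-backward normalization and for the
// path-enumeration oracle comparison).
// [[Rcpp::export(name = ".lsPosteriorCpp")]]
NumericMatrix lsPosteriorCpp(IntegerMatrix panel, IntegerVector target,
                             double switchRate, double errorRate) {
  const int K = panel.nrow(), V = panel.ncol();
  if (target.size() != V) stop("panel/target variant mismatch");
  std::vector<int> typed;
  for (int v = 0; v < V; ++v)
    if (target[v] != NA_INTEGER) typed.push_back(v);
  const int T = typed.size();
  if (T == 0) stop("no typed sites");
  const double e1 = 1.0 - errorRate, e0 = errorRate;
  NumericMatrix F(T, K), G(T, K);
  for (int t = 0; t < T; ++t) {
    const int v = typed[t], obs = target[v];
    double sum = 0.0;
    for (int k = 0; k < K; ++k) {
      double pred = (t == 0) ? 1.0 / K
        : (1.0 - switchRate) * F(t - 1, k) + switchRate / K;
      F(t, k) = pred * (panel(k, v) == obs ? e1 : e0);
      sum += F(t, k);
    }
    if (sum <= 0.0) stop("forward pass underflow");
    for (int k = 0; k < K; ++k) F(t, k) /= sum;
  }
  std::vector<double> b(K, 1.0), bnew(K);
  for (int t = T - 1; t >= 0; --t) {
    double gsum = 0.0;
    for (int k = 0; k < K; ++k) { G(t, k) = F(t, k) * b[k]; gsum += G(t, k); }
    for (int k = 0; k < K; ++k) G(t, k) /= gsum;
    if (t > 0) {
      const int v = typed[t], obs = target[v];
      double mix = 0.0;
      for (int k = 0; k < K; ++k) {
        bnew[k] = (panel(k, v) == obs ? e1 : e0) * b[k];
        mix += bnew[k];
      }
      mix /= K;
      double bsum = 0.0;
      for (int k = 0; k < K; ++k) {
        b[k] = (1.0 - switchRate) * bnew[k] + switchRate * mix;
        bsum += b[k];
      }
      for (int k = 0; k < K; ++k) b[k] /= bsum;
    }
  }
  return G;
}
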