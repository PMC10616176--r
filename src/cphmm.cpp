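// Compound-state HMM core: scaled forward-backward over the 2^w
// shift-register state space of a two-state promoter observed through a
// w-step elongation window, with the accumulated sufficient statistics
// needed by the EM M-step (expected promoter transition counts and the
// weighted regression of emissions on the register ON-count).
//
// State encoding: integer s in [0, 2^w); bit 0 is the newest (current)
// promoter state, bit w-1 the oldest still inside the window. A transition
// appends a new promoter bit: s' = ((s << 1) | b) & (2^w - 1), with
// probability A(s & 1, b).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int popcount_int(unsigned int v) {
  int c = 0;
  while (v) { c += v & 1u; v >>= 1; }
  return c;
}

// [[Rcpp::export]]
List cphmm_estep_cpp(NumericVector f, int w, NumericMatrix A,
                     NumericVector init, double nu, double b0, double sigma,
                     bool want_gamma = false) {
  const int T = f.size();
  const int M = 1 << w;
  const unsigned int mask = M - 1;
  if (init.size() != M) stop("init must have length 2^w");
  if (sigma <= 0) stop("sigma must be > 0");

  std::vector<int> pop(M);
  for (int s = 0; s < M; ++s) pop[s] = popcount_int((unsigned int)s);

  // per-timepoint emission density by ON-count class
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double lognorm = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  std::vector<double> emis((size_t)T * (w + 1));
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c <= w; ++c) {
      double d = f[t] - (b0 + nu * c);
      emis[(size_t)t * (w + 1) + c] = std::exp(lognorm - d * d * inv2s2);
    }
  }

  double loglik = 0.0;
  // full alpha storage is needed for the xi accumulation in the backward pass
  std::vector<double> alpha_all((size_t)T * M);

  // forward
  {
    double sum = 0.0;
    for (int s = 0; s < M; ++s) {
      double v = init[s] * emis[(size_t)0 * (w + 1) + pop[s]];
      alpha_all[s] = v;
      sum += v;
    }
    if (sum <= 0 || !std::isfinite(sum)) {
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
    }
    for (int s = 0; s < M; ++s) alpha_all[s] /= sum;
    loglik += std::log(sum);
  }
  const double a00 = A(0, 0), a01 = A(0, 1), a10 = A(1, 0), a11 = A(1, 1);
  for (int t = 1; t < T; ++t) {
    const double* ap = &alpha_all[(size_t)(t - 1) * M];
    double* an = &alpha_all[(size_t)t * M];
    const double* et = &emis[(size_t)t * (w + 1)];
    double sum = 0.0;
    const int half = M >> 1;
    for (int s2 = 0; s2 < M; ++s2) {
      const int b = s2 & 1;
      const int p0 = s2 >> 1;          // predecessor with oldest bit 0
      const int p1 = (s2 >> 1) | half; // predecessor with oldest bit 1
      const double t0 = (p0 & 1) ? (b ? a11 : a10) : (b ? a01 : a00);
      const double t1 = (p1 & 1) ? (b ? a11 : a10) : (b ? a01 : a00);
      double v = (ap[p0] * t0 + ap[p1] * t1) * et[pop[s2]];
      an[s2] = v;
      sum += v;
    }
    if (sum <= 0 || !std::isfinite(sum)) {
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
    }
    for (int s2 = 0; s2 < M; ++s2) an[s2] /= sum;
    loglik += std::log(sum);
  }

  // backward with xi / gamma accumulation
  std::vector<double> beta(M, 1.0), beta_new(M);
  NumericMatrix counts(2, 2); // expected promoter transitions
  double W = 0, Sc = 0, Scc = 0, SF = 0, ScF = 0, SFF = 0;
  NumericMatrix gamma_out(want_gamma ? T : 1, want_gamma ? M : 1);
  NumericVector gamma1(M);

  // gamma at T
  {
    const double* aT = &alpha_all[(size_t)(T - 1) * M];
    double s2sum = 0.0;
    for (int s = 0; s < M; ++s) s2sum += aT[s];
    for (int s = 0; s < M; ++s) {
      double g = aT[s] / s2sum;
      int c = pop[s];
      W += g; Sc += g * c; Scc += (double)g * c * c;
      SF += g * f[T - 1]; ScF += g * c * f[T - 1];
      SFF += g * f[T - 1] * f[T - 1];
      if (want_gamma) gamma_out(T - 1, s) = g;
      if (T == 1) gamma1[s] = g;
    }
  }

  const int half = M >> 1;
  for (int t = T - 2; t >= 0; --t) {
    const double* at = &alpha_all[(size_t)t * M];
    const double* et1 = &emis[(size_t)(t + 1) * (w + 1)];
    // one scaled backward step: beta_new[s] = sum_b A(s&1,b) e_{t+1}(s') beta(s')
    double norm = 0.0;
    for (int s = 0; s < M; ++s) {
      const int s0 = (int)(((unsigned int)s << 1) & mask);       // b = 0
      const int s1 = (int)((((unsigned int)s << 1) | 1u) & mask); // b = 1
      const double aoff = (s & 1) ? a10 : a00;
      const double aon  = (s & 1) ? a11 : a01;
      beta_new[s] = aoff * et1[pop[s0]] * beta[s0] +
                    aon  * et1[pop[s1]] * beta[s1];
      norm += at[s] * beta_new[s];
    }
    if (norm <= 0 || !std::isfinite(norm)) {
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
    }
    // xi over compound transitions aggregated into 2x2 promoter counts
    double xsum = 0.0;
    double x00 = 0, x01 = 0, x10 = 0, x11 = 0;
    for (int s = 0; s < M; ++s) {
      const int s0 = (int)(((unsigned int)s << 1) & mask);
      const int s1 = (int)((((unsigned int)s << 1) | 1u) & mask);
      const double aoff = (s & 1) ? a10 : a00;
      const double aon  = (s & 1) ? a11 : a01;
      const double xi0 = at[s] * aoff * et1[pop[s0]] * beta[s0];
      const double xi1 = at[s] * aon  * et1[pop[s1]] * beta[s1];
      if (s & 1) { x10 += xi0; x11 += xi1; } else { x00 += xi0; x01 += xi1; }
      xsum += xi0 + xi1;
    }
    counts(0, 0) += x00 / xsum; counts(0, 1) += x01 / xsum;
    counts(1, 0) += x10 / xsum; counts(1, 1) += x11 / xsum;
    // gamma at t
    for (int s = 0; s < M; ++s) {
      double g = at[s] * beta_new[s] / norm;
      int c = pop[s];
      W += g; Sc += g * c; Scc += (double)g * c * c;
      SF += g * f[t]; ScF += g * c * f[t];
      SFF += g * f[t] * f[t];
      if (want_gamma) gamma_out(t, s) = g;
      if (t == 0) gamma1[s] = g;
    }
    // rescale beta for stability
    double bmax = 0.0;
    for (int s = 0; s < M; ++s) bmax = std::max(bmax, beta_new[s]);
    for (int s = 0; s < M; ++s) beta[s] = beta_new[s] / bmax;
  }

  List out = List::create(
    _["loglik"] = loglik, _["ok"] = true,
    _["counts"] = counts, _["gamma1"] = gamma1,
    _["W"] = W, _["Sc"] = Sc, _["Scc"] = Scc,
    _["SF"] = SF, _["ScF"] = ScF, _["SFF"] = SFF);
  if (want_gamma) out["gamma"] = gamma_out;
  return out;
}
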