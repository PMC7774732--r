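// Scaled forward-backward recursions and Baum-Welch updates for the
// two-transient-state active-surveillance HMM.
//
// Parameter vector layout (shared with R's param_vector()):
//   0 pi_nfr, 1 apr, 2 exit_fr_rp, 3 exit_fr_norp, 4 exit_nfr_rp,
//   5 exit_nfr_norp, 6 sens, 7 spec,
//   8..12  FR  mixture: weight, mu1, mu2, sigma1, sigma2
//   13..17 NFR mixture: weight, mu1, mu2, sigma1, sigma2
//
// Observation codes: biopsy 0 = none, 1 = GS<=6, 2 = GS>=7; psa NA = none.
// Exit codes: 0 censored, 1 RP favorable, 2 RP non-favorable, 3 no RP.
//
// Within-year event order (the likelihood convention): the year-t transition
// happens first; an exit replaces the year-t observation slot; surviving
// transient states emit at the end of year t.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

struct Pars {
  double pi, apr, efr_rp, efr_norp, enfr_rp, enfr_norp, sens, spec;
  double w[2], m1[2], m2[2], s1[2], s2[2]; // per state: 0 = FR, 1 = NFR
};

static Pars unpack(const NumericVector& p) {
  if (p.size() != 18) stop("parameter vector must have length 18");
  Pars q;
  q.pi = p[0]; q.apr = p[1];
  q.efr_rp = p[2]; q.efr_norp = p[3]; q.enfr_rp = p[4]; q.enfr_norp = p[5];
  q.sens = p[6]; q.spec = p[7];
  for (int s = 0; s < 2; ++s) {
    int o = 8 + 5 * s;
    q.w[s] = p[o]; q.m1[s] = p[o + 1]; q.m2[s] = p[o + 2];
    q.s1[s] = p[o + 3]; q.s2[s] = p[o + 4];
  }
  return q;
}

static NumericVector pack(const Pars& q) {
  NumericVector p(18);
  p[0] = q.pi; p[1] = q.apr;
  p[2] = q.efr_rp; p[3] = q.efr_norp; p[4] = q.enfr_rp; p[5] = q.enfr_norp;
  p[6] = q.sens; p[7] = q.spec;
  for (int s = 0; s < 2; ++s) {
    int o = 8 + 5 * s;
    p[o] = q.w[s]; p[o + 1] = q.m1[s]; p[o + 2] = q.m2[s];
    p[o + 3] = q.s1[s]; p[o + 4] = q.s2[s];
  }
  return p;
}

static inline double npdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) * INV_SQRT_2PI / sd;
}

// per-state emission likelihood of one observation year; also returns the
// two mixture-component contributions (d1, d2) when PSA is present
static inline double emis(const Pars& q, int state, int bio, double psa,
                          double* d1, double* d2) {
  double e = 1.0;
  if (bio == 1) e = (state == 0) ? q.spec : (1.0 - q.sens);
  else if (bio == 2) e = (state == 0) ? (1.0 - q.spec) : q.sens;
  *d1 = *d2 = 0.0;
  if (!ISNA(psa)) {
    *d1 = q.w[state] * npdf(psa, q.m1[state], q.s1[state]);
    *d2 = (1.0 - q.w[state]) * npdf(psa, q.m2[state], q.s2[state]);
    e *= (*d1 + *d2);
  }
  return e;
}

struct Stats {
  double init_nfr = 0;
  double a_ff = 0, a_fn = 0, a_nn = 0;              // transient transitions
  double e_frp = 0, e_fnorp = 0, e_nrp = 0, e_nnorp = 0; // exits by source
  double b_pos[2] = {0, 0}, b_neg[2] = {0, 0};      // biopsy counts by state
  double r[2][2] = {{0, 0}, {0, 0}};                // PSA resp. [state][comp]
  double rx[2][2] = {{0, 0}, {0, 0}};
  double rx2[2][2] = {{0, 0}, {0, 0}};
  double loglik = 0;
};

// One E-step over the cohort. If gamma0 / gammaN are non-null they receive
// P(NFR | data) at year 0 per patient and at each observation year.
static void fb_cohort(const IntegerVector& nobs, const IntegerVector& exit_code,
                      const IntegerVector& biopsy, const NumericVector& psa,
                      const Pars& q, Stats& S,
                      NumericVector* gamma0, NumericVector* gammaN,
                      NumericVector* ll_pat) {
  const int np = nobs.size();
  const double tff = 1.0 - q.apr - q.efr_rp - q.efr_norp;
  const double tnn = 1.0 - q.enfr_rp - q.enfr_norp;
  int kmax = 1;
  for (int i = 0; i < np; ++i) kmax = std::max(kmax, (int)nobs[i]);
  std::vector<double> A(2 * (kmax + 1)), C(kmax + 1), E0(kmax + 1),
      E1(kmax + 1), D10(kmax + 1), D20(kmax + 1), D11(kmax + 1),
      D21(kmax + 1), B(2 * (kmax + 1));
  int base = 0;
  for (int i = 0; i < np; ++i) {
    const int k = nobs[i];
    A[0] = 1.0 - q.pi; A[1] = q.pi;
    double ll = 0.0;
    for (int t = 1; t <= k; ++t) {
      int j = base + t - 1;
      E0[t] = emis(q, 0, biopsy[j], psa[j], &D10[t], &D20[t]);
      E1[t] = emis(q, 1, biopsy[j], psa[j], &D11[t], &D21[t]);
      double a0 = A[2 * (t - 1)] * tff * E0[t];
      double a1 = (A[2 * (t - 1)] * q.apr + A[2 * (t - 1) + 1] * tnn) * E1[t];
      double c = a0 + a1;
      if (!(c > 0.0) || !R_finite(c))
        stop("non-finite likelihood for patient %d (year %d)", i + 1, t);
      A[2 * t] = a0 / c; A[2 * t + 1] = a1 / c;
      C[t] = c; ll += std::log(c);
    }
    // exit factor
    double d0 = 1.0, d1 = 1.0;
    switch (exit_code[i]) {
    case 0: break;
    case 1: d0 = q.efr_rp;   d1 = 0.0;         break;
    case 2: d0 = 0.0;        d1 = q.enfr_rp;   break;
    case 3: d0 = q.efr_norp; d1 = q.enfr_norp; break;
    default: stop("invalid exit code");
    }
    double Lex = A[2 * k] * d0 + A[2 * k + 1] * d1;
    if (!(Lex > 0.0) || !R_finite(Lex))
      stop("non-finite likelihood for patient %d (exit)", i + 1);
    ll += std::log(Lex);
    S.loglik += ll;
    if (ll_pat) (*ll_pat)[i] = ll;

    // backward pass (scaled); B[t] has the same scaling as beta-hat
    B[2 * k] = d0; B[2 * k + 1] = d1;
    for (int t = k; t >= 1; --t) {
      B[2 * (t - 1)] = (tff * E0[t] * B[2 * t] + q.apr * E1[t] * B[2 * t + 1]) / C[t];
      B[2 * (t - 1) + 1] = (tnn * E1[t] * B[2 * t + 1]) / C[t];
    }

    // posteriors and expected counts
    double g0 = A[1] * B[1] / Lex; // P(NFR at diagnosis | data)
    S.init_nfr += g0;
    if (gamma0) (*gamma0)[i] = g0;
    for (int t = 1; t <= k; ++t) {
      int j = base + t - 1;
      double gN = A[2 * t + 1] * B[2 * t + 1] / Lex;
      double gF = 1.0 - gN;
      if (gammaN) (*gammaN)[j] = gN;
      double inv = 1.0 / (C[t] * Lex);
      S.a_ff += A[2 * (t - 1)] * tff * E0[t] * B[2 * t] * inv;
      S.a_fn += A[2 * (t - 1)] * q.apr * E1[t] * B[2 * t + 1] * inv;
      S.a_nn += A[2 * (t - 1) + 1] * tnn * E1[t] * B[2 * t + 1] * inv;
      if (biopsy[j] == 1) { S.b_neg[0] += gF; S.b_neg[1] += gN; }
      else if (biopsy[j] == 2) { S.b_pos[0] += gF; S.b_pos[1] += gN; }
      if (!ISNA(psa[j])) {
        double x = psa[j];
        double f0 = D10[t] + D20[t], f1 = D11[t] + D21[t];
        if (f0 > 0.0) {
          double r1 = gF * D10[t] / f0, r2 = gF * D20[t] / f0;
          S.r[0][0] += r1; S.rx[0][0] += r1 * x; S.rx2[0][0] += r1 * x * x;
          S.r[0][1] += r2; S.rx[0][1] += r2 * x; S.rx2[0][1] += r2 * x * x;
        }
        if (f1 > 0.0) {
          double r1 = gN * D11[t] / f1, r2 = gN * D21[t] / f1;
          S.r[1][0] += r1; S.rx[1][0] += r1 * x; S.rx2[1][0] += r1 * x * x;
          S.r[1][1] += r2; S.rx[1][1] += r2 * x; S.rx2[1][1] += r2 * x * x;
        }
      }
    }
    // exit transition counts
    switch (exit_code[i]) {
    case 1: S.e_frp += 1.0; break;
    case 2: S.e_nrp += 1.0; break;
    case 3: {
      double xf = A[2 * k] * q.efr_norp / Lex;
      double xn = A[2 * k + 1] * q.enfr_norp / Lex;
      S.e_fnorp += xf; S.e_nnorp += xn;
      break;
    }
    default: break;
    }
    base += k;
  }
}

static List stats_to_list(const Stats& S, int np) {
  NumericVector counts = NumericVector::create(
    _["init_nfr"] = S.init_nfr, _["fr_fr"] = S.a_ff, _["fr_nfr"] = S.a_fn,
    _["nfr_nfr"] = S.a_nn, _["fr_rpfav"] = S.e_frp, _["fr_norp"] = S.e_fnorp,
    _["nfr_rpnonfav"] = S.e_nrp, _["nfr_norp"] = S.e_nnorp);
  NumericVector bio = NumericVector::create(
    _["pos_fr"] = S.b_pos[0], _["neg_fr"] = S.b_neg[0],
    _["pos_nfr"] = S.b_pos[1], _["neg_nfr"] = S.b_neg[1]);
  NumericMatrix ps(4, 3);
  rownames(ps) = CharacterVector::create("fr.1", "fr.2", "nfr.1", "nfr.2");
  colnames(ps) = CharacterVector::create("r", "rx", "rx2");
  for (int s = 0; s < 2; ++s)
    for (int c = 0; c < 2; ++c) {
      int row = 2 * s + c;
      ps(row, 0) = S.r[s][c]; ps(row, 1) = S.rx[s][c]; ps(row, 2) = S.rx2[s][c];
    }
  return List::create(_["loglik"] = S.loglik, _["n_patients"] = np,
                      _["counts"] = counts, _["biopsy"] = bio, _["psa"] = ps);
}

// [[Rcpp::export]]
List cpp_fb(IntegerVector nobs, IntegerVector exit_code, IntegerVector biopsy,
            NumericVector psa, NumericVector par) {
  Pars q = unpack(par);
  Stats S;
  NumericVector gamma0(nobs.size()), gammaN(biopsy.size()),
                ll_pat(nobs.size());
  fb_cohort(nobs, exit_code, biopsy, psa, q, S, &gamma0, &gammaN, &ll_pat);
  List out = stats_to_list(S, nobs.size());
  out["gamma0"] = gamma0;
  out["gamma"] = gammaN;
  out["loglik_patient"] = ll_pat;
  return out;
}

// closed-form Baum-Welch update from expected counts; parameters whose
// expected denominator is (numerically) empty are held at their current value
static Pars m_update(const Stats& S, const Pars& cur, int np, double var_floor,
                     bool* held) {
  Pars q = cur;
  *held = false;
  const double tiny = 1e-12;
  q.pi = S.init_nfr / np;
  double dF = S.a_ff + S.a_fn + S.e_frp + S.e_fnorp;
  if (dF > tiny) {
    q.apr = S.a_fn / dF; q.efr_rp = S.e_frp / dF; q.efr_norp = S.e_fnorp / dF;
  } else *held = true;
  double dN = S.a_nn + S.e_nrp + S.e_nnorp;
  if (dN > tiny) {
    q.enfr_rp = S.e_nrp / dN; q.enfr_norp = S.e_nnorp / dN;
  } else *held = true;
  double bn = S.b_pos[1] + S.b_neg[1];
  if (bn > tiny) q.sens = S.b_pos[1] / bn; else *held = true;
  double bf = S.b_pos[0] + S.b_neg[0];
  if (bf > tiny) q.spec = S.b_neg[0] / bf; else *held = true;
  for (int s = 0; s < 2; ++s) {
    double tot = S.r[s][0] + S.r[s][1];
    if (tot <= tiny) { *held = true; continue; }
    q.w[s] = S.r[s][0] / tot;
    if (S.r[s][0] > tiny) {
      double mu = S.rx[s][0] / S.r[s][0];
      double v = S.rx2[s][0] / S.r[s][0] - mu * mu;
      q.m1[s] = mu; q.s1[s] = std::sqrt(std::max(v, var_floor));
    }
    if (S.r[s][1] > tiny) {
      double mu = S.rx[s][1] / S.r[s][1];
      double v = S.rx2[s][1] / S.r[s][1] - mu * mu;
      q.m2[s] = mu; q.s2[s] = std::sqrt(std::max(v, var_floor));
    }
  }
  return q;
}

// [[Rcpp::export]]
List cpp_m_step(List stats, NumericVector par, double var_floor) {
  Pars cur = unpack(par);
  Stats S;
  NumericVector counts = stats["counts"], bio = stats["biopsy"];
  NumericMatrix ps = stats["psa"];
  int np = stats["n_patients"];
  S.init_nfr = counts["init_nfr"];
  S.a_ff = counts["fr_fr"]; S.a_fn = counts["fr_nfr"]; S.a_nn = counts["nfr_nfr"];
  S.e_frp = counts["fr_rpfav"]; S.e_fnorp = counts["fr_norp"];
  S.e_nrp = counts["nfr_rpnonfav"]; S.e_nnorp = counts["nfr_norp"];
  S.b_pos[0] = bio["pos_fr"]; S.b_neg[0] = bio["neg_fr"];
  S.b_pos[1] = bio["pos_nfr"]; S.b_neg[1] = bio["neg_nfr"];
  for (int s = 0; s < 2; ++s)
    for (int c = 0; c < 2; ++c) {
      int row = 2 * s + c;
      S.r[s][c] = ps(row, 0); S.rx[s][c] = ps(row, 1); S.rx2[s][c] = ps(row, 2);
    }
  bool held;
  Pars q = m_update(S, cur, np, var_floor, &held);
  return List::create(_["par"] = pack(q), _["held"] = held);
}

// [[Rcpp::export]]
List cpp_em(IntegerVector nobs, IntegerVector exit_code, IntegerVector biopsy,
            NumericVector psa, NumericVector par0, int max_iter,
            double rel_tol, double var_floor) {
  Pars q = unpack(par0);
  const int np = nobs.size();
  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false, any_held = false;
  double ll_prev = R_NegInf;
  int it = 0;
  for (; it < max_iter; ++it) {
    Stats S;
    fb_cohort(nobs, exit_code, biopsy, psa, q, S, nullptr, nullptr, nullptr);
    trace.push_back(S.loglik);
    if (it > 0 &&
        std::fabs(S.loglik - ll_prev) <
          rel_tol * (std::fabs(ll_prev) + 1e-3)) {
      converged = true;
      break;
    }
    ll_prev = S.loglik;
    bool held;
    q = m_update(S, q, np, var_floor, &held);
    any_held = any_held || held;
  }
  return List::create(_["par"] = pack(q),
                      _["loglik"] = trace.empty() ? R_NegInf : trace.back(),
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int)trace.size(),
                      _["converged"] = converged,
                      _["emission_held"] = any_held);
}
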