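#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Codons are 1-based; codon 1 is START and carries no density. Rate vectors
// passed from R cover codons 2..L (k_L is the termination rate), so internal
// arrays are indexed by codon with slot 0..1 unused.

// ---------------------------------------------------------------------------
// Initiation-limited series expansion of the stationary l-TASEP.
//
// Stationary probabilities are expanded in powers of the initiation rate
// (equivalently 1/kappa): configurations with n ribosomes carry weight
// O(alpha^n).  Working in units alpha = 1 with relative rates kappa_i, and
// writing p(C) = P(C)/P(empty):
//   singles:  p(S_i) = c_i + e_i,  c_i = 1/kappa_i (order 1), e_i (order 2)
//   pairs:    p(i,j) = d_ij        (order 2), A-site spacing j - i >= ell
// Per-state flux balance at each order gives forward recursions for c, d, e.
// Truncating after two-ribosome configurations leaves an absolute density
// error of third order in 1/kappa.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector ila_rho_cpp(NumericVector kappa, int ell) {
  const int n = kappa.size();      // codons 2..L
  const int L = n + 1;
  std::vector<double> K(L + 1, 0.0), c(L + 1, 0.0), e(L + 1, 0.0);
  for (int i = 2; i <= L; ++i) {
    K[i] = kappa[i - 2];
    if (K[i] <= 0.0) stop("all kappa must be positive");
    c[i] = 1.0 / K[i];
  }

  // pair amplitudes d[i][j], i = 2..L-ell, j = i+ell..L
  std::vector<std::vector<double> > d;
  const bool pairs = (L - ell >= 2);
  if (pairs) d.assign(L + 1, std::vector<double>(L + 1, 0.0));
  double dsum = 0.0;
  if (pairs) {
    for (int i = 2; i <= L - ell; ++i) {
      for (int j = i + ell; j <= L; ++j) {
        double denom = K[j] + ((j >= i + ell + 1) ? K[i] : 0.0);
        double num = 0.0;
        if (i == 2 && j >= ell + 2) num += c[j];          // initiation onto S_j
        if (i >= 3)                 num += K[i - 1] * d[i - 1][j];
        if (j - 1 >= i + ell)       num += K[j - 1] * d[i][j - 1];
        d[i][j] = num / denom;
        dsum += d[i][j];
      }
    }
  }

  // second-order single-ribosome corrections
  for (int i = 2; i <= L; ++i) {
    double num = 0.0;
    if (i >= 3) num += K[i - 1] * e[i - 1];
    if (i >= ell + 2) num -= c[i];                    // initiation out of S_i
    if (pairs && i + ell <= L) num += K[L] * d[i][L]; // pair partner terminates
    e[i] = num / K[i];
  }

  // consistent second-order truncation of rho_i = Num_i / Z: the extensive
  // normalization contribution c_i * sum_j c_j cancels against the pair sum
  // (distant pairs factorize, d_ij -> c_i c_j), leaving a local correction
  // that stays bounded for long transcripts
  (void)dsum;
  double csum = 0.0;
  for (int i = 2; i <= L; ++i) csum += c[i];

  NumericVector rho(n);
  for (int i = 2; i <= L; ++i) {
    double D = 0.0;
    if (pairs) {
      if (i <= L - ell) for (int j = i + ell; j <= L; ++j) D += d[i][j];
      for (int j = 2; j <= i - ell; ++j) D += d[j][i];
    }
    rho[i - 2] = c[i] + e[i] + D - c[i] * csum;
  }
  return rho;
}

// ---------------------------------------------------------------------------
// Continuous-time (Gillespie) simulation of the inhomogeneous l-TASEP.
// Ribosomes are tracked by A-site position; two A-sites are at least ell
// codons apart.  Initiation (rate alpha) needs codons 2..ell+1 free of
// A-sites; a hop i -> i+1 (rate k_i) needs the next downstream A-site at
// i+ell+1 or beyond; termination from codon L (rate k_L) needs nothing.
// ---------------------------------------------------------------------------

namespace {

struct Rng {
  std::uint64_t s[2];
  explicit Rng(std::uint64_t seed) {
    // splitmix64 expansion of the seed
    std::uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      std::uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  std::uint64_t next() { // xoroshiro128+
    std::uint64_t a = s[0], b = s[1];
    std::uint64_t r = a + b;
    b ^= a;
    s[0] = ((a << 55) | (a >> 9)) ^ b ^ (b << 14);
    s[1] = (b << 36) | (b >> 28);
    return r;
  }
  double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

} // namespace

// [[Rcpp::export]]
List gillespie_cpp(NumericVector kappa, double alpha, int ell,
                   int burn_terminations, double burn_max_time,
                   double sample_time, int n_batches, double seed) {
  const int n = kappa.size();
  const int L = n + 1;
  if (L < ell + 1) stop("L must be at least ell + 1");
  std::vector<double> K(L + 1, 0.0);
  for (int i = 2; i <= L; ++i) {
    K[i] = kappa[i - 2];
    if (K[i] <= 0.0) stop("all rates must be positive");
  }
  if (alpha <= 0.0) stop("alpha must be positive");
  if (sample_time <= 0.0) stop("sample_time must be positive");

  Rng rng(static_cast<std::uint64_t>(seed));
  std::vector<int> pos;            // ascending A-site positions
  pos.reserve(L / ell + 2);
  std::vector<double> rates;
  rates.reserve(L / ell + 3);

  const int B = n_batches;
  const double batch_len = sample_time / B;
  std::vector<std::vector<double> > rho_b(B, std::vector<double>(L + 1, 0.0));
  std::vector<double> tie_b(B, 0.0), term_b(B, 0.0);
  std::vector<std::vector<double> > occ_b(B, std::vector<double>(L + 1, 0.0));
  std::vector<std::vector<double> > clr_b(B, std::vector<double>(L + 1, 0.0));
  std::vector<double> bond_cnt(L + 1, 0.0);
  double init_cnt = 0.0;
  long long terms = 0;
  bool sampling = false;
  double t = 0.0;

  // enabled moves; rates[0] is initiation (0 if blocked), then one per ribosome
  auto build_rates = [&](double &total) {
    rates.clear();
    bool init_ok = pos.empty() || pos.front() >= ell + 2;
    rates.push_back(init_ok ? alpha : 0.0);
    total = rates[0];
    const int m = (int)pos.size();
    for (int r = 0; r < m; ++r) {
      int i = pos[r];
      double rt;
      if (i == L) rt = K[L];
      else if (r == m - 1 || pos[r + 1] >= i + ell + 1) rt = K[i];
      else rt = 0.0;
      rates.push_back(rt);
      total += rt;
    }
  };

  auto accumulate = [&](double t0, double dt) {
    const int m = (int)pos.size();
    bool tie_ok = pos.empty() || pos.front() >= ell + 2;
    double cur = t0, remaining = dt;
    while (remaining > 1e-300) {
      int b = (int)(cur / batch_len);
      if (b >= B) b = B - 1;
      double seg = (b + 1) * batch_len - cur;
      if (seg > remaining) seg = remaining;
      if (seg <= 0.0) seg = remaining;  // guard against fp edge
      for (int r = 0; r < m; ++r) {
        int i = pos[r];
        rho_b[b][i] += seg;
        occ_b[b][i] += seg;
        bool clear = (i == L) || (r == m - 1) || (pos[r + 1] > i + ell);
        if (clear) clr_b[b][i] += seg;
      }
      if (tie_ok) tie_b[b] += seg;
      cur += seg;
      remaining -= seg;
    }
  };

  // burn-in: run until a termination quota or a wall of simulated time
  long long burn_terms = 0;
  double burn_t = 0.0;
  while (burn_terms < burn_terminations && burn_t < burn_max_time) {
    double total;
    build_rates(total);
    burn_t += -std::log(rng.unif()) / total;
    double u = rng.unif() * total, acc = 0.0;
    int ev = -1;
    for (int r = 0; r < (int)rates.size(); ++r) {
      acc += rates[r];
      if (u <= acc) { ev = r; break; }
    }
    if (ev < 0) ev = (int)rates.size() - 1;
    if (ev == 0) pos.insert(pos.begin(), 2);
    else {
      int r = ev - 1;
      if (pos[r] == L) { pos.pop_back(); ++burn_terms; }
      else ++pos[r];
    }
  }

  // sampling window
  sampling = true;
  t = 0.0;
  while (t < sample_time) {
    double total;
    build_rates(total);
    double dt = -std::log(rng.unif()) / total;
    if (t + dt >= sample_time) {
      accumulate(t, sample_time - t);
      t = sample_time;
      break;
    }
    accumulate(t, dt);
    t += dt;
    double u = rng.unif() * total, acc = 0.0;
    int ev = -1;
    for (int r = 0; r < (int)rates.size(); ++r) {
      acc += rates[r];
      if (u <= acc) { ev = r; break; }
    }
    if (ev < 0) ev = (int)rates.size() - 1;
    int b = (int)(t / batch_len);
    if (b >= B) b = B - 1;
    if (ev == 0) {
      pos.insert(pos.begin(), 2);
      init_cnt += 1.0;
    } else {
      int r = ev - 1;
      int i = pos[r];
      bond_cnt[i] += 1.0;
      if (i == L) {
        pos.pop_back();
        ++terms;
        term_b[b] += 1.0;
      } else {
        ++pos[r];
      }
    }
  }
  (void)sampling;

  // batch-means summaries
  NumericVector rho(n), rho_se(n), tee(n), tee_se(n), J_bond(n);
  double tie = 0.0, tie_se = 0.0, J = 0.0, J_se = 0.0;
  for (int i = 2; i <= L; ++i) {
    double mtot = 0.0, m2 = 0.0;
    for (int b = 0; b < B; ++b) mtot += rho_b[b][i];
    double mean = mtot / sample_time;
    for (int b = 0; b < B; ++b) {
      double x = rho_b[b][i] / batch_len - mean;
      m2 += x * x;
    }
    rho[i - 2] = mean;
    rho_se[i - 2] = std::sqrt(m2 / (B - 1.0) / B);
    J_bond[i - 2] = bond_cnt[i] / sample_time;

    double osum = 0.0, csum = 0.0;
    for (int b = 0; b < B; ++b) { osum += occ_b[b][i]; csum += clr_b[b][i]; }
    if (osum > 0.0) {
      double ratio = csum / osum;
      tee[i - 2] = ratio;
      int nb = 0; double v = 0.0;
      for (int b = 0; b < B; ++b) {
        if (occ_b[b][i] > 0.0) {
          double x = clr_b[b][i] / occ_b[b][i] - ratio;
          v += x * x;
          ++nb;
        }
      }
      tee_se[i - 2] = nb > 1 ? std::sqrt(v / (nb - 1.0) / nb) : NA_REAL;
    } else {
      tee[i - 2] = NA_REAL;
      tee_se[i - 2] = NA_REAL;
    }
  }
  {
    double msum = 0.0;
    for (int b = 0; b < B; ++b) msum += tie_b[b];
    tie = msum / sample_time;
    double v = 0.0;
    for (int b = 0; b < B; ++b) {
      double x = tie_b[b] / batch_len - tie;
      v += x * x;
    }
    tie_se = std::sqrt(v / (B - 1.0) / B);
    double jm = 0.0;
    for (int b = 0; b < B; ++b) jm += term_b[b];
    J = jm / sample_time;
    double jv = 0.0;
    for (int b = 0; b < B; ++b) {
      double x = term_b[b] / batch_len - J;
      jv += x * x;
    }
    J_se = std::sqrt(jv / (B - 1.0) / B);
  }

  return List::create(
    _["rho"] = rho, _["rho_se"] = rho_se,
    _["tie"] = tie, _["tie_se"] = tie_se,
    _["tee"] = tee, _["tee_se"] = tee_se,
    _["J"] = J, _["J_se"] = J_se,
    _["J_bond"] = J_bond,
    _["J_init"] = init_cnt / sample_time,
    _["n_terminations"] = (double)terms,
    _["burn_time"] = burn_t,
    _["burn_terminations"] = (double)burn_terms);
}
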