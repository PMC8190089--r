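#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Parameter vector layout shared with R (see .param_vector in R/model.R):
//  0 N        1 k_act    2 k_rep    3 k_noise  4 v0       5 vJ
//  6 phi      7 sigma_J  8 lambda_J 9 T_J     10 sigma_S 11 lambda_S
// 12 T_S     13 T_D     14 kappa_D 15 rho_D   16 D_min   17 alpha
// 18 alpha0  19 delta   20 vUA_S   21 r_init
enum Par { iN, iKact, iKrep, iKnoise, iV0, iVJ, iPhi, iSigJ, iLamJ, iTJ,
           iSigS, iLamS, iTS, iTD, iKapD, iRhoD, iDmin, iAlpha, iAlpha0,
           iDelta, iVUAS, iRinit };

// piecewise-constant temperature lookup: value on [t_i, t_{i+1}) is temps[i];
// the final step extends to the profile duration.
static double temp_at(const std::vector<double>& bt, const std::vector<double>& bT,
                      double t) {
  // bt strictly increasing, bt[0] == 0
  size_t lo = 0, hi = bt.size();
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (bt[mid] <= t) lo = mid; else hi = mid;
  }
  return bT[lo];
}

struct Rhs {
  const double* p;
  double T;  // current temperature (constant within a mesh interval)
  // y = (J, S, D, r, a, m)
  void operator()(const double* y, double* dy) const {
    const double indJ = (T >= p[iTJ]) ? 1.0 : 0.0;
    const double indS = (T >= p[iTS]) ? 1.0 : 0.0;
    const double J = y[0], S = y[1], D = y[2], r = y[3], a = y[4], m = y[5];
    dy[0] = p[iSigJ] * indJ - p[iLamJ] * J;
    dy[1] = p[iSigS] * indS - p[iLamS] * S;
    dy[2] = (T >= p[iTD]) ? -p[iKapD] * (D - p[iDmin]) : p[iRhoD] * (1.0 - D);
    const double u = 1.0 - r - a;
    dy[3] = (p[iKrep] * r + p[iKnoise]) * u
          - (p[iKact] * a + p[iKnoise] + p[iV0] + p[iVJ] * p[iPhi] * J) * r;
    dy[4] = (p[iKact] * a + p[iKnoise] + p[iVUAS] * S) * u
          - (p[iKrep] * r + p[iKnoise]) * a;
    dy[5] = D * (p[iAlpha0] + p[iAlpha] * S * a * (1.0 - r)) - p[iDelta] * m;
  }
};

static void rk4_step(const Rhs& f, double* y, double h, int n) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  f(y, k1);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  f(tmp, k2);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  f(tmp, k3);
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * k3[i];
  f(tmp, k4);
  for (int i = 0; i < n; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Build the integration mesh: output grid 0, dt, ..., duration merged with the
// profile breakpoints, so every interval has constant temperature.
static void build_mesh(const std::vector<double>& bt, double duration, double dt,
                       std::vector<double>& mesh, std::vector<int>& out_idx) {
  std::vector<double> grid;
  int n_out = (int)std::ceil(duration / dt - 1e-12) + 1;
  for (int i = 0; i < n_out; ++i) grid.push_back(std::min(i * dt, duration));
  if (grid.back() < duration) grid.push_back(duration);
  std::vector<double> all(grid);
  for (double b : bt) if (b > 0.0 && b < duration) all.push_back(b);
  std::sort(all.begin(), all.end());
  all.erase(std::unique(all.begin(), all.end(),
            [](double a, double b){ return std::fabs(a - b) < 1e-12; }), all.end());
  mesh = all;
  out_idx.clear();
  size_t j = 0;
  for (size_t i = 0; i < mesh.size(); ++i) {
    if (j < grid.size() && std::fabs(mesh[i] - grid[j]) < 1e-12) {
      out_idx.push_back((int)i);
      ++j;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector bp_times, NumericVector bp_temps,
                           double duration, NumericVector pars, double dt) {
  std::vector<double> bt(bp_times.begin(), bp_times.end());
  std::vector<double> bT(bp_temps.begin(), bp_temps.end());
  const double* p = REAL(pars);
  std::vector<double> mesh; std::vector<int> out_idx;
  build_mesh(bt, duration, dt, mesh, out_idx);

  double y[6] = {0.0, 0.0, 1.0, p[iRinit], 0.0,
                 p[iDelta] > 0 ? p[iAlpha0] / p[iDelta] : 0.0};
  NumericMatrix out((int)out_idx.size(), 7);
  Rhs f; f.p = p;
  size_t oi = 0;
  for (size_t i = 0; i + 1 <= mesh.size(); ++i) {
    if (oi < out_idx.size() && (int)i == out_idx[oi]) {
      out(oi, 0) = mesh[i];
      for (int k = 0; k < 6; ++k) out(oi, k + 1) = y[k];
      ++oi;
    }
    if (i + 1 == mesh.size()) break;
    f.T = temp_at(bt, bT, mesh[i]);
    rk4_step(f, y, mesh[i + 1] - mesh[i], 6);
    if (!std::isfinite(y[3]) || !std::isfinite(y[4]) || !std::isfinite(y[5]))
      stop("integration produced non-finite state at t = %f h", mesh[i + 1]);
  }
  colnames(out) = CharacterVector::create("time_h", "J", "S", "D", "r", "a", "m");
  return out;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Exact stochastic simulation of the N-nucleosome locus with rates held
// piecewise-constant on the signal grid; mRNA integrated exactly (linear ODE
// with piecewise-constant coefficients between state changes).
// [[Rcpp::export]]
List cpp_ssa(NumericVector bp_times, NumericVector bp_temps, double duration,
             NumericVector pars, int n_runs, double seed, double dt) {
  std::vector<double> bt(bp_times.begin(), bp_times.end());
  std::vector<double> bT(bp_temps.begin(), bp_temps.end());
  const double* p = REAL(pars);
  const int N = (int)std::lround(p[iN]);

  // signals on the mesh (J, S, D only; r,a,m slots integrated but unused)
  std::vector<double> mesh; std::vector<int> out_idx;
  build_mesh(bt, duration, dt, mesh, out_idx);
  const int n_out = (int)out_idx.size();
  std::vector<double> gJ(n_out), gS(n_out), gD(n_out), gt(n_out);
  {
    double y[6] = {0.0, 0.0, 1.0, 0.0, 0.0, 0.0};
    Rhs f; f.p = p;
    size_t oi = 0;
    for (size_t i = 0; i < mesh.size(); ++i) {
      if (oi < (size_t)n_out && (int)i == out_idx[oi]) {
        gt[oi] = mesh[i]; gJ[oi] = y[0]; gS[oi] = y[1]; gD[oi] = y[2];
        ++oi;
      }
      if (i + 1 == mesh.size()) break;
      f.T = temp_at(bt, bT, mesh[i]);
      rk4_step(f, y, mesh[i + 1] - mesh[i], 6);
    }
  }

  std::vector<double> sum_r(n_out, 0.0), sum_a(n_out, 0.0), sum_m(n_out, 0.0);
  std::vector<double> ss_r(n_out, 0.0), ss_m(n_out, 0.0);

  const double kact = p[iKact], krep = p[iKrep], knoise = p[iKnoise],
               v0 = p[iV0], vJphi = p[iVJ] * p[iPhi], vUAS = p[iVUAS],
               alpha = p[iAlpha], alpha0 = p[iAlpha0], delta = p[iDelta];
  const int nR0 = (int)std::lround(p[iRinit] * N);

  for (int run = 0; run < n_runs; ++run) {
    std::mt19937_64 rng(splitmix64((uint64_t)std::llround(seed) +
                                   0x100000001ULL * (uint64_t)run));
    std::uniform_real_distribution<double> U(0.0, 1.0);
    int nR = nR0, nA = 0;
    double m = delta > 0 ? alpha0 / delta : 0.0;
    for (int c = 0; c < n_out; ++c) {
      const double r = (double)nR / N, a = (double)nA / N;
      sum_r[c] += r; ss_r[c] += r * r;
      sum_m[c] += m; ss_m[c] += m * m;
      sum_a[c] += a;
      if (c + 1 == n_out) break;
      const double J = gJ[c], S = gS[c], D = gD[c];
      double t = gt[c];
      const double t_end = gt[c + 1];
      while (t < t_end) {
        const int nU = N - nR - nA;
        const double aRU = nR * (kact * nA / N + knoise + v0 + vJphi * J);
        const double aUR = nU * (krep * nR / N + knoise);
        const double aUA = nU * (kact * nA / N + knoise + vUAS * S);
        const double aAU = nA * (krep * nR / N + knoise);
        const double tot = aRU + aUR + aUA + aAU;
        const double remaining = t_end - t;
        double tau = remaining;
        bool fire = false;
        if (tot > 0.0) {
          double u1 = U(rng);
          while (u1 <= 0.0) u1 = U(rng);
          const double w = -std::log(u1) / tot;
          if (w < remaining) { tau = w; fire = true; }
        }
        // exact mRNA update over [t, t+tau] with constant production
        const double prod = D * (alpha0 + alpha * S * ((double)nA / N) *
                                 (1.0 - (double)nR / N));
        if (delta > 0) {
          const double mss = prod / delta;
          m = mss + (m - mss) * std::exp(-delta * tau);
        } else {
          m += prod * tau;
        }
        t += tau;
        if (fire) {
          const double u2 = U(rng) * tot;
          if (u2 < aRU)                { --nR; }
          else if (u2 < aRU + aUR)     { ++nR; }
          else if (u2 < aRU + aUR + aUA) { ++nA; }
          else                         { --nA; }
        }
      }
    }
  }

  NumericVector r_mean(n_out), a_mean(n_out), m_mean(n_out),
                r_sem(n_out), m_sem(n_out), tv(n_out);
  for (int c = 0; c < n_out; ++c) {
    tv[c] = gt[c];
    const double mr = sum_r[c] / n_runs, mm = sum_m[c] / n_runs;
    r_mean[c] = mr; a_mean[c] = sum_a[c] / n_runs; m_mean[c] = mm;
    if (n_runs > 1) {
      const double vr = std::max(0.0, (ss_r[c] - n_runs * mr * mr) / (n_runs - 1));
      const double vm = std::max(0.0, (ss_m[c] - n_runs * mm * mm) / (n_runs - 1));
      r_sem[c] = std::sqrt(vr / n_runs);
      m_sem[c] = std::sqrt(vm / n_runs);
    } else {
      r_sem[c] = 0.0; m_sem[c] = 0.0;
    }
  }
  return List::create(_["time_h"] = tv, _["r"] = r_mean, _["a"] = a_mean,
                      _["m"] = m_mean, _["sem_r"] = r_sem, _["sem_m"] = m_sem,
                      _["J"] = NumericVector(gJ.begin(), gJ.end()),
                      _["S"] = NumericVector(gS.begin(), gS.end()),
                      _["D"] = NumericVector(gD.begin(), gD.end()));
}
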