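// Stochastic integration core for the multi-area covert-search accumulator
// network: 6 LIP units + 6 LIP input OU processes, 2 IT units + 2 IT OU
// processes, 2 gated AIP accumulators and 2 thresholded motor units (20 SDEs).
//
// State layout (indices):
//   0..5   x_lip   (L1, L2, L3, R1, R2, R3)
//   6..11  rho_lip (same order)
//   12..13 x_it    (left-facing, right-facing)
//   14..15 rho_it  (same order)
//   16..17 x_aip   (L, R)
//   18..19 x_m     (L, R)
//
// Trial-level RNG is a counter-seeded xoshiro256++ stream (seeded by
// splitmix64 from the master seed, a stream id and the trial index), so every
// trial is reproducible independently of batch order.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// ---- parameter vector layout (kept in step with R/parameters.R) ----
enum Par {
  P_DELAY, T_DELAY, TAU_M, TAU_IT, TAU_AIP, TAU_LIP,
  ETA_MAIPIT, ETA_LIP, ETA_DECAY1, ETA_DECAY2, ALPHA_LIP,
  W_AIPM, W_ITAIP, W_LIPAIP, W_AIPLIP, BETA_AIPLIP, BETA_MAIP, BETA_MITLIP,
  S_LIP, S_TAR, S_BACK, S_ORI, C_MAIP, C_IT, C_LIP,
  K_M, G_M, K_AIP, G_AIP, T_0, THETA, N_PAR
};

// ---- counter-based RNG ----
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0, 1]
  double unif() { return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0); }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), a = 6.283185307179586 * v;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

inline uint64_t trial_seed(uint64_t master, uint64_t stream, uint64_t trial) {
  uint64_t x = master;
  uint64_t a = Xoshiro::splitmix(x);
  x ^= stream * 0xD1342543DE82EF95ULL + 0x2545F4914F6CDD1DULL;
  uint64_t b = Xoshiro::splitmix(x);
  x ^= trial * 0x9E3779B97F4A7C15ULL;
  uint64_t c = Xoshiro::splitmix(x);
  return a ^ (b + 0x165667B19E3779F9ULL) ^ Xoshiro::rotl(c, 17);
}

// ---- deterministic nonlinearities ----
inline double phi_fun(double I) {
  double u = I - 0.384;
  if (std::fabs(u) < 1e-12) return 0.001 + 0.352 / 355.52;
  double denom = -std::expm1(-352.0 * u) + 3.52 * u;
  return 0.001 + 0.352 * u / denom;
}

inline double gate_fun(double I, double g) {
  double d = I - g;
  return d > 0.0 ? d : 0.0;
}

inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// ring-distance neighbour lists for the six LIP units, on the cycle
// L1 - R1 - R2 - R3 - L3 - L2 - L1 (indices 0,3,4,5,2,1)
const int NB1[6][2] = {{3, 1}, {0, 2}, {1, 5}, {0, 4}, {3, 5}, {2, 4}};
const int NB2[6][2] = {{4, 2}, {3, 5}, {0, 4}, {1, 5}, {0, 2}, {1, 3}};
const int NB3[6]    = {5, 4, 3, 2, 1, 0};

struct Condition {
  int set_size;   // 2, 4, 6
  int pos;        // 0..5 (L1,L2,L3,R1,R2,R3)
  int ori;        // 0 = left-facing, 1 = right-facing
};

inline double i_per(int set_size, int loc, double s_lip) {
  // perceptual input: L1,R1 for set size 2; L1,R1,L2,R2 for 4; all for 6
  if (set_size == 6) return s_lip;
  if (set_size == 4) return (loc == 0 || loc == 3 || loc == 1 || loc == 4) ? s_lip : 0.0;
  return (loc == 0 || loc == 3) ? s_lip : 0.0;
}

struct Engine {
  const double *p;        // parameter vector, Par layout
  double tau_noise, dt, motor_cap;
  bool lip_leak, clamp_nonneg;
  int noise_scale;        // 0: c/tau (literal), 1: c/sqrt(tau)
  Condition cond;

  void drift(const double *x, double t, double *dx) const {
    double i_mi = p[BETA_MITLIP] * (x[18] + x[19]);
    double i_maip = p[BETA_MAIP] * (x[18] + x[19]);
    // LIP units
    for (int i = 0; i < 6; ++i) {
      bool left = i < 3;
      double x_aip_same = left ? x[16] : x[17];
      double x_aip_opp  = left ? x[17] : x[16];
      double inhib = p[ETA_LIP] * ((x[NB1[i][0]] + x[NB1[i][1]])
                   + p[ETA_DECAY1] * (x[NB2[i][0]] + x[NB2[i][1]])
                   + p[ETA_DECAY1] * p[ETA_DECAY2] * x[NB3[i]]);
      double I = -p[BETA_AIPLIP] * x_aip_opp + p[W_AIPLIP] * x_aip_same
               + p[ALPHA_LIP] * x[i] - i_mi - inhib + x[6 + i];
      dx[i] = (phi_fun(I) - (lip_leak ? x[i] : 0.0)) / p[TAU_LIP];
    }
    // LIP input OU processes
    for (int i = 0; i < 6; ++i) {
      double inp = i_per(cond.set_size, i, p[S_LIP]) * heav(t - p[P_DELAY])
                 + (cond.pos == i ? p[S_TAR] : 0.0) * heav(t - p[P_DELAY] - p[T_DELAY])
                 + p[S_BACK];
      dx[6 + i] = (-x[6 + i] + inp) / tau_noise;
    }
    // IT units (0 left-facing, 1 right-facing)
    for (int k = 0; k < 2; ++k) {
      double I = x[14 + k] - p[ETA_MAIPIT] * x[12 + (1 - k)] - i_mi;
      dx[12 + k] = (phi_fun(I) - x[12 + k]) / p[TAU_IT];
    }
    // IT input OU processes
    for (int k = 0; k < 2; ++k) {
      double inp = (cond.ori == k ? p[S_ORI] : 0.0) * heav(t - p[P_DELAY] - p[T_DELAY]);
      dx[14 + k] = (-x[14 + k] + inp) / tau_noise;
    }
    // AIP (left-facing IT drives left AIP; same-hemifield LIP sum)
    for (int k = 0; k < 2; ++k) {
      double lip_sum = k == 0 ? x[0] + x[1] + x[2] : x[3] + x[4] + x[5];
      double gin = p[W_ITAIP] * x[12 + k] + p[W_LIPAIP] * lip_sum - i_maip;
      dx[16 + k] = (-p[K_AIP] * x[16 + k] - p[ETA_MAIPIT] * x[16 + (1 - k)]
                   + gate_fun(gin, p[G_AIP])) / p[TAU_AIP];
    }
    // motor
    for (int k = 0; k < 2; ++k) {
      dx[18 + k] = (-p[K_M] * x[18 + k] - p[ETA_MAIPIT] * x[18 + (1 - k)]
                   + gate_fun(p[W_AIPM] * x[16 + k], p[G_M])) / p[TAU_M];
    }
  }

  void noise_amp(double *g) const {
    for (int i = 0; i < 20; ++i) g[i] = 0.0;
    double tl = noise_scale == 0 ? tau_noise : std::sqrt(tau_noise);
    double ta = noise_scale == 0 ? p[TAU_AIP] : std::sqrt(p[TAU_AIP]);
    double tm = noise_scale == 0 ? p[TAU_M] : std::sqrt(p[TAU_M]);
    for (int i = 0; i < 6; ++i) g[6 + i] = p[C_LIP] / tl;
    g[14] = g[15] = p[C_IT] / tl;
    g[16] = g[17] = p[C_MAIP] / ta;
    g[18] = g[19] = p[C_MAIP] / tm;
  }

  // one RK2 (Honeycutt) step with additive noise; psi: 20 N(0,1) draws
  void step(double *x, double t, const double *g, const double *psi) const {
    double f0[20], f1[20], xt[20];
    double sq = std::sqrt(dt);
    drift(x, t, f0);
    for (int i = 0; i < 20; ++i) xt[i] = x[i] + dt * f0[i] + sq * g[i] * psi[i];
    drift(xt, t + dt, f1);
    for (int i = 0; i < 20; ++i)
      x[i] += 0.5 * dt * (f0[i] + f1[i]) + sq * g[i] * psi[i];
    // clamps
    if (x[18] > motor_cap) x[18] = motor_cap;
    if (x[19] > motor_cap) x[19] = motor_cap;
    if (clamp_nonneg) {
      for (int k = 16; k < 20; ++k) if (x[k] < 0.0) x[k] = 0.0;
    }
  }
};

Engine make_engine(const NumericVector &par, const List &opts, Condition cond) {
  Engine e;
  if (par.size() != N_PAR) stop("parameter vector must have %d entries", (int)N_PAR);
  e.p = REAL(par);
  e.tau_noise = as<double>(opts["tau_noise"]);
  e.dt = as<double>(opts["dt"]);
  e.motor_cap = as<double>(opts["motor_cap"]);
  e.lip_leak = as<bool>(opts["lip_leak"]);
  e.clamp_nonneg = as<bool>(opts["clamp_nonneg"]);
  e.noise_scale = as<int>(opts["noise_scale"]);
  e.cond = cond;
  return e;
}

} // namespace

// Drift and noise-amplitude evaluation at an arbitrary state (used by tests
// to cross-check the R reference implementation).
// [[Rcpp::export]]
List cs_drift(NumericVector state, NumericVector par, int set_size, int pos,
              int ori, double t, List opts) {
  if (state.size() != 20) stop("state must have 20 entries");
  Condition cond{set_size, pos, ori};
  Engine e = make_engine(par, opts, cond);
  NumericVector dx(20), g(20);
  e.drift(REAL(state), t, REAL(dx));
  e.noise_amp(REAL(g));
  return List::create(_["drift"] = dx, _["noise"] = g);
}

// Simulate one batch of trials under a single condition.
// Returns crossing times (ms, NA on timeout), response sides (0 L, 1 R, NA),
// and optionally the running sum of LIP activities on a 1-ms grid
// (6 x n_grid), for mean-trajectory estimation.
// [[Rcpp::export]]
List cs_simulate_batch(NumericVector par, int set_size, int pos, int ori,
                       int n, double master_seed, double stream,
                       double t_max, List opts,
                       bool keep_traces, double trace_t_max) {
  Condition cond{set_size, pos, ori};
  Engine e = make_engine(par, opts, cond);
  double g[20];
  e.noise_amp(g);
  double theta = par[THETA];

  int steps_per_ms = (int)std::lround(1.0 / e.dt);
  if (std::fabs(steps_per_ms * e.dt - 1.0) > 1e-9)
    steps_per_ms = 0; // non-divisor dt: no grid snapping for traces
  int n_grid = keep_traces ? (int)std::floor(trace_t_max) + 1 : 0;
  NumericMatrix trace_sum(keep_traces ? 6 : 0, n_grid);
  // motor-unit running sums on the same grid (for diagnostics)
  NumericMatrix trace_sum_m(keep_traces ? 2 : 0, n_grid);

  NumericVector cross(n), rt(n);
  IntegerVector side(n);
  double psi[20];

  for (int tr = 0; tr < n; ++tr) {
    Xoshiro rng(trial_seed((uint64_t)master_seed, (uint64_t)stream, (uint64_t)tr));
    double x[20] = {0.0};
    double t = 0.0;
    int crossed = -1;
    double tcross = NA_REAL;
    double t_end = keep_traces ? std::max(t_max, trace_t_max) : t_max;
    int istep = 0;
    if (keep_traces && n_grid > 0) {
      for (int u = 0; u < 6; ++u) trace_sum(u, 0) += x[u];
      for (int u = 0; u < 2; ++u) trace_sum_m(u, 0) += x[18 + u];
    }
    while (t < t_end - 1e-9) {
      for (int i = 0; i < 20; ++i) psi[i] = (g[i] != 0.0) ? rng.norm() : 0.0;
      e.step(x, t, g, psi);
      t += e.dt;
      ++istep;
      bool finite = true;
      for (int i = 0; i < 20; ++i) if (!std::isfinite(x[i])) { finite = false; break; }
      if (!finite) stop("non-finite state at t = %.1f ms (trial %d)", t, tr + 1);
      if (crossed < 0 && (x[18] >= theta || x[19] >= theta)) {
        crossed = (x[19] > x[18]) ? 1 : 0;
        tcross = t;
        if (!keep_traces) break;
      }
      if (keep_traces && steps_per_ms > 0 && istep % steps_per_ms == 0) {
        int gi = istep / steps_per_ms;
        if (gi < n_grid) {
          for (int u = 0; u < 6; ++u) trace_sum(u, gi) += x[u];
          for (int u = 0; u < 2; ++u) trace_sum_m(u, gi) += x[18 + u];
        }
      }
      // once the response is in and the trace grid is filled, stop early
      if (keep_traces && crossed >= 0 && t >= trace_t_max - 1e-9) break;
    }
    if (crossed >= 0) {
      cross[tr] = tcross;
      rt[tr] = tcross + par[T_0];
      side[tr] = crossed;
    } else {
      cross[tr] = NA_REAL;
      rt[tr] = NA_REAL;
      side[tr] = NA_INTEGER;
    }
  }
  return List::create(_["crossing_ms"] = cross, _["rt_ms"] = rt,
                      _["side"] = side,
                      _["lip_trace_sum"] = trace_sum,
                      _["motor_trace_sum"] = trace_sum_m,
                      _["n"] = n);
}

// Simulate a single trial, returning the full state trajectory sampled every
// sample_every ms (plus the outcome). Used for plotting and spike synthesis.
// [[Rcpp::export]]
List cs_simulate_trial(NumericVector par, int set_size, int pos, int ori,
                       double seed, double stream, double trial_index,
                       double t_max, List opts, bool keep_trajectory,
                       double sample_every, bool stop_at_cross) {
  Condition cond{set_size, pos, ori};
  Engine e = make_engine(par, opts, cond);
  double g[20];
  e.noise_amp(g);
  double theta = par[THETA];
  Xoshiro rng(trial_seed((uint64_t)seed, (uint64_t)stream, (uint64_t)trial_index));

  int n_keep = keep_trajectory ? (int)std::floor(t_max / sample_every) + 1 : 0;
  NumericMatrix traj(keep_trajectory ? 20 : 0, n_keep);
  NumericVector traj_t(n_keep);
  int sample_steps = (int)std::lround(sample_every / e.dt);
  if (sample_steps < 1) sample_steps = 1;

  double x[20] = {0.0};
  double t = 0.0;
  int crossed = -1;
  double tcross = NA_REAL;
  double psi[20];
  int istep = 0, kept = 0;
  if (keep_trajectory) {
    for (int i = 0; i < 20; ++i) traj(i, 0) = x[i];
    traj_t[0] = 0.0;
    kept = 1;
  }
  while (t < t_max - 1e-9) {
    for (int i = 0; i < 20; ++i) psi[i] = (g[i] != 0.0) ? rng.norm() : 0.0;
    e.step(x, t, g, psi);
    t += e.dt;
    ++istep;
    bool finite = true;
    for (int i = 0; i < 20; ++i) if (!std::isfinite(x[i])) { finite = false; break; }
    if (!finite) stop("non-finite state at t = %.1f ms", t);
    if (keep_trajectory && istep % sample_steps == 0 && kept < n_keep) {
      for (int i = 0; i < 20; ++i) traj(i, kept) = x[i];
      traj_t[kept] = t;
      ++kept;
    }
    if (crossed < 0 && (x[18] >= theta || x[19] >= theta)) {
      crossed = (x[19] > x[18]) ? 1 : 0;
      tcross = t;
      if (stop_at_cross) break;
    }
  }
  if (keep_trajectory && kept < n_keep) {
    traj = traj(Range(0, 19), Range(0, kept - 1));
    traj_t = traj_t[Range(0, kept - 1)];
  }
  return List::create(
      _["crossing_ms"] = tcross,
      _["rt_ms"] = crossed >= 0 ? tcross + par[T_0] : NA_REAL,
      _["side"] = crossed >= 0 ? IntegerVector::create(crossed)
                               : IntegerVector::create(NA_INTEGER),
      _["trajectory"] = traj, _["trajectory_t"] = traj_t);
}
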