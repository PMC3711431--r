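// Exact stochastic simulation (Gillespie direct method) of the lac circuit.
//
// Species counts: n_Im (lacI mRNA), n_I (LacI tetramers), n_Y (LacY),
// n_Z (LacZ tetramers); 1 molecule == 1 nM. Eight channels: production and
// first-order decay of each species. Propensities depend on all counts
// through the quasi-steady-state sugar balance and the promoter occupancy
// model, and are recomputed after every event. External lactose is
// piecewise constant; waiting times are truncated at segment boundaries
// and propensities recomputed there. Randomness comes from R's RNG
// (unif_rand), so trajectories are bit-reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

struct LacPars {
  double eps_sum, eps12, KA_uM, h, crp;      // regulation
  double kc, kl, ky, kz, g, gm;              // kinetics
  double vy, Kext_mM, lamKext_uM, vz, K_uM;  // transport (uM internally)
  int variant;                               // 0 = autoregulated, 1 = clamped
  double f_clamp;
};

static LacPars pars_from_list(const List& p) {
  LacPars q;
  q.eps_sum = p["eps_sum"]; q.eps12 = p["eps12"];
  q.KA_uM = p["KA_uM"]; q.h = p["h"]; q.crp = p["crp"];
  q.kc = p["kc"]; q.kl = p["kl"]; q.ky = p["ky"]; q.kz = p["kz"];
  q.g = p["g"]; q.gm = p["gm"];
  q.vy = p["vy"]; q.Kext_mM = p["Kext_mM"]; q.lamKext_uM = p["lamKext_uM"];
  q.vz = p["vz"]; q.K_uM = p["K_uM"];
  q.variant = p["variant"]; q.f_clamp = p["f_clamp"];
  return q;
}

// non-negative root of the QSS lactose balance (uM); stable quadratic
static inline double qss_lactose(double nY, double nZ, double lext,
                                 const LacPars& p) {
  if (lext <= 0.0 || nY <= 0.0) return 0.0;
  double J = p.vy * nY * lext / (p.Kext_mM + lext);
  double a = p.vy * nY + 2.0 * p.vz * nZ - J;
  double b = p.vy * nY * p.K_uM + 2.0 * p.vz * nZ * p.lamKext_uM
             - J * (p.lamKext_uM + p.K_uM);
  double c = -J * p.lamKext_uM * p.K_uM;
  double s = std::sqrt(b * b - 4.0 * a * c);
  double q = (b >= 0.0) ? -(b + s) / 2.0 : -(b - s) / 2.0;
  double r1 = q / a, r2 = c / q;
  return (r1 > r2) ? r1 : r2;
}

// fill the 8 channel propensities; returns their sum.
// order: Im+ Im- I+ I- Y+ Y- Z+ Z-
static inline double propensities(const double n[4], double lext,
                                  const LacPars& p, double a[8]) {
  double A = qss_lactose(n[2], n[3], lext, p);
  double istar = n[1] / (1.0 + std::pow(A / p.KA_uM, p.h));
  double denom = 1.0 + p.eps_sum * istar;
  double fop = p.crp / denom;
  double fi = (p.variant == 0) ? (1.0 + p.eps12 * istar) / denom : p.f_clamp;
  a[0] = p.kc * fi;
  a[1] = p.gm * n[0];
  a[2] = p.kl * n[0];
  a[3] = p.g * n[1];
  a[4] = p.ky * fop;
  a[5] = p.g * n[2];
  a[6] = p.kz * fop;
  a[7] = p.g * n[3];
  double tot = 0.0;
  for (int i = 0; i < 8; ++i) tot += a[i];
  return tot;
}

static inline void apply_event(double n[4], int ch) {
  static const int species[8] = {0, 0, 1, 1, 2, 2, 3, 3};
  static const int delta[8]   = {1, -1, 1, -1, 1, -1, 1, -1};
  n[species[ch]] += delta[ch];
}

static inline int pick_channel(const double a[8], double atot) {
  double u = unif_rand() * atot, cum = 0.0;
  for (int i = 0; i < 7; ++i) {
    cum += a[i];
    if (u < cum) return i;
  }
  return 7;
}

// segment index for time t given segment start times (sorted, first 0)
static inline int seg_index(double t, const NumericVector& starts) {
  int k = 0;
  while (k + 1 < starts.size() && t >= starts[k + 1]) ++k;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_propensities(NumericVector state, double lext, List pars) {
  LacPars p = pars_from_list(pars);
  double n[4] = {state[0], state[1], state[2], state[3]};
  double a[8];
  propensities(n, lext, p, a);
  return NumericVector(a, a + 8);
}

// Trajectory recording. sample_dt > 0: state sampled on a regular grid
// (value held since the previous event). sample_dt <= 0: every event is
// recorded (bounded by max_records).
// [[Rcpp::export]]
List cpp_ssa_trajectory(NumericVector init, NumericVector seg_start,
                        NumericVector seg_lext, double t_end, List pars,
                        double sample_dt, int max_records) {
  LacPars p = pars_from_list(pars);
  double n[4] = {init[0], init[1], init[2], init[3]};
  double a[8];
  std::vector<double> rec_t;
  std::vector<double> rec_n[4];
  bool by_grid = sample_dt > 0.0;
  double next_sample = 0.0;
  auto record = [&](double t) {
    rec_t.push_back(t);
    for (int i = 0; i < 4; ++i) rec_n[i].push_back(n[i]);
  };
  if (!by_grid) record(0.0);
  double t = 0.0;
  int k = seg_index(0.0, seg_start);
  unsigned long long n_events = 0;
  while (t < t_end) {
    double seg_end = (k + 1 < seg_start.size()) ?
      std::min((double)seg_start[k + 1], t_end) : t_end;
    double lext = seg_lext[k];
    double atot = propensities(n, lext, p, a);
    double t_next;
    int ch = -1;
    if (atot <= 0.0) {
      t_next = seg_end;
    } else {
      double dt = -std::log(unif_rand()) / atot;
      t_next = t + dt;
      if (t_next >= seg_end) {
        t_next = seg_end;
      } else {
        ch = pick_channel(a, atot);
      }
    }
    if (by_grid) {
      while (next_sample <= t_next && next_sample <= t_end) {
        record(next_sample);
        next_sample += sample_dt;
      }
    }
    t = t_next;
    if (ch >= 0) {
      apply_event(n, ch);
      ++n_events;
      if (!by_grid) {
        if ((int)rec_t.size() >= max_records)
          stop("event record limit exceeded; use a sampling interval");
        record(t);
      }
    } else if (t >= seg_end && k + 1 < seg_start.size() &&
               seg_end == (double)seg_start[k + 1]) {
      ++k;
    }
  }
  return List::create(
    _["t_min"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["n_Im"] = NumericVector(rec_n[0].begin(), rec_n[0].end()),
    _["n_I"] = NumericVector(rec_n[1].begin(), rec_n[1].end()),
    _["n_Y"] = NumericVector(rec_n[2].begin(), rec_n[2].end()),
    _["n_Z"] = NumericVector(rec_n[3].begin(), rec_n[3].end()),
    _["n_events"] = (double)n_events,
    _["final"] = NumericVector::create(n[0], n[1], n[2], n[3])
  );
}

// Time-weighted stationary statistics for n_I and n_Y over [burn_in, t_end]
// at constant external lactose, plus occupancy histograms.
// [[Rcpp::export]]
List cpp_ssa_stationary(NumericVector init, double lext, double t_end,
                        double burn_in, List pars, int hist_max) {
  LacPars p = pars_from_list(pars);
  double n[4] = {init[0], init[1], init[2], init[3]};
  double a[8];
  double sum_t = 0.0;
  double s1[4] = {0, 0, 0, 0}, s2[4] = {0, 0, 0, 0};
  double t_zero_I = 0.0, t_zero_Y = 0.0;
  NumericVector hist_I(hist_max + 1), hist_Y(hist_max + 1);
  double t = 0.0;
  unsigned long long n_events = 0;
  while (t < t_end) {
    double atot = propensities(n, lext, p, a);
    double t_next;
    int ch = -1;
    if (atot <= 0.0) {
      t_next = t_end;
    } else {
      t_next = t - std::log(unif_rand()) / atot;
      if (t_next >= t_end) t_next = t_end; else ch = pick_channel(a, atot);
    }
    // accumulate the holding interval clipped to [burn_in, t_end]
    double lo = std::max(t, burn_in), hi = std::min(t_next, t_end);
    if (hi > lo) {
      double w = hi - lo;
      sum_t += w;
      for (int i = 0; i < 4; ++i) {
        s1[i] += w * n[i];
        s2[i] += w * n[i] * n[i];
      }
      if (n[1] == 0.0) t_zero_I += w;
      if (n[2] == 0.0) t_zero_Y += w;
      int bi = (int)std::min(n[1], (double)hist_max);
      int by = (int)std::min(n[2], (double)hist_max);
      hist_I[bi] += w;
      hist_Y[by] += w;
    }
    t = t_next;
    if (ch >= 0) { apply_event(n, ch); ++n_events; }
  }
  return List::create(
    _["weight_min"] = sum_t,
    _["sum1"] = NumericVector(s1, s1 + 4),
    _["sum2"] = NumericVector(s2, s2 + 4),
    _["t_zero_I"] = t_zero_I,
    _["t_zero_Y"] = t_zero_Y,
    _["hist_I"] = hist_I,
    _["hist_Y"] = hist_Y,
    _["n_events"] = (double)n_events,
    _["final"] = NumericVector::create(n[0], n[1], n[2], n[3])
  );
}

// First-passage times of n_Y through the on/off thresholds. The on-crossing
// (n_Y >= on_thr) is armed from on_start; the off-crossing (n_Y <= off_thr)
// from off_start (pass off_start >= t_end to disable). Returned times are
// relative to the respective phase starts; NA when never crossed.
// [[Rcpp::export]]
NumericVector cpp_ssa_first_passage(NumericVector init,
                                    NumericVector seg_start,
                                    NumericVector seg_lext, double t_end,
                                    List pars, double on_start,
                                    double off_start, double on_thr,
                                    double off_thr) {
  LacPars p = pars_from_list(pars);
  double n[4] = {init[0], init[1], init[2], init[3]};
  double a[8];
  double t_on = NA_REAL, t_off = NA_REAL;
  double t = 0.0;
  int k = seg_index(0.0, seg_start);
  while (t < t_end) {
    double seg_end = (k + 1 < seg_start.size()) ?
      std::min((double)seg_start[k + 1], t_end) : t_end;
    double lext = seg_lext[k];
    double atot = propensities(n, lext, p, a);
    if (atot <= 0.0) {
      t = seg_end;
    } else {
      double dt = -std::log(unif_rand()) / atot;
      if (t + dt >= seg_end) {
        t = seg_end;
      } else {
        t += dt;
        apply_event(n, pick_channel(a, atot));
        if (ISNA(t_on) && t >= on_start && t < off_start &&
            n[2] >= on_thr) {
          t_on = t - on_start;
        }
        if (ISNA(t_off) && t >= off_start && n[2] <= off_thr) {
          t_off = t - off_start;
          break; // nothing left to observe after the off-crossing
        }
        continue;
      }
    }
    if (t >= seg_end && k + 1 < seg_start.size() &&
        seg_end == (double)seg_start[k + 1]) ++k;
  }
  return NumericVector::create(_["t_on"] = t_on, _["t_off"] = t_off);
}
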