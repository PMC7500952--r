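#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the two-species production-only model
//
//   dIRF9/dt  = I(t) * (k4 + pf * nf)
//   dUSP18/dt = I(t) * Su(t) * (k5 + pf * nf)
//
// with pf = k1*IRF9/(k2+IRF9), nf = k3/(k3+USP18), I(t) a piecewise-constant
// 0/1 input given as half-open [on, off) intervals, and Su a stepwise gate
// that opens once the continuous exposure of the current ON episode reaches
// the episode's delay.  Optional additive Gaussian noise per step turns the
// scheme into the stochastic simulator; state is clamped at zero after every
// step.  Time on step n is computed as n*dt (not accumulated) so interval
// and gate boundaries land where they should; comparisons use a 1e-9 h slack.
//
// gate_mode: 0 always_on, 1 never_on, 2 fixed_delay (tau),
//            3 cell_cycle (delay drawn per ON episode from the phase
//            phase0 + on_time modulo cycle length cyc_T, zero inside the
//            half-open window [0, cyc_w)).
// noise_em:  false -> increment sigma*dt*N(0,1) per step ("plain_euler");
//            true  -> sigma*sqrt(dt)*N(0,1) (Euler-Maruyama).

static const double TEPS = 1e-9;

// [[Rcpp::export]]
List euler_integrate_cpp(double k1, double k2, double k3, double k4, double k5,
                         NumericVector on, NumericVector off,
                         int gate_mode, double tau,
                         double cyc_T, double cyc_w, double phase0,
                         bool pf_enabled, bool nf_enabled, bool knockdown,
                         bool gated_grouping,
                         double t_end, double dt, int thin,
                         double irf9_0, double usp18_0,
                         double sigma_i, double sigma_u, bool noise_em,
                         bool with_noise,
                         IntegerVector rec_steps = IntegerVector()) {
  const int n_int = on.size();
  const int n_steps = (int) std::lround(t_end / dt);
  // either record every thin-th step, or only the requested step indices
  const bool explicit_rec = rec_steps.size() > 0;
  // thinned recording always includes the final step
  const int n_rec = explicit_rec ? (int) rec_steps.size()
                                 : (n_steps / thin + 1 +
                                    (n_steps % thin ? 1 : 0));

  NumericVector rt(n_rec), ri(n_rec), ru(n_rec);
  IntegerVector rinp(n_rec);

  // per-episode gate delays
  std::vector<double> edel(n_int, 0.0);
  for (int j = 0; j < n_int; ++j) {
    if (gate_mode == 0) {
      edel[j] = 0.0;
    } else if (gate_mode == 1) {
      edel[j] = R_PosInf;
    } else if (gate_mode == 2) {
      edel[j] = tau;
    } else {
      // phase modulo cycle length without fmod (keeps the symbol set small)
      double ph = phase0 + on[j];
      ph -= cyc_T * std::floor(ph / cyc_T);
      if (ph >= cyc_T) ph = 0.0;
      edel[j] = (ph < cyc_w) ? 0.0 : (cyc_T - ph);
    }
  }

  double irf9 = irf9_0, usp18 = knockdown ? 0.0 : usp18_0;
  const double si = noise_em ? sigma_i * std::sqrt(dt) : sigma_i * dt;
  const double su = noise_em ? sigma_u * std::sqrt(dt) : sigma_u * dt;

  int idx = 0;   // current / next input interval
  int rec = 0;
  for (int n = 0; n <= n_steps; ++n) {
    double t = n * dt;
    while (idx < n_int && t >= off[idx] - TEPS) ++idx;
    bool on_now = (idx < n_int && t >= on[idx] - TEPS && t < off[idx] - TEPS);
    int I = on_now ? 1 : 0;
    int Sgate = 0;
    if (on_now) {
      double expo = t - on[idx];
      Sgate = (expo + TEPS >= edel[idx]) ? 1 : 0;
    }

    if (explicit_rec) {
      while (rec < n_rec && rec_steps[rec] == n) {
        rt[rec] = t; ri[rec] = irf9; ru[rec] = usp18; rinp[rec] = I;
        ++rec;
      }
      if (rec == n_rec) break;
    } else if (n % thin == 0 || n == n_steps) {
      rt[rec] = t; ri[rec] = irf9; ru[rec] = usp18; rinp[rec] = I;
      ++rec;
    }
    if (n == n_steps) break;

    double pf = pf_enabled ? (k1 * irf9 / (k2 + irf9)) : k1;
    double nf = (nf_enabled && !knockdown) ? (k3 / (k3 + usp18)) : 1.0;
    double drive = pf * nf;
    double dI, dU;
    if (gated_grouping) {
      dI = I * (k4 + drive);
      dU = I * Sgate * (k5 + drive);
    } else {
      dI = I * k4 + drive;
      dU = I * Sgate * k5 + drive;
    }

    irf9 += dt * dI;
    if (!knockdown) usp18 += dt * dU;
    if (with_noise) {
      irf9 += si * norm_rand();
      if (!knockdown) usp18 += su * norm_rand();
    }
    if (irf9 < 0) irf9 = 0;
    if (usp18 < 0) usp18 = 0;
  }

  return List::create(_["time_h"] = rt, _["irf9"] = ri,
                      _["usp18"] = ru, _["input"] = rinp);
}
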