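// Frame-grid integrator for the maze-path kinematic profile.
// Mirrors the documented dynamics in generate_trajectory(): cruise-speed
// controller with AR(1) set-point wander, half-sine acceleration bumps
// armed ahead of each photodetector, exact braking into the two stop
// targets, and dwell periods at the reward well and the start area.
// Uses R's RNG so a session is reproduced exactly by its seed.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".traj_integrate")]]
List traj_integrate(int n_trials, double dt, NumericVector pd_seq,
                    NumericVector stops, double rho, double sig,
                    double cruise, double ramp, double ctrl_tau,
                    double bump_amp, double bump_dur, double bump_rise,
                    double bump_lead, int n_dwell_reward, int n_dwell_start,
                    int n_alloc) {
  NumericVector t_v(n_alloc), d_v(n_alloc), v_v(n_alloc), a_v(n_alloc);
  IntegerVector trial_v(n_alloc);
  NumericMatrix cross(n_trials, 4);
  std::fill(cross.begin(), cross.end(), NA_REAL);

  RNGScope scope;
  int k = 0;
  double t = 0.0, jit = 0.0;
  // initial rest in the start area (trial index 0 = pre-session)
  for (int i = 0; i <= n_dwell_start; ++i) {
    t_v[k] = i * dt; d_v[k] = 0.0; v_v[k] = 0.0; a_v[k] = 0.0;
    trial_v[k] = 0;
    ++k;
  }
  t = t_v[k - 1];

  for (int tr = 0; tr < n_trials; ++tr) {
    double d = 0.0, v = 0.0;
    bool pd_done[3] = {false, false, false};
    bool bump_armed[3] = {true, true, true};
    double bump_t0 = -1e300;
    int stop_idx = 0;
    while (stop_idx < 2) {
      double target = stops[stop_idx];
      jit = rho * jit + sig * R::norm_rand();
      double v_set = cruise * (1.0 + jit);
      if (v > 0) {
        for (int i = 0; i < 3; ++i) {
          if (pd_done[i] || pd_seq[i] <= d) continue;
          if (bump_armed[i] && pd_seq[i] <= target &&
              (pd_seq[i] - d) / v <= bump_lead) {
            bump_t0 = t;
            bump_armed[i] = false;
          }
          break;  // only the next un-crossed PD is considered
        }
      }
      double a;
      if (v > 0 && (target - d) <= v * v / (2.0 * ramp) + v * dt) {
        double rem = target - d;
        if (rem < 1e-6) rem = 1e-6;
        a = -v * v / (2.0 * rem);
      } else {
        a = (v_set - v) / ctrl_tau;
        if (a > ramp) a = ramp;
        if (a < -ramp) a = -ramp;
        double tau = t - bump_t0;
        if (tau >= 0 && tau < bump_dur) {
          // front-steep bump: fast quarter-sine rise, slow cosine fall
          if (tau < bump_rise)
            a += bump_amp * std::sin(M_PI_2 * tau / bump_rise);
          else
            a += bump_amp *
              std::cos(M_PI_2 * (tau - bump_rise) / (bump_dur - bump_rise));
        }
      }
      double v_new = v + a * dt;
      if (v_new < 0) v_new = 0;
      double d_new = d + v_new * dt;
      t += dt;
      for (int i = 0; i < 3; ++i) {
        if (!pd_done[i] && d < pd_seq[i] && d_new >= pd_seq[i]) {
          cross(tr, i) = t - dt + (pd_seq[i] - d) / (d_new - d) * dt;
          pd_done[i] = true;
        }
      }
      bool arrived = d_new >= target - 1e-9;
      if (arrived) {
        d_new = target;
        v_new = 0.0;
      }
      t_v[k] = t; d_v[k] = d_new; v_v[k] = v_new;
      a_v[k] = (v_new - v) / dt; trial_v[k] = tr + 1;
      ++k;
      d = d_new; v = v_new;
      if (arrived) {
        int n_fr = (stop_idx == 0) ? n_dwell_reward : n_dwell_start;
        if (stop_idx == 0) cross(tr, 3) = t;
        for (int i = 1; i <= n_fr; ++i) {
          t_v[k] = t + dt * i; d_v[k] = d; v_v[k] = 0.0; a_v[k] = 0.0;
          trial_v[k] = tr + 1;
          ++k;
        }
        if (n_fr > 0) t = t_v[k - 1];
        ++stop_idx;
      }
      if (k + n_dwell_reward + n_dwell_start + 2 >= n_alloc)
        stop("trajectory integrator: allocation exhausted");
    }
  }
  return List::create(_["t"] = t_v[Range(0, k - 1)],
                      _["d"] = d_v[Range(0, k - 1)],
                      _["v"] = v_v[Range(0, k - 1)],
                      _["a"] = a_v[Range(0, k - 1)],
                      _["trial"] = trial_v[Range(0, k - 1)],
                      _["cross"] = cross);
}
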