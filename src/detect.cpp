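#include <Rcpp.h>
using namespace Rcpp;

// Per-sample state machine over one trial window (tracked samples only).
//
// Inputs are timestamps t and elevation e = y - baseline of the tracked
// samples, ordered in time. A rise episode is defined by a Schmitt
// trigger on elevation (arm at e >= hi, release at e < lo) and must be
// initiated by a sustained vertical-velocity crossing: k consecutive
// inter-sample velocities above v_min, beginning where a velocity
// Schmitt trigger (arm above v_min, release below v_release) turns on.
// The movement onset is found by walking back from the crossing through
// the contiguous frames still above v_release (the launch of the
// movement). The reported onset is the last sample
// before the first crossing frame, i.e. the last instant the hand was
// still at rest.
//
// Returns the episode count, the first episode's onset/peak/return times
// and peak elevation, the overall peak elevation, and whether the first
// episode began before stim_onset (a premature reaction).
// [[Rcpp::export]]
List detect_episodes_cpp(NumericVector t, NumericVector e,
                         double v_min, int k, double v_release,
                         double hi, double lo, double stim_onset) {
  const int m = t.size();
  if (m < 2) {
    return List::create(
      _["valid"] = false, _["n_reactions"] = 0,
      _["onset_s"] = NA_REAL, _["peak_s"] = NA_REAL, _["return_s"] = NA_REAL,
      _["peak_elevation_m"] = NA_REAL, _["premature"] = false);
  }

  std::vector<double> v(m, 0.0);
  for (int j = 1; j < m; ++j) {
    double dt = t[j] - t[j - 1];
    v[j] = dt > 0 ? (e[j] - e[j - 1]) / dt : 0.0;
  }

  // Candidate run starts: the velocity Schmitt trigger (arm when
  // v > v_min, release when v <= v_release) turns on at j, and the run
  // is sustained for k frames above v_min. A run that dips briefly but
  // stays above v_release does not restart.
  std::vector<bool> cand(m, false);
  bool vactive = false;
  for (int j = 1; j < m; ++j) {
    if (vactive) {
      vactive = v[j] > v_release;
    } else if (v[j] > v_min) {
      vactive = true;
      if (j + k - 1 < m) {
        bool ok = true;
        for (int a = 0; a < k; ++a) {
          if (!(v[j + a] > v_min)) { ok = false; break; }
        }
        if (ok) cand[j] = true;
      }
    }
  }

  // Schmitt trigger on elevation; state 0 = low, 1 = episode active,
  // 2 = high but unqualified (no initiating velocity crossing). The
  // initiating run of an episode is the last candidate start at or
  // before the elevation crossing and after the previous episode's
  // return; elevation reaching hi without such a run (slow drift) does
  // not count as a raise.
  int state = 0;
  int n_ep = 0;
  int first_c = -1, first_ret = -1;
  int last_ep_end = -1;
  double peak_all = 0.0;

  for (int j = 0; j < m; ++j) {
    if (e[j] > peak_all) peak_all = e[j];
    if (state == 0) {
      if (e[j] >= hi) {
        int c = -1;
        for (int a = j; a > last_ep_end; --a) {
          if (a >= 1 && cand[a]) { c = a; break; }
        }
        if (c >= 1) {
          // back up through the launch: contiguous frames above v_release
          while (c - 1 >= 1 && v[c - 1] > v_release) --c;
          state = 1;
          ++n_ep;
          if (n_ep == 1) first_c = c;
        } else {
          state = 2;
        }
      }
    } else {
      if (e[j] < lo) {
        if (state == 1 && n_ep == 1 && first_ret < 0) first_ret = j;
        if (state == 1) last_ep_end = j;
        state = 0;
      }
    }
  }

  double onset_s = NA_REAL, peak_s = NA_REAL, return_s = NA_REAL;
  double peak_elev = peak_all > 0 ? peak_all : 0.0;
  bool premature = false;
  if (n_ep > 0) {
    onset_s = t[first_c - 1];
    int span_end = first_ret >= 0 ? first_ret : m - 1;
    int pk = first_c;
    for (int j = first_c; j <= span_end; ++j) {
      if (e[j] > e[pk]) pk = j;
    }
    peak_s = t[pk];
    peak_elev = e[pk] > 0 ? e[pk] : 0.0;
    if (first_ret >= 0) return_s = t[first_ret];
    premature = onset_s < stim_onset;
  }

  return List::create(
    _["valid"] = true, _["n_reactions"] = n_ep,
    _["onset_s"] = onset_s, _["peak_s"] = peak_s, _["return_s"] = return_s,
    _["peak_elevation_m"] = peak_elev, _["premature"] = premature);
}
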