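// Fast inner loop of the agent simulation. Semantics are defined by the
// R-level operations (mb_update/mb_plan, fmf_rpe/fmf_update/fmf_iti_decay,
// mf_update, integrate_values, softmax_policy, attenuate_rpe,
// elevate_temperature); a test asserts step-for-step agreement between this
// engine and the pure-R engine at fixed seeds.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Task {
  int nS, nA, init;
  std::vector<int> nxt;      // nS x nA, 0-based successor, -1 illegal
  std::vector<double> rew;   // nS x nA
  std::vector<int> feat;     // nS x nA, 0-based feature (0 = None)
  std::vector<int> evt;      // nS x nA, 0 other / 1 CS / 2 US
  std::vector<bool> legal;   // nS x nA
  std::vector<bool> terminal;
  int at(int s, int a) const { return s + nS * a; }
};

// Synchronous value iteration on the learned model; identical sweep order
// and tolerance to the R mb_plan(). `succ` lists the successors with
// nonzero learned probability per (state, action), so each backup only sums
// over observed transitions.
void plan(const Task& tk, const std::vector<double>& T,
          const std::vector<double>& R,
          const std::vector<std::vector<int> >& succ, double gamma,
          std::vector<double>& Q, std::vector<double>& A) {
  const double tol = 1e-13;
  std::vector<double> maxq(tk.nS);
  for (int it = 0; it < 500; ++it) {
    for (int s = 0; s < tk.nS; ++s) {
      maxq[s] = 0.0;
      if (tk.terminal[s]) continue;
      bool any = false; double m = 0.0;
      for (int a = 0; a < tk.nA; ++a)
        if (tk.legal[tk.at(s, a)]) {
          double q = Q[tk.at(s, a)];
          if (!any || q > m) m = q;
          any = true;
        }
      if (any) maxq[s] = m;
    }
    double delta = 0.0;
    for (int s = 0; s < tk.nS; ++s)
      for (int a = 0; a < tk.nA; ++a) {
        int i = tk.at(s, a);
        if (!tk.legal[i]) continue;
        double acc = 0.0;
        const std::vector<int>& sc = succ[i];
        for (size_t k = 0; k < sc.size(); ++k)
          acc += T[i + tk.nS * tk.nA * sc[k]] * maxq[sc[k]];
        double q = R[i] + gamma * acc;
        double d = std::fabs(q - Q[i]);
        if (d > delta) delta = d;
        Q[i] = q;
      }
    if (delta < tol) break;
    if (it == 499) stop("value iteration did not converge");
  }
  for (int s = 0; s < tk.nS; ++s) {
    bool any = false; double m = 0.0;
    for (int a = 0; a < tk.nA; ++a)
      if (tk.legal[tk.at(s, a)]) {
        double q = Q[tk.at(s, a)];
        if (!any || q > m) m = q;
        any = true;
      }
    for (int a = 0; a < tk.nA; ++a) {
      int i = tk.at(s, a);
      A[i] = tk.legal[i] ? Q[i] - m : 0.0;
    }
  }
}

inline double attenuate(double d, double eta) {
  if (eta <= 0.0 || d <= 0.0) return d;
  double r = d - eta;
  return r > 0.0 ? r : 0.0;
}

} // namespace

// [[Rcpp::export]]
List sim_agent_cpp(List tab, List cfg, int n_sessions, int trials_per_session,
                   NumericVector eta_rpe, NumericVector eta_temp,
                   bool record = true) {
  Task tk;
  tk.nS = as<int>(tab["n_states"]);
  tk.nA = as<int>(tab["n_actions"]);
  tk.init = as<int>(tab["init"]) - 1;
  IntegerMatrix nxt = tab["next_state"];
  NumericMatrix rew = tab["reward"];
  IntegerMatrix fea = tab["feature"];
  IntegerMatrix evt = tab["event"];
  LogicalMatrix leg = tab["legal"];
  LogicalVector trm = tab["terminal"];
  tk.nxt.resize(tk.nS * tk.nA); tk.rew.resize(tk.nS * tk.nA);
  tk.feat.resize(tk.nS * tk.nA); tk.evt.resize(tk.nS * tk.nA);
  tk.legal.resize(tk.nS * tk.nA); tk.terminal.resize(tk.nS);
  for (int s = 0; s < tk.nS; ++s) {
    tk.terminal[s] = trm[s];
    for (int a = 0; a < tk.nA; ++a) {
      int i = tk.at(s, a);
      tk.nxt[i] = nxt(s, a) - 1;
      tk.rew[i] = rew(s, a);
      tk.feat[i] = fea(s, a) - 1;
      tk.evt[i] = evt(s, a);
      tk.legal[i] = leg(s, a);
    }
  }

  const double omega = as<double>(cfg["omega"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double gamma = as<double>(cfg["gamma"]);
  const double beta = as<double>(cfg["beta"]);
  const double u_iti = as<double>(cfg["u"]);
  const int variant = as<int>(cfg["variant"]); // 0 model, 1..4
  NumericVector V0 = cfg["v0"];                // length 4: None,Lever,Mag,Food
  const double q0 = as<double>(cfg["q0"]);
  const double r0 = as<double>(cfg["r0"]);

  const bool use_fmf = (variant == 0 || variant == 1);
  const bool use_mb = (variant == 0 || variant == 4);
  const bool use_mf = (variant >= 1);
  // dopamine-analogue log: the feature learner's RPE when present, else MF's
  const bool log_fmf = use_fmf;

  std::vector<double> V(4);
  for (int f = 0; f < 4; ++f) V[f] = V0[f];
  std::vector<double> T(tk.nS * tk.nA * tk.nS, 0.0);
  std::vector<double> Rr(tk.nS * tk.nA, 0.0);
  std::vector<double> Qmb(tk.nS * tk.nA, 0.0), Amb(tk.nS * tk.nA, 0.0);
  std::vector<double> Qmf(tk.nS * tk.nA, 0.0);
  for (int i = 0; i < tk.nS * tk.nA; ++i)
    if (tk.legal[i]) { Rr[i] = r0; Qmf[i] = q0; }
  std::vector<std::vector<int> > succ(tk.nS * tk.nA);
  if (use_mb) plan(tk, T, Rr, succ, gamma, Qmb, Amb);

  int n_trials = n_sessions * trials_per_session;
  IntegerVector t_session(n_trials), t_trial(n_trials);
  LogicalVector t_lever(n_trials), t_mag(n_trials);
  std::vector<int> l_session, l_trial, l_step, l_state, l_action, l_next,
      l_feature, l_event;
  std::vector<double> l_delta, l_delta_used;

  int idx = 0;
  std::vector<double> P(tk.nA), probs(tk.nA);
  std::vector<int> acts(tk.nA);
  for (int ses = 0; ses < n_sessions; ++ses) {
    double eta_r = eta_rpe[ses];
    double beta_eff = beta * (1.0 + eta_temp[ses]);
    for (int tr = 0; tr < trials_per_session; ++tr, ++idx) {
      // ITI: unrewarded magazine checks depress the magazine value
      V[2] *= (1.0 - u_iti);
      bool lever_eng = false, mag_eng = false;
      int s = tk.init, step = 0;
      while (!tk.terminal[s]) {
        ++step;
        int nLegal = 0;
        for (int a = 0; a < tk.nA; ++a)
          if (tk.legal[tk.at(s, a)]) acts[nLegal++] = a;
        // integrated decision values over legal actions
        double maxqmf = 0.0;
        if (use_mf) {
          bool any = false;
          for (int k = 0; k < nLegal; ++k) {
            double q = Qmf[tk.at(s, acts[k])];
            if (!any || q > maxqmf) maxqmf = q;
            any = true;
          }
        }
        for (int k = 0; k < nLegal; ++k) {
          int i = tk.at(s, acts[k]);
          int f = tk.feat[i];
          double p = 0.0;
          switch (variant) {
          case 0: p = omega * V[f] + (1.0 - omega) * Amb[i]; break;
          case 1: p = omega * V[f] + (1.0 - omega) * (Qmf[i] - maxqmf); break;
          case 2: p = (1.0 - omega) * (Qmf[i] - maxqmf) +
                      omega * (f == 1 ? maxqmf : 0.0); break;
          case 3: p = (1.0 - omega) * (Qmf[i] - maxqmf) +
                      omega * ((f == 1 || f == 2) ? maxqmf : 0.0); break;
          case 4: p = omega * (Qmf[i] - maxqmf) + (1.0 - omega) * Amb[i]; break;
          default: stop("unknown variant");
          }
          P[k] = p;
        }
        double m = P[0];
        for (int k = 1; k < nLegal; ++k) if (P[k] > m) m = P[k];
        double tot = 0.0;
        for (int k = 0; k < nLegal; ++k) {
          probs[k] = std::exp((P[k] - m) / beta_eff);
          tot += probs[k];
        }
        double u1 = unif_rand(), cum = 0.0;
        int a = acts[nLegal - 1];
        for (int k = 0; k < nLegal; ++k) {
          cum += probs[k] / tot;
          if (u1 <= cum) { a = acts[k]; break; }
        }
        int i = tk.at(s, a);
        int s2 = tk.nxt[i], f = tk.feat[i], ev = tk.evt[i];
        double r = tk.rew[i];
        bool term2 = tk.terminal[s2];

        double d_log = 0.0, d_log_used = 0.0;
        if (use_fmf) {
          double fut = 0.0;
          if (!term2) {
            bool any = false;
            for (int a2 = 0; a2 < tk.nA; ++a2)
              if (tk.legal[tk.at(s2, a2)]) {
                double vv = V[tk.feat[tk.at(s2, a2)]];
                if (!any || vv > fut) fut = vv;
                any = true;
              }
          }
          double d = r + gamma * fut - V[f];
          double du = attenuate(d, eta_r);
          if (f != 0) V[f] += alpha * du;
          if (log_fmf) { d_log = d; d_log_used = du; }
        }
        if (use_mf) {
          double fut = 0.0;
          if (!term2) {
            bool any = false;
            for (int a2 = 0; a2 < tk.nA; ++a2)
              if (tk.legal[tk.at(s2, a2)]) {
                double q = Qmf[tk.at(s2, a2)];
                if (!any || q > fut) fut = q;
                any = true;
              }
          }
          double d = r + gamma * fut - Qmf[i];
          double du = attenuate(d, eta_r);
          Qmf[i] += alpha * du;
          if (!log_fmf) { d_log = d; d_log_used = du; }
        }
        if (use_mb) {
          for (int s3 = 0; s3 < tk.nS; ++s3) {
            double ind = (s3 == s2) ? 1.0 : 0.0;
            int j = i + tk.nS * tk.nA * s3;
            double was = T[j];
            T[j] += alpha * (ind - T[j]);
            if (was == 0.0 && T[j] != 0.0) succ[i].push_back(s3);
          }
          Rr[i] += alpha * (r - Rr[i]);
          plan(tk, T, Rr, succ, gamma, Qmb, Amb);
        }
        if (ev == 2) {
          if (f == 1) lever_eng = true;
          else if (f == 2) mag_eng = true;
        }
        if (record) {
          l_session.push_back(ses + 1); l_trial.push_back(tr + 1);
          l_step.push_back(step); l_state.push_back(s + 1);
          l_action.push_back(a + 1); l_next.push_back(s2 + 1);
          l_feature.push_back(f + 1); l_event.push_back(ev);
          l_delta.push_back(d_log); l_delta_used.push_back(d_log_used);
        }
        s = s2;
      }
      t_session[idx] = ses + 1; t_trial[idx] = tr + 1;
      t_lever[idx] = lever_eng; t_mag[idx] = mag_eng;
    }
  }

  List steps = R_NilValue;
  if (record) {
    steps = List::create(
      _["session"] = wrap(l_session), _["trial"] = wrap(l_trial),
      _["step"] = wrap(l_step), _["state"] = wrap(l_state),
      _["action"] = wrap(l_action), _["next_state"] = wrap(l_next),
      _["feature"] = wrap(l_feature), _["event"] = wrap(l_event),
      _["delta"] = wrap(l_delta), _["delta_used"] = wrap(l_delta_used));
  }
  NumericVector Tout(T.begin(), T.end());
  Tout.attr("dim") = IntegerVector::create(tk.nS, tk.nA, tk.nS);
  NumericMatrix Qmb_out(tk.nS, tk.nA), Amb_out(tk.nS, tk.nA),
      Qmf_out(tk.nS, tk.nA), R_out(tk.nS, tk.nA);
  for (int s = 0; s < tk.nS; ++s)
    for (int a = 0; a < tk.nA; ++a) {
      int i = tk.at(s, a);
      Qmb_out(s, a) = Qmb[i]; Amb_out(s, a) = Amb[i];
      Qmf_out(s, a) = Qmf[i]; R_out(s, a) = Rr[i];
    }
  return List::create(
    _["trials"] = List::create(_["session"] = t_session, _["trial"] = t_trial,
                               _["lever"] = t_lever, _["magazine"] = t_mag),
    _["steps"] = steps,
    _["V"] = NumericVector(V.begin(), V.end()),
    _["T"] = Tout, _["R"] = R_out, _["Q_mb"] = Qmb_out, _["A_mb"] = Amb_out,
    _["Q_mf"] = Qmf_out);
}
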