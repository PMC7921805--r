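#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Single-team constants in pN / um / s.
struct Team {
  double Fs, Fd, pi0, eps0, vF, vB;
};

static Team as_team(const NumericVector &v) {
  Team t;
  t.Fs = v[0];
  t.Fd = v[1];
  t.pi0 = v[2];
  t.eps0 = v[3];
  t.vF = v[4];
  t.vB = v[5];
  return t;
}

// Cargo force (magnitude) and signed velocity for occupancy (np, nm).
// Mirrors the R reference cargo_mechanics(); tests cross-check the two.
static void cargo_mech(int np, int nm, const Team &fw, const Team &bw,
                       double &Fc, double &vc) {
  const double Lp = np * fw.Fs;
  const double Lm = nm * bw.Fs;
  if (np == 0 && nm == 0) {
    Fc = 0.0;
    vc = 0.0;
  } else if (nm == 0) {
    Fc = 0.0;
    vc = fw.vF;
  } else if (np == 0) {
    Fc = 0.0;
    vc = -bw.vF;
  } else if (Lp == Lm) {
    Fc = Lp;
    vc = 0.0;
  } else if (Lp > Lm) {
    const double q = (Lp * bw.vB) / (Lm * fw.vF);
    Fc = (Lp + Lm * q) / (1.0 + q);
    vc = (Lp - Lm) / (Lp / fw.vF + Lm / bw.vB);
  } else {
    const double q = (Lp * bw.vF) / (Lm * fw.vB);
    Fc = (Lp + Lm * q) / (1.0 + q);
    vc = (Lp - Lm) / (Lp / fw.vB + Lm / bw.vF);
  }
}

// Exact SSA over the four reaction channels (bind +, bind -, unbind +,
// unbind -) with a shared free pool of n_motors, recording every event
// epoch after an optional burn-in.  Clock and position are re-zeroed at the
// end of the burn-in; the recorded trajectory always starts at (0 s, 0 um)
// and ends exactly at `duration`.  Uses R's RNG, so set.seed() on the R
// side fixes the whole run.
// [[Rcpp::export(name = ".ssa_simulate_cpp")]]
List ssa_simulate_cpp(int n_motors, NumericVector forward,
                      NumericVector backward, double duration,
                      double burn_in, double max_events) {
  const Team fw = as_team(forward);
  const Team bw = as_team(backward);

  int np = 0, nm = 0;
  double t = 0.0;   // absolute simulation clock
  double x = 0.0;   // position, re-zeroed when recording starts
  double n_ev = 0.0;
  const double total_t = burn_in + duration;

  std::vector<double> times, pos;
  std::vector<int> nps, nms;
  bool recording = (burn_in <= 0.0);
  if (recording) {
    times.push_back(0.0);
    pos.push_back(0.0);
    nps.push_back(np);
    nms.push_back(nm);
  }

  bool truncated = false;
  while (true) {
    double Fc, vc;
    cargo_mech(np, nm, fw, bw, Fc, vc);

    const int free_m = n_motors - np - nm;
    const double r_bp = free_m * fw.pi0;
    const double r_bm = free_m * bw.pi0;
    const double r_up = (np > 0) ? np * fw.eps0 * std::exp(Fc / np / fw.Fd) : 0.0;
    const double r_um = (nm > 0) ? nm * bw.eps0 * std::exp(Fc / nm / bw.Fd) : 0.0;
    const double rtot = r_bp + r_bm + r_up + r_um;
    if (rtot <= 0.0)
      stop("total event rate is zero: corrupt motor state");

    const double tau = R::exp_rand() / rtot;
    const double t_next = t + tau;

    if (t_next >= total_t) {
      // close the trajectory exactly at the requested duration
      if (!recording) {
        times.push_back(0.0);
        pos.push_back(0.0);
        nps.push_back(np);
        nms.push_back(nm);
        x = vc * (total_t - burn_in);
      } else {
        x += vc * (total_t - t);
      }
      times.push_back(duration);
      pos.push_back(x);
      nps.push_back(np);
      nms.push_back(nm);
      break;
    }

    if (!recording && t_next >= burn_in) {
      // recording origin: exact burn-in epoch, pre-event state
      recording = true;
      times.push_back(0.0);
      pos.push_back(0.0);
      nps.push_back(np);
      nms.push_back(nm);
      x = vc * (t_next - burn_in);
    } else {
      x += vc * tau;
    }
    t = t_next;

    const double u = unif_rand() * rtot;
    if (u < r_bp)
      ++np;
    else if (u < r_bp + r_bm)
      ++nm;
    else if (u < r_bp + r_bm + r_up)
      --np;
    else
      --nm;

    if (recording) {
      times.push_back(t - burn_in);
      pos.push_back(x);
      nps.push_back(np);
      nms.push_back(nm);
    }

    n_ev += 1.0;
    if (max_events > 0.0 && n_ev >= max_events) {
      truncated = true;
      break;
    }
  }

  return List::create(_["time_s"] = wrap(times), _["position_um"] = wrap(pos),
                      _["n_plus"] = wrap(nps), _["n_minus"] = wrap(nms),
                      _["n_events"] = n_ev, _["truncated"] = truncated);
}
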