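// Tick engine for the 3D CTL / infected-cell agent-based model.
//
// The R layer owns configuration, arena construction and all analysis; this
// file only advances the state tick by tick and returns the contact log,
// per-target fates and (optionally) a per-tick structural audit.  All
// randomness goes through R's RNG so set.seed() in R governs every draw.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// minimum-image displacement along a periodic axis of length L
inline double pdelta(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard against round-off at the boundary
  if (x < 0) x = 0;
  return x;
}

struct Hist {
  std::vector<double> edges;  // n+1
  std::vector<double> cum;    // n, cumulative probabilities ending at 1
  double draw() const {
    double u = unif_rand();
    size_t k = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (k >= cum.size()) k = cum.size() - 1;
    double a = edges[k], b = edges[k + 1];
    return a + unif_rand() * (b - a);
  }
};

Hist make_hist(NumericVector edges, NumericVector probs) {
  Hist h;
  h.edges.assign(edges.begin(), edges.end());
  double s = 0;
  for (R_xlen_t i = 0; i < probs.size(); ++i) {
    s += probs[i];
    h.cum.push_back(s);
  }
  // guard against round-off so the last bin is always reachable
  h.cum.back() = 1.0;
  return h;
}

struct Vec3 { double x, y, z; };

inline Vec3 rand_unit() {
  for (;;) {
    Vec3 v = { norm_rand(), norm_rand(), norm_rand() };
    double n = std::sqrt(v.x * v.x + v.y * v.y + v.z * v.z);
    if (n > 1e-12) { v.x /= n; v.y /= n; v.z /= n; return v; }
  }
}

// rotate unit vector u by angle theta about a uniformly random axis
// perpendicular to u: new = cos(theta) u + sin(theta) w, |w| = 1, w ⟂ u
inline Vec3 reorient(const Vec3& u, double theta) {
  Vec3 w;
  for (;;) {
    Vec3 v = rand_unit();
    double d = v.x * u.x + v.y * u.y + v.z * u.z;
    w = { v.x - d * u.x, v.y - d * u.y, v.z - d * u.z };
    double n = std::sqrt(w.x * w.x + w.y * w.y + w.z * w.z);
    if (n > 1e-8) { w.x /= n; w.y /= n; w.z /= n; break; }
  }
  double c = std::cos(theta), s = std::sin(theta);
  return { c * u.x + s * w.x, c * u.y + s * w.y, c * u.z + s * w.z };
}

}  // namespace

// [[Rcpp::export]]
NumericVector reorient_cpp(NumericVector direction, double angle) {
  Vec3 u = { direction[0], direction[1], direction[2] };
  Vec3 r = reorient(u, angle);
  return NumericVector::create(r.x, r.y, r.z);
}

// [[Rcpp::export]]
List run_engine_cpp(NumericMatrix ctl_pos0, NumericMatrix ctl_dir0,
                    NumericVector ctl_speed0, NumericVector pers_clock0,
                    NumericVector kill_param,
                    NumericMatrix tgt_pos0, NumericVector susceptibility,
                    NumericVector visible_from,
                    List cfg, List hyp, List motility, List durmod,
                    bool audit, double snapshot_interval) {
  const double Xdim = cfg["X_dim"], Ydim = cfg["Y_dim"], Zdim = cfg["Z_dim"];
  const double R_T = cfg["R_T"], R_I = cfg["R_I"];
  const double I_CF = cfg["I_CF"], C_CF = cfg["C_CF"];
  const double T_pers = cfg["T_pers"], dt = cfg["dt"], T_Sim = cfg["T_Sim"];

  const int variant = as<int>(hyp["variant_code"]);
  const double hp = as<double>(hyp["p"]);
  const double k_I = as<double>(hyp["k_I"]);
  const double k_T = as<double>(hyp["k_T"]);
  const bool neg_mod = as<bool>(hyp["negative_modulation"]);
  const double dmg_d = as<double>(hyp["d"]);
  const double rep_r = as<double>(hyp["r"]);
  const double T_max = as<double>(hyp["T_max"]);
  const double T_death = as<double>(hyp["T_death"]);
  const bool zombie = as<bool>(hyp["zombie_contacts"]);
  const bool probabilistic = variant >= 1 && variant <= 5;

  Hist speed_h = make_hist(motility["speed_edges"], motility["speed_probs"]);
  Hist turn_h  = make_hist(motility["turn_edges"],  motility["turn_probs"]);
  const double dur_mu = durmod["log_mean"], dur_sd = durmod["log_sd"];
  const double dur_trunc = durmod["truncation_max"];  // Inf when unset

  const int NT = ctl_pos0.nrow(), NI = tgt_pos0.nrow();
  const double Rcoll_TT = C_CF * (R_T + R_T);
  const double Rcoll_TI = C_CF * (R_T + R_I);
  const double Rint = I_CF * (R_T + R_I);
  const double Rint2 = Rint * Rint;
  const double maxRcoll = std::max(Rcoll_TT, Rcoll_TI);

  // --- mutable state ---------------------------------------------------
  std::vector<Vec3> cp(NT), cd(NT);
  std::vector<double> cspeed(NT), pclock(NT), refr(NT, 0.0);
  std::vector<int> bound(NT, -1), CT(NT, 0);
  for (int i = 0; i < NT; ++i) {
    cp[i] = { ctl_pos0(i, 0), ctl_pos0(i, 1), ctl_pos0(i, 2) };
    cd[i] = { ctl_dir0(i, 0), ctl_dir0(i, 1), ctl_dir0(i, 2) };
    cspeed[i] = ctl_speed0[i];
    pclock[i] = pers_clock0[i];
  }
  std::vector<Vec3> tp(NI);
  std::vector<int> tstate(NI, 0), CI(NI, 0);  // 0 alive, 1 dying, 2 removed
  std::vector<double> dmg(NI, 0.0), first_contact(NI, NA_REAL),
      removal(NI, NA_REAL), death_due(NI, NA_REAL);
  for (int j = 0; j < NI; ++j)
    tp[j] = { tgt_pos0(j, 0), tgt_pos0(j, 1), tgt_pos0(j, 2) };

  // contact log
  std::vector<int> ev_ctl, ev_tgt, ev_zomb, ev_reason;  // reason 1 sched, 2 removed, 3 window_end
  std::vector<double> ev_start, ev_sched, ev_end;
  std::vector<std::vector<int> > open_by_tgt(NI);

  auto draw_duration = [&]() {
    double v;
    do { v = std::exp(R::rnorm(dur_mu, dur_sd)); } while (v > dur_trunc);
    return v;
  };

  auto free_ctl = [&](int i) {
    bound[i] = -1;
    cd[i] = rand_unit();
    cspeed[i] = speed_h.draw();
    refr[i] = T_pers;
    pclock[i] = 0.0;
  };

  const int n_ticks = (int)std::lround(T_Sim / dt);
  std::vector<int> perm(NT);
  for (int i = 0; i < NT; ++i) perm[i] = i;

  // audit traces
  std::vector<double> au_minsep;
  std::vector<int> au_alive, au_dying, au_removed, au_maxopen;

  // optional arena snapshots every snapshot_interval minutes
  const int snap_every = snapshot_interval > 0
      ? std::max(1, (int)std::lround(snapshot_interval / dt)) : 0;
  std::vector<double> sn_time, sn_x, sn_y, sn_z;
  std::vector<int> sn_id, sn_type, sn_state;
  auto take_snapshot = [&](double when) {
    for (int i = 0; i < NT; ++i) {
      sn_time.push_back(when); sn_id.push_back(i + 1); sn_type.push_back(0);
      sn_x.push_back(cp[i].x); sn_y.push_back(cp[i].y);
      sn_z.push_back(cp[i].z);
      sn_state.push_back(bound[i] >= 0 ? 1 : 0);
    }
    for (int jt = 0; jt < NI; ++jt) {
      if (tstate[jt] == 2) continue;
      sn_time.push_back(when); sn_id.push_back(jt + 1);
      sn_type.push_back(1);
      sn_x.push_back(tp[jt].x); sn_y.push_back(tp[jt].y);
      sn_z.push_back(tp[jt].z);
      sn_state.push_back(tstate[jt] + 2);
    }
  };

  for (int tick = 0; tick < n_ticks; ++tick) {
    const double t = tick * dt;

    // ---- (a) move free CTLs in a fresh random permutation ------------
    for (int i = NT - 1; i > 0; --i) {
      int k = (int)std::floor(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(perm[i], perm[k]);
    }
    for (int pi = 0; pi < NT; ++pi) {
      int i = perm[pi];
      if (refr[i] > 0) { refr[i] -= dt; if (refr[i] < 0) refr[i] = 0; }
      if (bound[i] >= 0) continue;
      if (pclock[i] >= T_pers - 1e-12) {
        cspeed[i] = speed_h.draw();
        cd[i] = reorient(cd[i], turn_h.draw());
        pclock[i] = 0.0;
      }
      const double L = cspeed[i] * dt;
      double tstar = L;
      bool hit = false;
      // closed z boundaries
      if (cd[i].z > 1e-15) {
        double tz = (Zdim - cp[i].z) / cd[i].z;
        if (tz < tstar) { tstar = tz; hit = true; }
      } else if (cd[i].z < -1e-15) {
        double tz = -cp[i].z / cd[i].z;
        if (tz < tstar) { tstar = tz; hit = true; }
      }
      // nucleus hard-core repulsion: other CTLs and all present targets
      const double reach2 = (L + maxRcoll) * (L + maxRcoll);
      for (int j = 0; j < NT + NI; ++j) {
        double ox, oy, oz, Rc;
        if (j < NT) {
          if (j == i) continue;
          ox = cp[j].x; oy = cp[j].y; oz = cp[j].z; Rc = Rcoll_TT;
        } else {
          int jt = j - NT;
          if (tstate[jt] == 2) continue;
          ox = tp[jt].x; oy = tp[jt].y; oz = tp[jt].z; Rc = Rcoll_TI;
        }
        double dx = pdelta(ox - cp[i].x, Xdim);
        double dy = pdelta(oy - cp[i].y, Ydim);
        double dz = oz - cp[i].z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > reach2) continue;
        double b = dx * cd[i].x + dy * cd[i].y + dz * cd[i].z;
        if (b <= 0) continue;  // moving away
        double cc = d2 - Rc * Rc;
        if (cc <= 1e-12) { tstar = 0; hit = true; break; }
        double disc = b * b - cc;
        if (disc <= 0) continue;
        double tcol = b - std::sqrt(disc);
        if (tcol < tstar) { tstar = tcol; hit = true; }
      }
      if (tstar < 0) tstar = 0;
      cp[i].x = wrap(cp[i].x + tstar * cd[i].x, Xdim);
      cp[i].y = wrap(cp[i].y + tstar * cd[i].y, Ydim);
      cp[i].z = cp[i].z + tstar * cd[i].z;
      if (cp[i].z < 0) cp[i].z = 0;
      if (cp[i].z > Zdim) cp[i].z = Zdim;
      if (hit) {
        cd[i] = rand_unit();  // forfeit remaining displacement this tick
        pclock[i] = 0.0;
      } else {
        pclock[i] += dt;
      }
    }

    // ---- (b) initiate contacts ---------------------------------------
    for (int i = 0; i < NT; ++i) {
      if (bound[i] >= 0 || refr[i] > 1e-12) continue;
      int best = -1;
      double bestd2 = Rint2;
      for (int jt = 0; jt < NI; ++jt) {
        if (tstate[jt] == 2) continue;
        if (visible_from[jt] > t) continue;
        if (tstate[jt] == 1) {
          if (!zombie) continue;
          if (death_due[jt] <= t + 1e-9) continue;  // removed this tick
        }
        double dx = pdelta(tp[jt].x - cp[i].x, Xdim);
        double dy = pdelta(tp[jt].y - cp[i].y, Ydim);
        double dz = tp[jt].z - cp[i].z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < bestd2) { bestd2 = d2; best = jt; }  // strict <: ties keep lower id
      }
      if (best >= 0) {
        int idx = (int)ev_ctl.size();
        ev_ctl.push_back(i); ev_tgt.push_back(best);
        ev_start.push_back(t); ev_sched.push_back(draw_duration());
        ev_end.push_back(NA_REAL); ev_reason.push_back(0);
        ev_zomb.push_back(tstate[best] == 1 ? 1 : 0);
        bound[i] = idx;
        CT[i] += 1;
        CI[best] += 1;
        if (ISNA(first_contact[best])) first_contact[best] = t;
        open_by_tgt[best].push_back(idx);
      }
    }

    // ---- (c) terminate contacts whose scheduled time has elapsed ------
    std::vector<int> ending;
    for (int i = 0; i < NT; ++i) {
      int e = bound[i];
      if (e >= 0 && t - ev_start[e] >= ev_sched[e] - 1e-9) ending.push_back(e);
    }
    // random order: simultaneous endings on one target decide independently
    for (int i = (int)ending.size() - 1; i > 0; --i) {
      int k = (int)std::floor(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(ending[i], ending[k]);
    }
    for (size_t q = 0; q < ending.size(); ++q) {
      int e = ending[q];
      int i = ev_ctl[e], jt = ev_tgt[e];
      ev_end[e] = ev_start[e] + ev_sched[e];
      ev_reason[e] = 1;
      std::vector<int>& op = open_by_tgt[jt];
      op.erase(std::remove(op.begin(), op.end(), e), op.end());
      free_ctl(i);
      if (probabilistic && !ev_zomb[e] && tstate[jt] == 0) {
        double prob = 0.0;
        switch (variant) {
          case 1: prob = hp; break;
          case 2: prob = k_I * CI[jt]; break;
          case 3: prob = neg_mod ? (CT[i] > 0 ? k_T / CT[i] : 0.0)
                                 : k_T * CT[i]; break;
          case 4: prob = kill_param[i]; break;
          case 5: prob = susceptibility[jt]; break;
        }
        if (prob < 0) prob = 0;
        if (prob > 1) prob = 1;
        if (unif_rand() < prob) {
          tstate[jt] = 1;
          death_due[jt] = ev_end[e] + T_death;
        }
      }
    }

    // ---- (d) damage accumulation, death clocks, removal ---------------
    if (variant >= 6) {
      for (int jt = 0; jt < NI; ++jt) {
        if (tstate[jt] != 0) continue;
        const std::vector<int>& op = open_by_tgt[jt];
        if (op.empty() && variant != 8) continue;
        double rate = 0.0;
        switch (variant) {
          case 6: case 8:
            rate = dmg_d * (double)op.size();
            break;
          case 7: {
            int nact = 0;
            for (size_t q = 0; q < op.size(); ++q)
              if (t - ev_start[op[q]] < T_max) ++nact;
            rate = dmg_d * nact;
            break;
          }
          case 9:
            for (size_t q = 0; q < op.size(); ++q)
              rate += k_T * CT[ev_ctl[op[q]]];
            break;
        }
        double dI = rate * dt;
        if (variant == 8) dI -= rep_r * dmg[jt] * dt;
        dmg[jt] += dI;
        if (dmg[jt] < 0) dmg[jt] = 0;
        if (dmg[jt] >= 1.0 - 1e-12) {
          tstate[jt] = 1;
          death_due[jt] = t + T_death;
        }
      }
    }
    for (int jt = 0; jt < NI; ++jt) {
      if (tstate[jt] == 1 && death_due[jt] <= t + 1e-9) {
        tstate[jt] = 2;
        removal[jt] = death_due[jt];
        std::vector<int>& op = open_by_tgt[jt];
        for (size_t q = 0; q < op.size(); ++q) {
          int e = op[q];
          ev_end[e] = std::max(ev_start[e], removal[jt]);
          ev_reason[e] = 2;
          free_ctl(ev_ctl[e]);
        }
        op.clear();
      }
    }

    // ---- audit ---------------------------------------------------------
    if (audit) {
      double minsep = R_PosInf;
      for (int i = 0; i < NT; ++i) {
        for (int j = i + 1; j < NT; ++j) {
          double dx = pdelta(cp[j].x - cp[i].x, Xdim);
          double dy = pdelta(cp[j].y - cp[i].y, Ydim);
          double dz = cp[j].z - cp[i].z;
          double r = std::sqrt(dx * dx + dy * dy + dz * dz) - Rcoll_TT;
          if (r < minsep) minsep = r;
        }
        for (int jt = 0; jt < NI; ++jt) {
          if (tstate[jt] == 2) continue;
          double dx = pdelta(tp[jt].x - cp[i].x, Xdim);
          double dy = pdelta(tp[jt].y - cp[i].y, Ydim);
          double dz = tp[jt].z - cp[i].z;
          double r = std::sqrt(dx * dx + dy * dy + dz * dz) - Rcoll_TI;
          if (r < minsep) minsep = r;
        }
      }
      int na = 0, nd = 0, nr = 0;
      for (int jt = 0; jt < NI; ++jt) {
        if (tstate[jt] == 0) ++na; else if (tstate[jt] == 1) ++nd; else ++nr;
      }
      std::vector<int> per_ctl(NT, 0);
      int maxopen = 0;
      for (int jt = 0; jt < NI; ++jt)
        for (size_t q = 0; q < open_by_tgt[jt].size(); ++q) {
          int c = ++per_ctl[ev_ctl[open_by_tgt[jt][q]]];
          if (c > maxopen) maxopen = c;
        }
      au_minsep.push_back(minsep);
      au_alive.push_back(na); au_dying.push_back(nd); au_removed.push_back(nr);
      au_maxopen.push_back(maxopen);
    }
    if (snap_every > 0 && tick % snap_every == 0) take_snapshot(t);
  }

  // close contacts still open at the end of the simulated window
  for (int jt = 0; jt < NI; ++jt) {
    std::vector<int>& op = open_by_tgt[jt];
    for (size_t q = 0; q < op.size(); ++q) {
      ev_end[op[q]] = T_Sim;
      ev_reason[op[q]] = 3;
    }
    op.clear();
  }

  CharacterVector reason_lab(ev_reason.size());
  for (size_t e = 0; e < ev_reason.size(); ++e) {
    reason_lab[e] = ev_reason[e] == 1 ? "scheduled"
                  : ev_reason[e] == 2 ? "target_removed" : "window_end";
  }

  NumericMatrix cpos(NT, 3);
  for (int i = 0; i < NT; ++i) {
    cpos(i, 0) = cp[i].x; cpos(i, 1) = cp[i].y; cpos(i, 2) = cp[i].z;
  }

  List out = List::create(
      _["events"] = List::create(
          _["ctl_id"] = wrap(ev_ctl), _["target_id"] = wrap(ev_tgt),
          _["start_min"] = wrap(ev_start), _["end_min"] = wrap(ev_end),
          _["scheduled_min"] = wrap(ev_sched), _["zombie"] = wrap(ev_zomb),
          _["end_reason"] = reason_lab),
      _["targets"] = List::create(
          _["state"] = wrap(tstate), _["contacts"] = wrap(CI),
          _["damage"] = wrap(dmg), _["first_contact_min"] = wrap(first_contact),
          _["removal_min"] = wrap(removal)),
      _["ctls"] = List::create(
          _["contacts"] = wrap(CT), _["position"] = cpos));
  if (snap_every > 0) {
    out["snapshots"] = List::create(
        _["time_min"] = wrap(sn_time), _["cell_id"] = wrap(sn_id),
        _["cell_type"] = wrap(sn_type), _["x"] = wrap(sn_x),
        _["y"] = wrap(sn_y), _["z"] = wrap(sn_z),
        _["state"] = wrap(sn_state));
  }
  if (audit) {
    out["audit"] = List::create(
        _["min_separation"] = wrap(au_minsep), _["n_alive"] = wrap(au_alive),
        _["n_dying"] = wrap(au_dying), _["n_removed"] = wrap(au_removed),
        _["max_open_per_ctl"] = wrap(au_maxopen));
  }
  return out;
}
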