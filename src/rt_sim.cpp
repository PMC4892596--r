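// Agent-based run-and-tumble simulator.
//
// Motion model: straight runs at speed u with rotational diffusion of the
// direction on the unit sphere (<d(t).d(0)> = exp(-2 Drot t)), tumbles at
// rate r = clip((1 - Q)/tau_loc, 0, cap/tau_loc), persistent reorientation
// with cos(phi) drawn from a linear-tilt density on [-1, 1].
//
// Sensing: per-attractant bilobed kernel handled as an exact 3-state
// exponential filter (moments of exp(-lambda t)) updated with the local
// concentration held constant over each step:
//   S0' = c - l S0,  S1' = l S0 - l S1,  S2' = 2 l S1 - l S2
//   Q_attr = amp * l * (S1 - (1-A)/2 * S2),  amp = K0 (absolute)
//   or K0 * cref/(c + ceps) (Weber, local-background linearization).
// Steady state in uniform c gives Q = amp * A * c (the kernel integral).
//
// All randomness goes through R's RNG so set.seed() gives bit-identical
// output.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Attract {
  double base, slope;            // c(x) = max(0, base + slope * x), uM
  double K0, lam, A;
  bool weber;
  double cref, ceps;
  // precomputed per dt
  double E, ldt;
};

struct Modulation {
  int driver;                    // attractant index, or -1 for m == 1
  std::vector<double> logc, m;   // log-linear anchors, clamped outside
};

inline double conc_at(const Attract& a, double x) {
  double c = a.base + a.slope * x;
  return c > 0.0 ? c : 0.0;
}

inline double mod_eval(const Modulation& mod, const std::vector<double>& c) {
  if (mod.driver < 0) return 1.0;
  double cc = c[mod.driver];
  const std::vector<double>& lx = mod.logc;
  const std::vector<double>& my = mod.m;
  size_t n = lx.size();
  if (cc <= 0.0) return my.front();
  double l = std::log(cc);
  if (l <= lx.front()) return my.front();
  if (l >= lx.back()) return my.back();
  size_t i = 1;
  while (i < n && lx[i] < l) ++i;
  double w = (l - lx[i - 1]) / (lx[i] - lx[i - 1]);
  return my[i - 1] + w * (my[i] - my[i - 1]);
}

struct Agent {
  double x, y, z;
  double dx, dy, dz;
  int phase;                     // 0 run, 1 tumble
  double tumble_left;
  double run_elapsed;
  bool run_censored;             // run started at t=0 (tracks assay)
  std::vector<double> S;         // 3 states per attractant
};

inline void normalize3(double& x, double& y, double& z) {
  double n = std::sqrt(x * x + y * y + z * z);
  x /= n; y /= n; z /= n;
}

// cos(phi) from density (1 + b c)/2 on [-1, 1], mean b/3
inline double draw_cos_tumble(double b) {
  double u = unif_rand();
  if (std::fabs(b) < 1e-12) return 2.0 * u - 1.0;
  double disc = 0.25 - b * (0.5 - 0.25 * b - u);
  return (-0.5 + std::sqrt(disc)) / (0.5 * b);
}

// rotate d by polar angle with cosine c and uniform azimuth
inline void reorient(double& dx, double& dy, double& dz, double c) {
  double ax, ay, az;
  if (std::fabs(dz) < 0.9) { ax = 0; ay = 0; az = 1; }
  else { ax = 1; ay = 0; az = 0; }
  // e1 = normalize(d x a), e2 = d x e1
  double e1x = dy * az - dz * ay, e1y = dz * ax - dx * az, e1z = dx * ay - dy * ax;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  double e2x = dy * e1z - dz * e1y, e2y = dz * e1x - dx * e1z, e2z = dx * e1y - dy * e1x;
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double psi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(psi), sp = std::sin(psi);
  double nx = c * dx + s * (cp * e1x + sp * e2x);
  double ny = c * dy + s * (cp * e1y + sp * e2y);
  double nz = c * dz + s * (cp * e1z + sp * e2z);
  normalize3(nx, ny, nz);
  dx = nx; dy = ny; dz = nz;
}

// planar variants: direction confined to the x-y plane (near-surface
// swimming as imaged in 2-D tracking assays); angular diffusion rate set so
// the direction correlation decays at the same rate exp(-2 Drot t) as the
// 3-D walk, and the tumble angle has the same cosine law with random sign.
inline void rotate_xy(double& dx, double& dy, double ang) {
  double ca = std::cos(ang), sa = std::sin(ang);
  double nx = ca * dx - sa * dy, ny = sa * dx + ca * dy;
  double n = std::sqrt(nx * nx + ny * ny);
  dx = nx / n; dy = ny / n;
}

inline void rot_diffuse(double& dx, double& dy, double& dz, double amp) {
  double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
  double dot = gx * dx + gy * dy + gz * dz;
  dx += amp * (gx - dot * dx);
  dy += amp * (gy - dot * dy);
  dz += amp * (gz - dot * dz);
  normalize3(dx, dy, dz);
}

// exact exponential-filter recursion over one step, input c held constant
inline void filter_update(std::vector<double>& S, size_t off, const Attract& a,
                          double c) {
  double cl = c / a.lam;
  double S0 = S[off], S1 = S[off + 1], S2 = S[off + 2];
  double E = a.E, ldt = a.ldt;
  S[off]     = cl + (S0 - cl) * E;
  S[off + 1] = E * S1 + cl * (1.0 - E) + ldt * E * (S0 - cl);
  S[off + 2] = E * S2 + 2.0 * cl * (1.0 - E - ldt * E) + 2.0 * ldt * E * S1 +
               ldt * ldt * E * (S0 - cl);
}

// Q: filter output; Qss: its steady value at the local concentration
// (the kernel-integral component, K0_eff * A * c). When dc_comp is on the
// local baseline run time is rescaled by (1 - Qss) so that the realized
// steady-state run time in a uniform medium is exactly tau_r * m(c): the
// modulation anchors are measurements of the *total* steady state and must
// not be counted twice.
inline void q_and_qss(const std::vector<double>& S,
                      const std::vector<Attract>& attr,
                      const std::vector<double>& c,
                      double& Q, double& Qss) {
  Q = 0.0; Qss = 0.0;
  for (size_t a = 0; a < attr.size(); ++a) {
    double amp = attr[a].K0;
    if (attr[a].weber) amp *= attr[a].cref / (c[a] + attr[a].ceps);
    Q += amp * attr[a].lam *
         (S[3 * a + 1] - 0.5 * (1.0 - attr[a].A) * S[3 * a + 2]);
    Qss += amp * attr[a].A * c[a];
  }
}

std::vector<Attract> unpack_attr(const NumericMatrix& am, double dt) {
  std::vector<Attract> attr(am.nrow());
  for (int i = 0; i < am.nrow(); ++i) {
    Attract& a = attr[i];
    a.base = am(i, 0); a.slope = am(i, 1);
    a.K0 = am(i, 2); a.lam = am(i, 3); a.A = am(i, 4);
    a.weber = am(i, 5) != 0.0;
    a.cref = am(i, 6); a.ceps = am(i, 7);
    a.E = std::exp(-a.lam * dt);
    a.ldt = a.lam * dt;
  }
  return attr;
}

Modulation unpack_mod(const List& ml) {
  Modulation m;
  m.driver = as<int>(ml["driver"]);
  NumericVector lc = ml["logc"], mm = ml["m"];
  m.logc.assign(lc.begin(), lc.end());
  m.m.assign(mm.begin(), mm.end());
  return m;
}

inline void init_filter_steady(std::vector<double>& S,
                               const std::vector<Attract>& attr,
                               const std::vector<double>& c) {
  for (size_t a = 0; a < attr.size(); ++a) {
    double cl = c[a] / attr[a].lam;
    S[3 * a] = cl; S[3 * a + 1] = cl; S[3 * a + 2] = 2.0 * cl;
  }
}

} // namespace

// [[Rcpp::export(name = ".rt_tracks_cpp")]]
List rt_tracks_cpp(int n_agents, double T, double dt, int frame_stride,
                   double u, double u_sd, double tau_r, double D_rot,
                   double cos_tilt, double tumble_duration, double rate_cap,
                   NumericMatrix attr_mat, List mod_list,
                   bool dc_comp, bool planar, bool record_runs) {
  std::vector<Attract> attr = unpack_attr(attr_mat, dt);
  Modulation mod = unpack_mod(mod_list);
  size_t na = attr.size();
  int n_steps = (int)std::lround(T / dt);
  int n_frames = n_steps / frame_stride + 1;
  double rot_amp = std::sqrt(2.0 * D_rot * dt);
  double rot_amp_xy = std::sqrt(2.0 * (2.0 * D_rot) * dt);

  NumericVector out_id(n_agents * n_frames), out_t(n_agents * n_frames),
      out_x(n_agents * n_frames), out_y(n_agents * n_frames),
      out_z(n_agents * n_frames);
  std::vector<double> run_durations, tumble_cos;
  std::vector<int> run_agent;
  NumericVector agent_u(n_agents);

  RNGScope scope;
  std::vector<double> c(na);
  long idx = 0;
  for (int ag = 0; ag < n_agents; ++ag) {
    // per-bacterium running speed (population heterogeneity)
    double ua = u;
    if (u_sd > 0) {
      do { ua = u + u_sd * norm_rand(); } while (ua < 2.0);
    }
    agent_u[ag] = ua;
    Agent A;
    A.x = 0; A.y = 0; A.z = 0;
    // isotropic initial direction (in the plane when planar)
    double zz = planar ? 0.0 : 2.0 * unif_rand() - 1.0;
    double ph = 2.0 * M_PI * unif_rand();
    double sz = std::sqrt(std::max(0.0, 1.0 - zz * zz));
    A.dx = sz * std::cos(ph); A.dy = sz * std::sin(ph); A.dz = zz;
    A.phase = 0; A.tumble_left = 0; A.run_elapsed = 0; A.run_censored = true;
    A.S.assign(3 * na, 0.0);
    for (size_t a = 0; a < na; ++a) c[a] = conc_at(attr[a], A.x);
    init_filter_steady(A.S, attr, c);

    out_id[idx] = ag + 1; out_t[idx] = 0;
    out_x[idx] = A.x; out_y[idx] = A.y; out_z[idx] = A.z; ++idx;

    for (int st = 1; st <= n_steps; ++st) {
      for (size_t a = 0; a < na; ++a) {
        c[a] = conc_at(attr[a], A.x);
        filter_update(A.S, 3 * a, attr[a], c[a]);
      }
      if (A.phase == 0) {
        double Q, Qss;
        q_and_qss(A.S, attr, c, Q, Qss);
        double tau_loc = tau_r * mod_eval(mod, c);
        if (dc_comp) tau_loc *= std::max(1.0 - Qss, 0.05);
        double rate = (1.0 - Q) / tau_loc;
        if (rate < 0.0) rate = 0.0;
        if (rate > rate_cap / tau_loc) rate = rate_cap / tau_loc;
        A.x += ua * dt * A.dx; A.y += ua * dt * A.dy; A.z += ua * dt * A.dz;
        if (D_rot > 0) {
          if (planar) rotate_xy(A.dx, A.dy, rot_amp_xy * norm_rand());
          else rot_diffuse(A.dx, A.dy, A.dz, rot_amp);
        }
        A.run_elapsed += dt;
        if (unif_rand() < rate * dt) {
          if (record_runs && !A.run_censored) {
            run_durations.push_back(A.run_elapsed);
            run_agent.push_back(ag + 1);
          }
          A.run_elapsed = 0; A.run_censored = false;
          if (tumble_duration > 0) {
            A.phase = 1; A.tumble_left = tumble_duration;
          } else {
            double cc = draw_cos_tumble(cos_tilt);
            if (record_runs) tumble_cos.push_back(cc);
            if (planar)
              rotate_xy(A.dx, A.dy,
                        (unif_rand() < 0.5 ? 1.0 : -1.0) * std::acos(cc));
            else reorient(A.dx, A.dy, A.dz, cc);
          }
        }
      } else {
        A.tumble_left -= dt;
        if (A.tumble_left <= 0) {
          double cc = draw_cos_tumble(cos_tilt);
          if (record_runs) tumble_cos.push_back(cc);
          if (planar)
            rotate_xy(A.dx, A.dy,
                      (unif_rand() < 0.5 ? 1.0 : -1.0) * std::acos(cc));
          else reorient(A.dx, A.dy, A.dz, cc);
          A.phase = 0;
        }
      }
      if (st % frame_stride == 0) {
        out_id[idx] = ag + 1; out_t[idx] = st * dt;
        out_x[idx] = A.x; out_y[idx] = A.y; out_z[idx] = A.z; ++idx;
      }
    }
  }
  List res = List::create(
      _["track_id"] = out_id, _["t"] = out_t,
      _["x"] = out_x, _["y"] = out_y, _["z"] = out_z,
      _["agent_u"] = agent_u);
  if (record_runs) {
    res["run_agent"] = wrap(run_agent);
    res["run_durations"] = wrap(run_durations);
    res["tumble_cos"] = wrap(tumble_cos);
  }
  return res;
}

// [[Rcpp::export(name = ".rt_race_cpp")]]
List rt_race_cpp(double T, double dt, int snap_stride,
                 double L, double W, double Hh, double inject_rate,
                 double u, double tau_r, double D_rot, double cos_tilt,
                 double tumble_duration, double rate_cap,
                 NumericMatrix attr_mat, List mod_list, bool dc_comp) {
  std::vector<Attract> attr = unpack_attr(attr_mat, dt);
  Modulation mod = unpack_mod(mod_list);
  size_t na = attr.size();
  int n_steps = (int)std::lround(T / dt);
  double rot_amp = std::sqrt(2.0 * D_rot * dt);

  std::vector<Agent> agents;
  std::vector<double> snap_t, snap_x, snap_y;
  long injected = 0, absorbed = 0, returned = 0;

  RNGScope scope;
  std::vector<double> c(na), c_entry(na);
  for (size_t a = 0; a < na; ++a) c_entry[a] = conc_at(attr[a], 0.0);

  // snapshot at t = 0 (empty channel): nothing to record
  for (int st = 1; st <= n_steps; ++st) {
    // Poisson injection at the entry face, flux-weighted inward direction
    int k = (int)R::rpois(inject_rate * dt);
    for (int j = 0; j < k; ++j) {
      Agent A;
      A.x = 1e-6; A.y = W * unif_rand(); A.z = Hh * unif_rand();
      double mu = std::sqrt(unif_rand());            // cosine-law entry flux
      double ps = 2.0 * M_PI * unif_rand();
      double sm = std::sqrt(std::max(0.0, 1.0 - mu * mu));
      A.dx = mu; A.dy = sm * std::cos(ps); A.dz = sm * std::sin(ps);
      A.phase = 0; A.tumble_left = 0; A.run_elapsed = 0; A.run_censored = true;
      A.S.assign(3 * na, 0.0);
      init_filter_steady(A.S, attr, c_entry);       // adapted to entry conc
      agents.push_back(A);
      ++injected;
    }
    for (size_t i = 0; i < agents.size();) {
      Agent& A = agents[i];
      for (size_t a = 0; a < na; ++a) {
        c[a] = conc_at(attr[a], A.x);
        filter_update(A.S, 3 * a, attr[a], c[a]);
      }
      if (A.phase == 0) {
        double Q, Qss;
        q_and_qss(A.S, attr, c, Q, Qss);
        double tau_loc = tau_r * mod_eval(mod, c);
        if (dc_comp) tau_loc *= std::max(1.0 - Qss, 0.05);
        double rate = (1.0 - Q) / tau_loc;
        if (rate < 0.0) rate = 0.0;
        if (rate > rate_cap / tau_loc) rate = rate_cap / tau_loc;
        A.x += u * dt * A.dx; A.y += u * dt * A.dy; A.z += u * dt * A.dz;
        if (D_rot > 0) rot_diffuse(A.dx, A.dy, A.dz, rot_amp);
        if (unif_rand() < rate * dt) {
          if (tumble_duration > 0) { A.phase = 1; A.tumble_left = tumble_duration; }
          else reorient(A.dx, A.dy, A.dz, draw_cos_tumble(cos_tilt));
        }
      } else {
        A.tumble_left -= dt;
        if (A.tumble_left <= 0) {
          reorient(A.dx, A.dy, A.dz, draw_cos_tumble(cos_tilt));
          A.phase = 0;
        }
      }
      // reflecting side walls
      if (A.y < 0)  { A.y = -A.y; A.dy = -A.dy; }
      if (A.y > W)  { A.y = 2 * W - A.y; A.dy = -A.dy; }
      if (A.z < 0)  { A.z = -A.z; A.dz = -A.dz; }
      if (A.z > Hh) { A.z = 2 * Hh - A.z; A.dz = -A.dz; }
      // absorbing ends: reservoir (x = L) and back into the injection channel
      if (A.x >= L) {
        ++absorbed;
        agents[i] = agents.back(); agents.pop_back();
      } else if (A.x < 0) {
        ++returned;
        agents[i] = agents.back(); agents.pop_back();
      } else {
        ++i;
      }
    }
    if (st % snap_stride == 0) {
      double tnow = st * dt;
      for (size_t i = 0; i < agents.size(); ++i) {
        snap_t.push_back(tnow);
        snap_x.push_back(agents[i].x);
        snap_y.push_back(agents[i].y);
      }
    }
  }
  return List::create(
      _["t"] = wrap(snap_t), _["x"] = wrap(snap_x), _["y"] = wrap(snap_y),
      _["injected"] = (double)injected, _["absorbed"] = (double)absorbed,
      _["returned"] = (double)returned, _["remaining"] = (double)agents.size());
}

// Exact exponential-filter response to a piecewise-constant concentration
// series (exposed for cross-checking against quadrature convolution).
// [[Rcpp::export(name = ".rt_filter_cpp")]]
NumericVector rt_filter_cpp(NumericVector conc, double dt,
                            double K0, double lam, double A) {
  Attract at; at.K0 = K0; at.lam = lam; at.A = A; at.weber = false;
  at.cref = 0; at.ceps = 0; at.E = std::exp(-lam * dt); at.ldt = lam * dt;
  std::vector<double> S(3, 0.0);
  int n = conc.size();
  NumericVector Q(n);
  for (int i = 0; i < n; ++i) {
    filter_update(S, 0, at, conc[i]);
    Q[i] = K0 * lam * (S[1] - 0.5 * (1.0 - A) * S[2]);
  }
  return Q;
}
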