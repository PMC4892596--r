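// Crank-Nicolson finite-volume stepper for the 1-D drift-diffusion equation
//   dt rho = dx(D dx rho) - dx(v rho)
// on a uniform grid with Dirichlet boundaries rho(0) = rho0 (maintained
// source density) and rho(L) = 0 (absorbing reservoir). Fluxes are evaluated
// at cell faces with central averaging, so the interior update telescopes and
// discrete mass balance d/dt(sum rho dx) = J_in - J_out holds to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".pde_cn_cpp")]]
List pde_cn_cpp(NumericVector Df, NumericVector vf, double dx, double dt,
                int n_steps, int record_stride, double rho0,
                NumericVector rho_init) {
  int N = rho_init.size() - 1;      // nodes 0..N, faces 0..N-1
  int ni = N - 1;                   // interior unknowns 1..N-1
  std::vector<double> rho(rho_init.begin(), rho_init.end());
  rho[0] = rho0; rho[N] = 0.0;

  // M rho coefficients at interior node i: A_i rho_{i-1} + B_i rho_i + C_i rho_{i+1}
  std::vector<double> Ai(ni), Bi(ni), Ci(ni);
  for (int i = 1; i <= ni; ++i) {
    double vl = vf[i - 1], vr = vf[i], Dl = Df[i - 1], Dr = Df[i];
    Ai[i - 1] = vl / (2 * dx) + Dl / (dx * dx);
    Bi[i - 1] = (vl - vr) / (2 * dx) - (Dl + Dr) / (dx * dx);
    Ci[i - 1] = -vr / (2 * dx) + Dr / (dx * dx);
  }
  // Crank-Nicolson tridiagonal (I - dt/2 M); constant in time
  std::vector<double> la(ni), di(ni), ua(ni);
  for (int i = 0; i < ni; ++i) {
    la[i] = -0.5 * dt * Ai[i];
    di[i] = 1.0 - 0.5 * dt * Bi[i];
    ua[i] = -0.5 * dt * Ci[i];
  }

  int n_rec = n_steps / record_stride + 1;
  NumericMatrix rho_out(n_rec, N + 1);
  NumericVector t_out(n_rec), Jin(n_rec), Jout(n_rec), mass(n_rec);

  auto face_flux = [&](const std::vector<double>& r, int f) {
    return vf[f] * 0.5 * (r[f] + r[f + 1]) - Df[f] * (r[f + 1] - r[f]) / dx;
  };
  auto total_mass = [&](const std::vector<double>& r) {
    double m = 0.5 * (r[0] + r[N]);
    for (int i = 1; i < N; ++i) m += r[i];
    return m * dx;
  };

  int rec = 0;
  for (int j = 0; j <= N; ++j) rho_out(rec, j) = rho[j];
  t_out[rec] = 0.0; mass[rec] = total_mass(rho);
  Jin[rec] = face_flux(rho, 0); Jout[rec] = face_flux(rho, N - 1);
  ++rec;

  std::vector<double> rhs(ni), cp(ni), dp(ni), rnew(rho);
  for (int st = 1; st <= n_steps; ++st) {
    // rhs = rho + dt/2 M rho (+ Dirichlet contributions, constant in time,
    // already inside M via rho[0], rho[N])
    for (int i = 1; i <= ni; ++i)
      rhs[i - 1] = rho[i] + 0.5 * dt *
        (Ai[i - 1] * rho[i - 1] + Bi[i - 1] * rho[i] + Ci[i - 1] * rho[i + 1]);
    // move known boundary terms of the implicit side to the rhs
    rhs[0]      -= la[0] * rho0;
    rhs[ni - 1] -= ua[ni - 1] * 0.0;
    // Thomas solve
    cp[0] = ua[0] / di[0];
    dp[0] = rhs[0] / di[0];
    for (int i = 1; i < ni; ++i) {
      double m = di[i] - la[i] * cp[i - 1];
      cp[i] = ua[i] / m;
      dp[i] = (rhs[i] - la[i] * dp[i - 1]) / m;
    }
    rnew[ni] = dp[ni - 1];
    for (int i = ni - 2; i >= 0; --i) rnew[i + 1] = dp[i] - cp[i] * rnew[i + 2];
    rnew[0] = rho0; rnew[N] = 0.0;

    if (st % record_stride == 0) {
      for (int j = 0; j <= N; ++j) rho_out(rec, j) = rnew[j];
      t_out[rec] = st * dt;
      mass[rec] = total_mass(rnew);
      // CN-consistent face fluxes (average of old and new states)
      Jin[rec]  = 0.5 * (face_flux(rho, 0) + face_flux(rnew, 0));
      Jout[rec] = 0.5 * (face_flux(rho, N - 1) + face_flux(rnew, N - 1));
      ++rec;
    }
    rho = rnew;
  }
  return List::create(_["t"] = t_out, _["rho"] = rho_out, _["J_in"] = Jin,
                      _["J_out"] = Jout, _["mass"] = mass);
}
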