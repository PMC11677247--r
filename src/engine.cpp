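// Explicit-dynamics core: bonded FCC pair lattice with a many-body pair
// closure, radial-return plasticity for metals, and explicit Biot
// pore-pressure coupling with Darcy exchange.
//
// The many-body part of the pair response is driven by the local strain
// tensor of each element, least-squares fitted from its pair normal strains
// through a precomputed 6x6 pseudo-inverse of the bond-direction moment
// matrix. The fit is exact for affine deformation at any coordination
// number (free surfaces included), which makes the closure reproduce
// isotropic linear (poro)elasticity in the uniform limit without any
// fixed-point iteration.
//
// Conventions: tension-positive stress, compression-positive pore pressure,
// SI units. Pair normal n points from element i to element j.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// bc bitmask
static const int BC_VX = 1;     // x velocity prescribed (v_bc[,0] * scale(t))
static const int BC_VY = 2;
static const int BC_VZ = 4;
static const int BC_WAVE = 8;   // applicator: vx = waveform(t), vy = vz = 0
static const int BC_RAMP = 16;  // ramp set: vz = ramp(t), vx = vy = 0

// forward stroke: half-sine rise, hold, mirrored fall; then an optional
// slower recovery half-sine (amplitude V_rec < 0) that returns the head to
// its start position so the pulse train carries no net displacement
static inline double wave_v(double t, double V, double t_rise, double t_hold,
                            double t_rec, double V_rec,
                            double period, int n_pulses) {
  if (t < 0.0 || t >= n_pulses * period) return 0.0;
  double tp = t - period * std::floor(t / period);
  if (tp < t_rise) return V * std::sin(M_PI * tp / (2.0 * t_rise));
  if (tp < t_rise + t_hold) return V;
  if (tp < 2.0 * t_rise + t_hold)
    return V * std::sin(M_PI * (2.0 * t_rise + t_hold - tp) / (2.0 * t_rise));
  double t_on = 2.0 * t_rise + t_hold;
  if (V_rec != 0.0 && tp < t_on + t_rec)
    return -V_rec * std::sin(M_PI * (tp - t_on) / t_rec);
  return 0.0;
}

// exact displacement integral of the waveform (so the prescribed plate
// position stays accurate even when t_rise is below the timestep)
static inline double wave_u(double t, double V, double t_rise, double t_hold,
                            double t_rec, double V_rec,
                            double period, int n_pulses) {
  if (t < 0.0) return 0.0;
  double ramp = V * 2.0 * t_rise / M_PI;             // one half-sine ramp
  double D = 2.0 * ramp + V * t_hold;                // forward-stroke disp
  double R = V_rec * 2.0 * t_rec / M_PI;             // recovery disp
  int completed = std::min((int)std::floor(t / period), n_pulses);
  double u = completed * (D - R);
  if (completed >= n_pulses) return u;
  double tp = t - completed * period;
  if (tp < t_rise)
    return u + ramp * (1.0 - std::cos(M_PI * tp / (2.0 * t_rise)));
  if (tp < t_rise + t_hold)
    return u + ramp + V * (tp - t_rise);
  double t_on = 2.0 * t_rise + t_hold;
  if (tp < t_on)
    return u + ramp + V * t_hold +
      ramp * std::cos(M_PI * (t_on - tp) / (2.0 * t_rise));
  if (V_rec != 0.0 && tp < t_on + t_rec)
    return u + D - V_rec * (t_rec / M_PI) *
      (1.0 - std::cos(M_PI * (tp - t_on) / t_rec));
  return u + D - R;
}

static inline double ramp_v(double t, double v, double t_start) {
  if (t < 0.0) return 0.0;
  if (t_start > 0.0 && t < t_start) return v * std::sin(M_PI * t / (2.0 * t_start));
  return v;
}

static inline void dir6(double nx, double ny, double nz, double* m) {
  m[0] = nx * nx; m[1] = ny * ny; m[2] = nz * nz;
  m[3] = 2.0 * nx * ny; m[4] = 2.0 * nx * nz; m[5] = 2.0 * ny * nz;
}

// symmetric 6x6 eigendecomposition (cyclic Jacobi); A destroyed, V gets
// eigenvectors in columns, w the eigenvalues
static void eig6(double A[36], double V[36], double w[6]) {
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) V[6 * r + c] = (r == c) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 6; ++p)
      for (int q = p + 1; q < 6; ++q) off += A[6 * p + q] * A[6 * p + q];
    if (off < 1e-30) break;
    for (int p = 0; p < 6; ++p)
      for (int q = p + 1; q < 6; ++q) {
        double apq = A[6 * p + q];
        if (std::fabs(apq) < 1e-300) continue;
        double theta = (A[6 * q + q] - A[6 * p + p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 6; ++k) {
          double akp = A[6 * k + p], akq = A[6 * k + q];
          A[6 * k + p] = c * akp - s * akq;
          A[6 * k + q] = s * akp + c * akq;
        }
        for (int k = 0; k < 6; ++k) {
          double apk = A[6 * p + k], aqk = A[6 * q + k];
          A[6 * p + k] = c * apk - s * aqk;
          A[6 * q + k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 6; ++k) {
          double vkp = V[6 * k + p], vkq = V[6 * k + q];
          V[6 * k + p] = c * vkp - s * vkq;
          V[6 * k + q] = s * vkp + c * vkq;
        }
      }
  }
  for (int k = 0; k < 6; ++k) w[k] = A[6 * k + k];
}

// truncated pseudo-inverse of a symmetric PSD 6x6 bond-moment matrix:
// eigenmodes below rel_tol * max eigenvalue are dropped (rank-deficient
// edge/corner elements), so the strain fit is minimum-norm and never
// amplifies unresolved modes
static void pinv6(const double A[36], double Ainv[36],
                  double rel_tol = 1e-2) {
  double B[36], V[36], w[6];
  std::copy(A, A + 36, B);
  eig6(B, V, w);
  double wmax = 0.0;
  for (int k = 0; k < 6; ++k) wmax = std::max(wmax, w[k]);
  double winv[6];
  for (int k = 0; k < 6; ++k)
    winv[k] = (w[k] > rel_tol * wmax && wmax > 0.0) ? 1.0 / w[k] : 0.0;
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) {
      double s = 0.0;
      for (int k = 0; k < 6; ++k) s += V[6 * r + k] * winv[k] * V[6 * c + k];
      Ainv[6 * r + c] = s;
    }
}

// Per-element strain-fit operators from reference pair geometry.
static void build_strain_fit(const IntegerMatrix& pairs,
                             const NumericMatrix& pos, int n,
                             std::vector<double>& Q /* 36*n */) {
  const int m = pairs.nrow();
  std::vector<double> M6(36 * (size_t)n, 0.0);
  for (int k = 0; k < m; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double rx = pos(j, 0) - pos(i, 0);
    double ry = pos(j, 1) - pos(i, 1);
    double rz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(rx * rx + ry * ry + rz * rz);
    double mm[6];
    dir6(rx / r, ry / r, rz / r, mm);
    for (int e : {i, j}) {
      double* Me = &M6[36 * (size_t)e];
      for (int a = 0; a < 6; ++a)
        for (int b = 0; b < 6; ++b) Me[6 * a + b] += mm[a] * mm[b];
    }
  }
  Q.assign(36 * (size_t)n, 0.0);
  for (int e = 0; e < n; ++e)
    pinv6(&M6[36 * (size_t)e], &Q[36 * (size_t)e]);
}

// trace rows of the fit operators: eps_v_e = qvec_e . s6_e, so the fit
// weight of bond k in element e's volumetric strain is qvec_e . m_k
static void fit_trace_rows(const std::vector<double>& Q, int n,
                           std::vector<double>& qv) {
  qv.assign(6 * (size_t)n, 0.0);
  for (int e = 0; e < n; ++e)
    for (int b = 0; b < 6; ++b)
      qv[6 * (size_t)e + b] = Q[36 * (size_t)e + b] +
        Q[36 * (size_t)e + 6 + b] + Q[36 * (size_t)e + 12 + b];
}

// [[Rcpp::export]]
List cpp_neighbor_pairs(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], pos(i, a));
      hi[a] = std::max(hi[a], pos(i, a));
    }
  const double cell = cutoff * 1.0000001;
  int nc[3];
  for (int a = 0; a < 3; ++a)
    nc[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cell) + 1);
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  auto bin_of = [&](int i) {
    int c[3];
    for (int a = 0; a < 3; ++a) {
      c[a] = (int)std::floor((pos(i, a) - lo[a]) / cell);
      if (c[a] < 0) c[a] = 0;
      if (c[a] >= nc[a]) c[a] = nc[a] - 1;
    }
    return (size_t)(c[0] + nc[0] * (c[1] + nc[1] * c[2]));
  };
  for (int i = 0; i < n; ++i) bins[bin_of(i)].push_back(i);
  std::vector<int> pi, pj;
  std::vector<double> pr;
  const double c2 = cutoff * cutoff;
  for (int cx = 0; cx < nc[0]; ++cx)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cz = 0; cz < nc[2]; ++cz) {
        const std::vector<int>& b0 =
          bins[(size_t)(cx + nc[0] * (cy + nc[1] * cz))];
        if (b0.empty()) continue;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              int ex = cx + dx, ey = cy + dy, ez = cz + dz;
              if (ex < 0 || ey < 0 || ez < 0 ||
                  ex >= nc[0] || ey >= nc[1] || ez >= nc[2]) continue;
              const std::vector<int>& b1 =
                bins[(size_t)(ex + nc[0] * (ey + nc[1] * ez))];
              for (int i : b0)
                for (int j : b1) {
                  if (j <= i) continue;
                  double ddx = pos(j, 0) - pos(i, 0);
                  double ddy = pos(j, 1) - pos(i, 1);
                  double ddz = pos(j, 2) - pos(i, 2);
                  double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                  if (d2 <= c2) {
                    pi.push_back(i + 1);
                    pj.push_back(j + 1);
                    pr.push_back(std::sqrt(d2));
                  }
                }
            }
      }
  IntegerMatrix pairs((int)pi.size(), 2);
  NumericVector r0((int)pi.size());
  for (int k = 0; k < (int)pi.size(); ++k) {
    pairs(k, 0) = pi[k];
    pairs(k, 1) = pj[k];
    r0[k] = pr[k];
  }
  return List::create(_["pairs"] = pairs, _["r0"] = r0);
}

// One kinematics evaluation: pair normal strains, normals, and the shear
// strain increment implied by the given velocities/spins over dt.
// [[Rcpp::export]]
List cpp_kinematics_step(NumericMatrix pos, IntegerMatrix pairs,
                         NumericVector r0, NumericMatrix gamma,
                         NumericMatrix vel, NumericMatrix omega, double dt) {
  const int m = pairs.nrow();
  NumericVector eps_n(m), r_now(m);
  NumericMatrix nrm(m, 3), gamma_new(m, 3);
  for (int k = 0; k < m; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double rx = pos(j, 0) - pos(i, 0);
    double ry = pos(j, 1) - pos(i, 1);
    double rz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (r <= 0.0) stop("coincident elements in pair %d", k + 1);
    double nx = rx / r, ny = ry / r, nz = rz / r;
    r_now[k] = r;
    eps_n[k] = (r - r0[k]) / r0[k];
    nrm(k, 0) = nx; nrm(k, 1) = ny; nrm(k, 2) = nz;
    // relative slip velocity at the contact point, rigid-rotation free:
    // dv = (v_j - v_i) - 0.5 (w_i + w_j) x (r n)
    double wx = 0.5 * (omega(i, 0) + omega(j, 0));
    double wy = 0.5 * (omega(i, 1) + omega(j, 1));
    double wz = 0.5 * (omega(i, 2) + omega(j, 2));
    double dvx = vel(j, 0) - vel(i, 0) - (wy * rz - wz * ry);
    double dvy = vel(j, 1) - vel(i, 1) - (wz * rx - wx * rz);
    double dvz = vel(j, 2) - vel(i, 2) - (wx * ry - wy * rx);
    double dvn = dvx * nx + dvy * ny + dvz * nz;
    double gx = gamma(k, 0) + (dvx - dvn * nx) * dt / r0[k];
    double gy = gamma(k, 1) + (dvy - dvn * ny) * dt / r0[k];
    double gz = gamma(k, 2) + (dvz - dvn * nz) * dt / r0[k];
    double gn = gx * nx + gy * ny + gz * nz;  // keep gamma tangential
    gamma_new(k, 0) = gx - gn * nx;
    gamma_new(k, 1) = gy - gn * ny;
    gamma_new(k, 2) = gz - gn * nz;
  }
  return List::create(_["eps_n"] = eps_n, _["r"] = r_now, _["normal"] = nrm,
                      _["gamma"] = gamma_new);
}

// Pair closure + element stress from a given strain state (single pass:
// the many-body term comes from the fitted local strain tensor).
// [[Rcpp::export]]
List cpp_closure_stress(IntegerMatrix pairs, NumericVector r_now,
                        NumericMatrix nrm, NumericVector eps_n,
                        NumericMatrix gamma, NumericVector G, NumericVector K,
                        NumericVector alpha, NumericVector P,
                        NumericVector sigma_y, NumericVector A_pairs,
                        NumericVector fb_scale, double V_elem, int n_elem) {
  const int m = pairs.nrow();
  // strain fit from the supplied pair state
  std::vector<double> Q;
  {
    std::vector<double> M6(36 * (size_t)n_elem, 0.0);
    for (int k = 0; k < m; ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      double mm[6];
      dir6(nrm(k, 0), nrm(k, 1), nrm(k, 2), mm);
      for (int e : {i, j}) {
        double* Me = &M6[36 * (size_t)e];
        for (int a = 0; a < 6; ++a)
          for (int b = 0; b < 6; ++b) Me[6 * a + b] += mm[a] * mm[b];
      }
    }
    Q.assign(36 * (size_t)n_elem, 0.0);
    for (int e = 0; e < n_elem; ++e)
      pinv6(&M6[36 * (size_t)e], &Q[36 * (size_t)e]);
  }
  std::vector<double> s6(6 * (size_t)n_elem, 0.0);
  for (int k = 0; k < m; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double mm[6];
    dir6(nrm(k, 0), nrm(k, 1), nrm(k, 2), mm);
    for (int e : {i, j})
      for (int a = 0; a < 6; ++a) s6[6 * (size_t)e + a] += eps_n[k] * mm[a];
  }
  NumericVector vm(n_elem), sbar_out(n_elem), epsv(n_elem);
  NumericMatrix stress(n_elem, 6);
  std::vector<double> sfb(n_elem), pfac(n_elem, 1.0);
  for (int e = 0; e < n_elem; ++e) {
    double eh[6];
    const double* Qe = &Q[36 * (size_t)e];
    for (int a = 0; a < 6; ++a) {
      eh[a] = 0.0;
      for (int b = 0; b < 6; ++b) eh[a] += Qe[6 * a + b] * s6[6 * (size_t)e + b];
    }
    double ev = eh[0] + eh[1] + eh[2];
    epsv[e] = ev;
    double ed[6] = {eh[0] - ev / 3.0, eh[1] - ev / 3.0, eh[2] - ev / 3.0,
                    eh[3], eh[4], eh[5]};
    double dd = ed[0] * ed[0] + ed[1] * ed[1] + ed[2] * ed[2] +
                2.0 * (ed[3] * ed[3] + ed[4] * ed[4] + ed[5] * ed[5]);
    double v = 2.0 * G[e] * std::sqrt(1.5 * dd);
    sfb[e] = K[e] * ev;  // effective (skeleton) mean stress
    if (R_finite(sigma_y[e]) && v > sigma_y[e]) pfac[e] = sigma_y[e] / v;
    vm[e] = v * pfac[e];
    double p_tot = K[e] * ev - alpha[e] * P[e];
    sbar_out[e] = p_tot;
    for (int a = 0; a < 6; ++a)
      stress(e, a) = 2.0 * G[e] * pfac[e] * ed[a] + (a < 3 ? p_tot : 0.0);
  }
  std::vector<double> degc(n_elem, 0.0), Abar(n_elem, 0.0);
  for (int k = 0; k < m; ++k) {
    for (int e : {pairs(k, 0) - 1, pairs(k, 1) - 1}) {
      degc[e] += 1.0;
      Abar[e] += A_pairs[k];
    }
  }
  for (int e = 0; e < n_elem; ++e) Abar[e] /= std::max(degc[e], 1.0);
  std::vector<double> qv;
  fit_trace_rows(Q, n_elem, qv);
  std::vector<double> sig_n(m);
  NumericMatrix tau_out(m, 3);
  for (int k = 0; k < m; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double Gi = G[i], Gj = G[j];
    double H = 2.0 / (1.0 / (2.0 * Gi) + 1.0 / (2.0 * Gj));
    double bi = 1.0 - 2.0 * Gi / (3.0 * K[i]);
    double bj = 1.0 - 2.0 * Gj / (3.0 * K[j]);
    // many-body and fluid terms enter each bond through its own fit weight
    // (energy gradient of the fitted volumetric strain)
    double mm[6];
    dir6(nrm(k, 0), nrm(k, 1), nrm(k, 2), mm);
    double wi = 0.0, wj = 0.0;
    for (int b = 0; b < 6; ++b) {
      wi += qv[6 * (size_t)i + b] * mm[b];
      wj += qv[6 * (size_t)j + b] * mm[b];
    }
    double sn = H * eps_n[k] +
      2.0 * (fb_scale[i] * (bi * sfb[i] - alpha[i] * P[i]) * Abar[i] * wi +
             fb_scale[j] * (bj * sfb[j] - alpha[j] * P[j]) * Abar[j] * wj) /
        A_pairs[k];
    double fp2 = std::min(pfac[i], pfac[j]);
    double tx = H * gamma(k, 0) * fp2, ty = H * gamma(k, 1) * fp2,
           tz = H * gamma(k, 2) * fp2;
    if (fp2 < 1.0) {
      double pbar = 0.5 * (sbar_out[i] + sbar_out[j]);
      sn = pbar + fp2 * (sn - pbar);
    }
    sig_n[k] = sn;
    tau_out(k, 0) = tx; tau_out(k, 1) = ty; tau_out(k, 2) = tz;
  }
  return List::create(_["sbar"] = sbar_out, _["vm"] = vm, _["eps_v"] = epsv,
                      _["sig_n"] = NumericVector(sig_n.begin(), sig_n.end()),
                      _["tau"] = tau_out, _["stress"] = stress);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, IntegerMatrix pairs, NumericVector r0,
             List props, List bc, List drivers, List ctrl) {
  // --- unpack -------------------------------------------------------------
  NumericMatrix pos = clone(pos0);
  const int n = pos.nrow(), m = pairs.nrow();
  NumericVector G = props["G"], K = props["K"], alpha = props["alpha"],
                Mbiot = props["M"], mass = props["mass"],
                sigma_y = props["sigma_y"], trans = props["trans"];
  LogicalVector is_metal = props["is_metal"];
  NumericVector A_pairs = props["A_pairs"];  // per-pair facet areas
  // per-pair stiffness multiplier: series-spring partition of bonds that
  // cross the analytic metal-tissue interface (smooths the staircase)
  NumericVector H_scale = props["H_scale"];
  // per-element multiplier of the many-body/fluid force terms (1 for the
  // FCC lattice; alternative discretizations carry their own constant)
  NumericVector fb_scale = props["fb_scale"];
  const double V_elem = as<double>(props["V_elem"]);
  const double d = as<double>(props["d"]);

  IntegerVector bc_code = bc["code"];
  NumericMatrix v_bc = bc["v_bc"];
  const double bc_hold_t = as<double>(bc["hold_t"]);
  NumericVector ext_fz = bc["ext_fz"];
  LogicalVector drained = bc["drained"];
  // impedance-matched dashpots on truncation (cut) faces: c = Z * d^2
  NumericVector absorb_c = bc["absorb_c"];

  const double wV = as<double>(drivers["wave_V"]);
  const double w_rise = as<double>(drivers["wave_t_rise"]);
  const double w_hold = as<double>(drivers["wave_t_hold"]);
  const double w_rec = as<double>(drivers["wave_t_rec"]);
  const double wVr = as<double>(drivers["wave_V_rec"]);
  const double w_period = as<double>(drivers["wave_period"]);
  const int w_n = as<int>(drivers["wave_n_pulses"]);
  const double ramp_vel = as<double>(drivers["ramp_v"]);
  const double ramp_t_start = as<double>(drivers["ramp_t_start"]);
  const double F_target = as<double>(drivers["ramp_target"]);
  const double u_max = as<double>(drivers["ramp_u_max"]);
  const int smooth_w = std::max(1, as<int>(drivers["ramp_smooth_steps"]));
  const int hold_steps = as<int>(drivers["ramp_hold_steps"]);

  const double dt = as<double>(ctrl["dt"]);
  const int n_steps = as<int>(ctrl["n_steps"]);
  const double damp = as<double>(ctrl["damping"]);
  const bool poro_on = as<bool>(ctrl["poro"]);
  const int rec_every = std::max(1, as<int>(ctrl["record_every"]));
  IntegerVector zone_idx = ctrl["zone_idx"];          // 1-based
  List gauges = ctrl["gauges"];                       // list of 1-based idx
  const bool rec_zone = as<bool>(ctrl["record_zone"]);

  // --- state --------------------------------------------------------------
  std::vector<double> vel(3 * (size_t)n, 0.0), omg(3 * (size_t)n, 0.0),
    acc(3 * (size_t)n, 0.0), aacc(3 * (size_t)n, 0.0),
    frc(3 * (size_t)n, 0.0), trq(3 * (size_t)n, 0.0);
  if (ctrl.containsElementNamed("vel0") && !Rf_isNull(ctrl["vel0"])) {
    NumericMatrix v0 = ctrl["vel0"];
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) vel[3 * (size_t)i + a] = v0(i, a);
  }
  std::vector<double> gam(3 * (size_t)m, 0.0), sbar(n, 0.0), vmis(n, 0.0),
    P(n, 0.0), eps_v(n, 0.0), eps_v_prev(n, 0.0), S(6 * (size_t)n, 0.0),
    sig_n(m, 0.0), tau(3 * (size_t)m, 0.0), sfb(n, 0.0), pfac(n, 1.0),
    shear_int(n, 0.0);
  if (ctrl.containsElementNamed("P0") && !Rf_isNull(ctrl["P0"])) {
    NumericVector p0 = ctrl["P0"];
    for (int i = 0; i < n; ++i) P[i] = p0[i];
  }
  std::vector<int> deg(n, 0);
  for (int k = 0; k < m; ++k) {
    deg[pairs(k, 0) - 1]++;
    deg[pairs(k, 1) - 1]++;
  }
  std::vector<double> Q;  // 6x6 strain-fit operator per element
  build_strain_fit(pairs, pos, n, Q);
  std::vector<double> qv;
  fit_trace_rows(Q, n, qv);
  // per-element mean bond facet area (used by the many-body force terms)
  std::vector<double> Abar(n, 0.0);
  for (int k = 0; k < m; ++k) {
    Abar[pairs(k, 0) - 1] += A_pairs[k];
    Abar[pairs(k, 1) - 1] += A_pairs[k];
  }
  for (int e = 0; e < n; ++e) Abar[e] /= std::max(deg[e], 1);
  std::vector<double> inertia(n);
  for (int i = 0; i < n; ++i) inertia[i] = 0.4 * mass[i] * 0.25 * d * d;

  // diffusion sub-cycling
  int nsub = 1;
  if (poro_on) {
    double mx = 0.0;
    std::vector<double> tsum(n, 0.0);
    for (int k = 0; k < m; ++k) {
      tsum[pairs(k, 0) - 1] += trans[k];
      tsum[pairs(k, 1) - 1] += trans[k];
    }
    for (int i = 0; i < n; ++i)
      if (!is_metal[i]) mx = std::max(mx, Mbiot[i] * tsum[i]);
    if (mx > 0.0) nsub = std::max(1, (int)std::ceil(dt * mx / 0.5));
  }

  // ramp bookkeeping
  bool ramp_frozen = false, ramp_reached = false;
  double u_ramp = 0.0, u_at_target = NA_REAL, t_at_target = NA_REAL;
  std::vector<double> Fz_window(smooth_w, 0.0);
  int win_fill = 0;
  long steps_since_target = -1;

  // zone pair mask for max-shear tracking
  std::vector<char> in_zone(n, 0);
  for (int z = 0; z < zone_idx.size(); ++z) in_zone[zone_idx[z] - 1] = 1;
  std::vector<char> zpair(m, 0);
  for (int k = 0; k < m; ++k)
    if (in_zone[pairs(k, 0) - 1] || in_zone[pairs(k, 1) - 1]) zpair[k] = 1;
  double max_zone_shear = 0.0;
  double U_pair = 0.0;

  // recording buffers
  std::vector<double> t_hist, F_hist, Fs_hist, u_hist, KE_hist, U_hist,
    Up_hist, px_hist, py_hist, pz_hist, zshear_hist;
  std::vector<std::vector<double>> zs_sbar, zs_vm, zs_shear, zs_P;
  std::vector<std::vector<double>> gauge_vx(gauges.size());
  const int nz = zone_idx.size();

  auto apply_bc_v = [&](double t) {
    double scale = (t < bc_hold_t) ? 1.0 : 0.0;
    for (int i = 0; i < n; ++i) {
      int c = bc_code[i];
      if (c == 0) continue;
      size_t o = 3 * (size_t)i;
      if (c & BC_WAVE) {
        vel[o] = wave_v(t, wV, w_rise, w_hold, w_rec, wVr, w_period, w_n);
        vel[o + 1] = 0.0; vel[o + 2] = 0.0;
        acc[o] = acc[o + 1] = acc[o + 2] = 0.0;
        omg[o] = omg[o + 1] = omg[o + 2] = 0.0;
        continue;
      }
      if (c & BC_RAMP) {
        vel[o] = 0.0; vel[o + 1] = 0.0;
        vel[o + 2] = ramp_frozen ? 0.0 : ramp_v(t, ramp_vel, ramp_t_start);
        acc[o] = acc[o + 1] = acc[o + 2] = 0.0;
        omg[o] = omg[o + 1] = omg[o + 2] = 0.0;
        continue;
      }
      if (c & BC_VX) { vel[o] = v_bc(i, 0) * scale; acc[o] = 0.0; }
      if (c & BC_VY) { vel[o + 1] = v_bc(i, 1) * scale; acc[o + 1] = 0.0; }
      if (c & BC_VZ) { vel[o + 2] = v_bc(i, 2) * scale; acc[o + 2] = 0.0; }
      if (c == (BC_VX | BC_VY | BC_VZ))
        omg[o] = omg[o + 1] = omg[o + 2] = 0.0;
    }
  };

  // stress + force evaluation at current positions/velocities
  std::vector<double> nrm(3 * (size_t)m), rno(m), epn(m);
  std::vector<double> s6(6 * (size_t)n);
  auto evaluate = [&](bool update_state, double dt_loc) {
    // kinematics
    for (int k = 0; k < m; ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      size_t oi = 3 * (size_t)i, oj = 3 * (size_t)j, ok = 3 * (size_t)k;
      double rx = pos(j, 0) - pos(i, 0);
      double ry = pos(j, 1) - pos(i, 1);
      double rz = pos(j, 2) - pos(i, 2);
      double r = std::sqrt(rx * rx + ry * ry + rz * rz);
      rno[k] = r;
      double nx = rx / r, ny = ry / r, nz = rz / r;
      nrm[ok] = nx; nrm[ok + 1] = ny; nrm[ok + 2] = nz;
      epn[k] = (r - r0[k]) / r0[k];
      if (update_state) {
        // midpoint velocities (v + a dt/2, w + aw dt/2): keeps the shear
        // "position" update consistent with the Verlet position update
        double h = 0.5 * dt_loc;
        double wx = 0.5 * (omg[oi] + h * aacc[oi] + omg[oj] + h * aacc[oj]);
        double wy = 0.5 * (omg[oi + 1] + h * aacc[oi + 1] +
                           omg[oj + 1] + h * aacc[oj + 1]);
        double wz = 0.5 * (omg[oi + 2] + h * aacc[oi + 2] +
                           omg[oj + 2] + h * aacc[oj + 2]);
        double dvx = vel[oj] + h * acc[oj] - vel[oi] - h * acc[oi] -
          (wy * rz - wz * ry);
        double dvy = vel[oj + 1] + h * acc[oj + 1] - vel[oi + 1] -
          h * acc[oi + 1] - (wz * rx - wx * rz);
        double dvz = vel[oj + 2] + h * acc[oj + 2] - vel[oi + 2] -
          h * acc[oi + 2] - (wx * ry - wy * rx);
        double dvn = dvx * nx + dvy * ny + dvz * nz;
        double gx = gam[ok] + (dvx - dvn * nx) * dt_loc / r0[k];
        double gy = gam[ok + 1] + (dvy - dvn * ny) * dt_loc / r0[k];
        double gz = gam[ok + 2] + (dvz - dvn * nz) * dt_loc / r0[k];
        double gn = gx * nx + gy * ny + gz * nz;
        gam[ok] = gx - gn * nx;
        gam[ok + 1] = gy - gn * ny;
        gam[ok + 2] = gz - gn * nz;
      }
    }
    // local strain tensors (least-squares fit over the element's bonds)
    std::fill(s6.begin(), s6.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      size_t ok = 3 * (size_t)k;
      double mm[6];
      dir6(nrm[ok], nrm[ok + 1], nrm[ok + 2], mm);
      for (int e : {i, j})
        for (int a = 0; a < 6; ++a) s6[6 * (size_t)e + a] += epn[k] * mm[a];
    }
    for (int e = 0; e < n; ++e) {
      double eh[6];
      const double* Qe = &Q[36 * (size_t)e];
      for (int a = 0; a < 6; ++a) {
        eh[a] = 0.0;
        for (int b = 0; b < 6; ++b)
          eh[a] += Qe[6 * a + b] * s6[6 * (size_t)e + b];
      }
      double ev = eh[0] + eh[1] + eh[2];
      eps_v[e] = ev;
      double ed0 = eh[0] - ev / 3.0, ed1 = eh[1] - ev / 3.0,
             ed2 = eh[2] - ev / 3.0;
      double dd = ed0 * ed0 + ed1 * ed1 + ed2 * ed2 +
                  2.0 * (eh[3] * eh[3] + eh[4] * eh[4] + eh[5] * eh[5]);
      double v = 2.0 * G[e] * std::sqrt(1.5 * dd);
      sfb[e] = K[e] * ev;
      pfac[e] = (R_finite(sigma_y[e]) && v > sigma_y[e]) ? sigma_y[e] / v : 1.0;
      vmis[e] = v * pfac[e];
      shear_int[e] = vmis[e] / (2.0 * G[e]);
      size_t oe = 6 * (size_t)e;
      double p_tot = K[e] * ev - alpha[e] * P[e];
      S[oe] = 2.0 * G[e] * pfac[e] * ed0 + p_tot;
      S[oe + 1] = 2.0 * G[e] * pfac[e] * ed1 + p_tot;
      S[oe + 2] = 2.0 * G[e] * pfac[e] * ed2 + p_tot;
      S[oe + 3] = 2.0 * G[e] * pfac[e] * eh[3];
      S[oe + 4] = 2.0 * G[e] * pfac[e] * eh[4];
      S[oe + 5] = 2.0 * G[e] * pfac[e] * eh[5];
      sbar[e] = p_tot;
    }
    // pore pressure: storage from the strain increment + Darcy exchange
    if (update_state && poro_on) {
      for (int i = 0; i < n; ++i)
        if (!is_metal[i])
          P[i] += -alpha[i] * Mbiot[i] * (eps_v[i] - eps_v_prev[i]);
      double dts = dt_loc / nsub;
      std::vector<double> dP(n);
      for (int s = 0; s < nsub; ++s) {
        std::fill(dP.begin(), dP.end(), 0.0);
        for (int k = 0; k < m; ++k) {
          if (trans[k] <= 0.0) continue;
          int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
          double f = trans[k] * (P[j] - P[i]);
          dP[i] += f;
          dP[j] -= f;
        }
        for (int i = 0; i < n; ++i)
          if (!is_metal[i]) P[i] += dts * Mbiot[i] * dP[i];
        for (int i = 0; i < n; ++i)
          if (drained[i] || is_metal[i]) P[i] = 0.0;
      }
    }
    if (update_state) std::copy(eps_v.begin(), eps_v.end(), eps_v_prev.begin());
    // pair stresses, forces, torques, pair-level elastic energy
    std::fill(frc.begin(), frc.end(), 0.0);
    std::fill(trq.begin(), trq.end(), 0.0);
    U_pair = 0.0;
    for (int k = 0; k < m; ++k) {
      int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
      size_t ok = 3 * (size_t)k, oi = 3 * (size_t)i, oj = 3 * (size_t)j;
      double Gi = G[i], Gj = G[j];
      double H = H_scale[k] * 2.0 / (1.0 / (2.0 * Gi) + 1.0 / (2.0 * Gj));
      double bi = 1.0 - 2.0 * Gi / (3.0 * K[i]);
      double bj = 1.0 - 2.0 * Gj / (3.0 * K[j]);
      double Ak = A_pairs[k];
      // Biot total normal force: pair spring on the pair facet, plus the
      // many-body term K*eps_v and fluid pressure entering each bond
      // through that bond's own fit weight w = qvec . m (the energy
      // gradient of the fitted volumetric strain: symmetric, conservative,
      // and equal to the uniform closure in the interior where w = 1/4)
      double mm[6];
      dir6(nrm[3 * (size_t)k], nrm[3 * (size_t)k + 1],
           nrm[3 * (size_t)k + 2], mm);
      double wi = 0.0, wj = 0.0;
      for (int b = 0; b < 6; ++b) {
        wi += qv[6 * (size_t)i + b] * mm[b];
        wj += qv[6 * (size_t)j + b] * mm[b];
      }
      double sn = H * epn[k] +
        2.0 * (fb_scale[i] * (bi * sfb[i] - alpha[i] * P[i]) * Abar[i] * wi +
               fb_scale[j] * (bj * sfb[j] - alpha[j] * P[j]) * Abar[j] * wj) / Ak;
      double fp = std::min(pfac[i], pfac[j]);
      double tx = H * gam[ok] * fp, ty = H * gam[ok + 1] * fp,
             tz = H * gam[ok + 2] * fp;
      if (fp < 1.0) {
        double pbar = 0.5 * (sbar[i] + sbar[j]);
        sn = pbar + fp * (sn - pbar);
      }
      sig_n[k] = sn;
      tau[ok] = tx; tau[ok + 1] = ty; tau[ok + 2] = tz;
      double nx = nrm[ok], ny = nrm[ok + 1], nz = nrm[ok + 2];
      double fx = Ak * (sn * nx + tx);
      double fy = Ak * (sn * ny + ty);
      double fz = Ak * (sn * nz + tz);
      frc[oi] += fx; frc[oi + 1] += fy; frc[oi + 2] += fz;
      frc[oj] -= fx; frc[oj + 1] -= fy; frc[oj + 2] -= fz;
      // torque from the tangential traction at the shared contact point
      double hq = 0.5 * rno[k] * Ak;
      double tqx = hq * (ny * tz - nz * ty);
      double tqy = hq * (nz * tx - nx * tz);
      double tqz = hq * (nx * ty - ny * tx);
      trq[oi] += tqx; trq[oi + 1] += tqy; trq[oi + 2] += tqz;
      trq[oj] += tqx; trq[oj + 1] += tqy; trq[oj + 2] += tqz;
      U_pair += 0.5 * Ak * r0[k] *
        (sn * epn[k] + tx * gam[ok] + ty * gam[ok + 1] + tz * gam[ok + 2]);
    }
    for (int i = 0; i < n; ++i) {
      size_t o = 3 * (size_t)i;
      frc[o + 2] += ext_fz[i];
      if (absorb_c[i] > 0.0) {
        frc[o] -= absorb_c[i] * vel[o];
        frc[o + 1] -= absorb_c[i] * vel[o + 1];
        frc[o + 2] -= absorb_c[i] * vel[o + 2];
      }
    }
  };

  // --- time loop ----------------------------------------------------------
  apply_bc_v(0.0);
  evaluate(false, dt);
  for (int i = 0; i < n; ++i) {
    size_t o = 3 * (size_t)i;
    for (int a = 0; a < 3; ++a) {
      acc[o + a] = frc[o + a] / mass[i];
      aacc[o + a] = trq[o + a] / inertia[i];
    }
  }
  apply_bc_v(0.0);

  int last_step = n_steps;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    apply_bc_v(t);
    // positions (applicator follows the exact waveform displacement)
    double du_wave = wave_u(t + dt, wV, w_rise, w_hold, w_rec, wVr,
                            w_period, w_n) -
                     wave_u(t, wV, w_rise, w_hold, w_rec, wVr, w_period, w_n);
    for (int i = 0; i < n; ++i) {
      size_t o = 3 * (size_t)i;
      if (bc_code[i] & BC_WAVE) {
        pos(i, 0) += du_wave;
        continue;
      }
      pos(i, 0) += vel[o] * dt + 0.5 * acc[o] * dt * dt;
      pos(i, 1) += vel[o + 1] * dt + 0.5 * acc[o + 1] * dt * dt;
      pos(i, 2) += vel[o + 2] * dt + 0.5 * acc[o + 2] * dt * dt;
    }
    if (!ramp_frozen && F_target > 0.0) {
      double vr = ramp_v(t, ramp_vel, ramp_t_start);
      u_ramp += std::fabs(vr) * dt;
    }
    evaluate(true, dt);
    // damping (local, non-viscous) on the free axes
    if (damp > 0.0) {
      for (int i = 0; i < n; ++i) {
        int c = bc_code[i];
        if (c & (BC_WAVE | BC_RAMP)) continue;  // fully prescribed drivers
        size_t o = 3 * (size_t)i;
        for (int a = 0; a < 3; ++a) {
          if (c & (1 << a)) continue;  // this axis is prescribed
          double sgn = (vel[o + a] > 0.0) ? 1.0 : ((vel[o + a] < 0.0) ? -1.0 : 0.0);
          frc[o + a] -= damp * std::fabs(frc[o + a]) * sgn;
        }
        if (c != (BC_VX | BC_VY | BC_VZ)) {
          for (int a = 0; a < 3; ++a) {
            double sgw = (omg[o + a] > 0.0) ? 1.0 : ((omg[o + a] < 0.0) ? -1.0 : 0.0);
            trq[o + a] -= damp * std::fabs(trq[o + a]) * sgw;
          }
        }
      }
    }
    // integrate velocities and spins (two-half-kick updates)
    for (int i = 0; i < n; ++i) {
      size_t o = 3 * (size_t)i;
      for (int a = 0; a < 3; ++a) {
        double anew = frc[o + a] / mass[i];
        vel[o + a] += 0.5 * (acc[o + a] + anew) * dt;
        acc[o + a] = anew;
        double wnew = trq[o + a] / inertia[i];
        omg[o + a] += 0.5 * (aacc[o + a] + wnew) * dt;
        aacc[o + a] = wnew;
      }
    }
    apply_bc_v(t + dt);

    // ramp reaction force (force exerted by the rest of the model on the set)
    double Fz_set = 0.0;
    if (F_target > 0.0) {
      for (int i = 0; i < n; ++i)
        if (bc_code[i] & BC_RAMP) Fz_set += frc[3 * (size_t)i + 2];
      double R = std::fabs(Fz_set);
      Fz_window[s % smooth_w] = R;
      if (win_fill < smooth_w) win_fill++;
      double Rs = 0.0;
      for (int w = 0; w < win_fill; ++w) Rs += Fz_window[w];
      Rs /= win_fill;
      if (!ramp_frozen && win_fill == smooth_w && Rs >= F_target) {
        ramp_frozen = true;
        ramp_reached = true;
        u_at_target = u_ramp;
        t_at_target = t;
        steps_since_target = 0;
      }
      if (!ramp_frozen && u_ramp > u_max) { last_step = s + 1; }
      if (steps_since_target >= 0 && ++steps_since_target >= hold_steps) {
        last_step = s + 1;
      }
      if ((s + 1) % rec_every == 0 || s == 0) {
        t_hist.push_back(t + dt);
        F_hist.push_back(R);
        Fs_hist.push_back(Rs);
        u_hist.push_back(u_ramp);
      }
    } else if ((s + 1) % rec_every == 0 || s == 0) {
      t_hist.push_back(t + dt);
    }

    // trackers
    for (int k = 0; k < m; ++k) {
      if (!zpair[k]) continue;
      size_t ok = 3 * (size_t)k;
      double g2 = gam[ok] * gam[ok] + gam[ok + 1] * gam[ok + 1] +
                  gam[ok + 2] * gam[ok + 2];
      if (g2 > max_zone_shear) max_zone_shear = g2;
    }

    if ((s + 1) % rec_every == 0 || s == 0) {
      double KE = 0.0, U = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
      for (int i = 0; i < n; ++i) {
        size_t o = 3 * (size_t)i;
        KE += 0.5 * mass[i] * (vel[o] * vel[o] + vel[o + 1] * vel[o + 1] +
                               vel[o + 2] * vel[o + 2]);
        KE += 0.5 * inertia[i] * (omg[o] * omg[o] + omg[o + 1] * omg[o + 1] +
                                  omg[o + 2] * omg[o + 2]);
        double Vh = V_elem * std::max(deg[i], 1) / 12.0;
        U += Vh * (sbar[i] * sbar[i] / (2.0 * K[i]) +
                   vmis[i] * vmis[i] / (6.0 * G[i]));
        if (poro_on && !is_metal[i] && R_finite(Mbiot[i]) && Mbiot[i] > 0)
          U += Vh * P[i] * P[i] / (2.0 * Mbiot[i]);
        mx += mass[i] * vel[o];
        my += mass[i] * vel[o + 1];
        mz += mass[i] * vel[o + 2];
      }
      KE_hist.push_back(KE);
      U_hist.push_back(U);
      Up_hist.push_back(U_pair);
      px_hist.push_back(mx); py_hist.push_back(my); pz_hist.push_back(mz);
      zshear_hist.push_back(std::sqrt(max_zone_shear));
      if (rec_zone && nz > 0) {
        std::vector<double> a(nz), b(nz), c(nz), e(nz);
        for (int z = 0; z < nz; ++z) {
          int i = zone_idx[z] - 1;
          a[z] = sbar[i];
          b[z] = vmis[i];
          c[z] = shear_int[i];
          e[z] = P[i];
        }
        zs_sbar.push_back(a); zs_vm.push_back(b);
        zs_shear.push_back(c); zs_P.push_back(e);
      }
      for (int g = 0; g < gauges.size(); ++g) {
        IntegerVector gi = gauges[g];
        double v = 0.0;
        for (int q = 0; q < gi.size(); ++q) v += vel[3 * (size_t)(gi[q] - 1)];
        gauge_vx[g].push_back(v / std::max(1, (int)gi.size()));
      }
      if (!R_finite(KE))
        stop("non-finite state at step %d: simulation diverged "
             "(reduce dt or check configuration)", s + 1);
    }
    if (last_step == s + 1) break;
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }

  // --- pack results -------------------------------------------------------
  auto mat_from = [&](std::vector<std::vector<double>>& v) {
    int nr = (int)v.size();
    NumericMatrix out(nr, nz);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nz; ++c) out(r, c) = v[r][c];
    return out;
  };
  NumericMatrix vel_out(n, 3), omg_out(n, 3), stress_out(n, 6);
  NumericVector sbar_out(n), vm_out(n), P_out(n), shear_out(n), epsv_out(n);
  for (int i = 0; i < n; ++i) {
    size_t o = 3 * (size_t)i;
    for (int a = 0; a < 3; ++a) {
      vel_out(i, a) = vel[o + a];
      omg_out(i, a) = omg[o + a];
    }
    for (int a = 0; a < 6; ++a) stress_out(i, a) = S[6 * (size_t)i + a];
    sbar_out[i] = sbar[i];
    vm_out[i] = vmis[i];
    P_out[i] = P[i];
    shear_out[i] = shear_int[i];
    epsv_out[i] = eps_v[i];
  }
  NumericMatrix gam_out(m, 3);
  for (int k = 0; k < m; ++k)
    for (int a = 0; a < 3; ++a) gam_out(k, a) = gam[3 * (size_t)k + a];
  List gg(gauge_vx.size());
  for (size_t g = 0; g < gauge_vx.size(); ++g)
    gg[g] = NumericVector(gauge_vx[g].begin(), gauge_vx[g].end());
  List out;
  out["pos"] = pos; out["vel"] = vel_out; out["omega"] = omg_out;
  out["sbar"] = sbar_out; out["vm"] = vm_out; out["P"] = P_out;
  out["shear"] = shear_out; out["eps_v"] = epsv_out; out["stress"] = stress_out;
  out["gamma"] = gam_out;
  out["t"] = NumericVector(t_hist.begin(), t_hist.end());
  out["F_ramp"] = NumericVector(F_hist.begin(), F_hist.end());
  out["F_ramp_smooth"] = NumericVector(Fs_hist.begin(), Fs_hist.end());
  out["u_ramp"] = NumericVector(u_hist.begin(), u_hist.end());
  out["KE"] = NumericVector(KE_hist.begin(), KE_hist.end());
  out["U"] = NumericVector(U_hist.begin(), U_hist.end());
  out["U_pair"] = NumericVector(Up_hist.begin(), Up_hist.end());
  out["momentum"] = DataFrame::create(
    _["px"] = NumericVector(px_hist.begin(), px_hist.end()),
    _["py"] = NumericVector(py_hist.begin(), py_hist.end()),
    _["pz"] = NumericVector(pz_hist.begin(), pz_hist.end()));
  out["max_zone_pair_shear"] = std::sqrt(max_zone_shear);
  out["zone_shear_hist"] =
    NumericVector(zshear_hist.begin(), zshear_hist.end());
  out["zone_sbar"] = mat_from(zs_sbar); out["zone_vm"] = mat_from(zs_vm);
  out["zone_shear"] = mat_from(zs_shear); out["zone_P"] = mat_from(zs_P);
  out["gauges"] = gg;
  out["ramp_reached"] = ramp_reached; out["u_at_target"] = u_at_target;
  out["t_at_target"] = t_at_target; out["nsub"] = nsub;
  out["steps_run"] = last_step;
  return out;
}
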