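#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Crankshaft Metropolis kernel for a closed bead-rod loop with harmonic
// joint bending energy E_i = (kappa_i / 2) * theta_i^2 (units of kT).
// Positions are modified in place on a local copy; the R wrapper owns
// parameter validation and seeding (R's RNG is used, so set.seed() in R
// makes runs reproducible).

static inline double joint_theta(const std::vector<double> &x,
                                 const std::vector<double> &y,
                                 const std::vector<double> &z,
                                 int n, int j) {
  int jm = (j - 1 + n) % n, jp = (j + 1) % n;
  double ax = x[j] - x[jm], ay = y[j] - y[jm], az = z[j] - z[jm];
  double bx = x[jp] - x[j], by = y[jp] - y[j], bz = z[jp] - z[j];
  double dot = ax * bx + ay * by + az * bz;
  double cx = ay * bz - az * by;
  double cy = az * bx - ax * bz;
  double cz = ax * by - ay * bx;
  double crs = std::sqrt(cx * cx + cy * cy + cz * cz);
  return std::atan2(crs, dot);
}

static inline double joint_energy(const std::vector<double> &x,
                                  const std::vector<double> &y,
                                  const std::vector<double> &z,
                                  const NumericVector &kappa, int n, int j) {
  double th = joint_theta(x, y, z, n, j);
  return 0.5 * kappa[j] * th * th;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericMatrix pos, NumericVector kappa,
                IntegerVector ds_joints,   // 0-based joints summed as dsDNA energy
                int dye_i, int dye_j,      // 0-based node indices, -1 = none
                IntegerVector watch1,      // 0-based joints: mean angle series 1
                IntegerVector watch2,      // 0-based joints: mean angle series 2
                double n_equil_d, double n_sample_d, int record_interval,
                double max_angle) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
  }
  std::vector<bool> is_ds(n, false);
  for (int k = 0; k < ds_joints.size(); ++k) is_ds[ds_joints[k]] = true;

  long long n_equil = (long long)n_equil_d;
  long long n_sample = (long long)n_sample_d;
  long long n_rec = record_interval > 0 ? n_sample / record_interval : 0;

  NumericVector rec_ds(n_rec), rec_total(n_rec), rec_dye(n_rec);
  NumericVector rec_w1(n_rec), rec_w2(n_rec);

  // running totals, refreshed from scratch periodically to kill fp drift
  double e_total = 0.0, e_ds = 0.0;
  for (int j = 0; j < n; ++j) {
    double e = joint_energy(x, y, z, kappa, n, j);
    e_total += e;
    if (is_ds[j]) e_ds += e;
  }

  long long accepted = 0, proposals = 0, rec_idx = 0;
  long long total_steps = n_equil + n_sample;

  for (long long step = 0; step < total_steps; ++step) {
    int u = (int)(unif_rand() * n);
    if (u == n) u = n - 1;
    double ang = (2.0 * unif_rand() - 1.0) * max_angle;
    int up = (u + 1) % n, um = (u - 1 + n) % n;

    double axx = x[up] - x[um], axy = y[up] - y[um], axz = z[up] - z[um];
    double an = std::sqrt(axx * axx + axy * axy + axz * axz);
    ++proposals;
    bool accept = false;
    double ox = x[u], oy = y[u], oz = z[u];
    if (an > 1e-12) {
      axx /= an; axy /= an; axz /= an;
      // Rodrigues rotation of (p_u - p_um) about unit axis
      double vx = ox - x[um], vy = oy - y[um], vz = oz - z[um];
      double c = std::cos(ang), s = std::sin(ang);
      double adotv = axx * vx + axy * vy + axz * vz;
      double rx = vx * c + (axy * vz - axz * vy) * s + axx * adotv * (1 - c);
      double ry = vy * c + (axz * vx - axx * vz) * s + axy * adotv * (1 - c);
      double rz = vz * c + (axx * vy - axy * vx) * s + axz * adotv * (1 - c);

      // joints touched by moving node u
      int touched[3] = {um, u, up};
      double e_old = 0.0, e_old_ds = 0.0;
      for (int t = 0; t < 3; ++t) {
        double e = joint_energy(x, y, z, kappa, n, touched[t]);
        e_old += e;
        if (is_ds[touched[t]]) e_old_ds += e;
      }
      x[u] = x[um] + rx; y[u] = y[um] + ry; z[u] = z[um] + rz;
      double e_new = 0.0, e_new_ds = 0.0;
      for (int t = 0; t < 3; ++t) {
        double e = joint_energy(x, y, z, kappa, n, touched[t]);
        e_new += e;
        if (is_ds[touched[t]]) e_new_ds += e;
      }
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        accept = true;
        e_total += dE;
        e_ds += e_new_ds - e_old_ds;
      } else {
        x[u] = ox; y[u] = oy; z[u] = oz;
      }
    }
    if (accept) ++accepted;

    if (step >= n_equil && record_interval > 0 &&
        ((step - n_equil + 1) % record_interval == 0) && rec_idx < n_rec) {
      if ((rec_idx & 1023) == 0) {  // periodic full refresh
        e_total = 0.0; e_ds = 0.0;
        for (int j = 0; j < n; ++j) {
          double e = joint_energy(x, y, z, kappa, n, j);
          e_total += e;
          if (is_ds[j]) e_ds += e;
        }
      }
      rec_ds[rec_idx] = e_ds;
      rec_total[rec_idx] = e_total;
      if (dye_i >= 0 && dye_j >= 0) {
        double dx = x[dye_i] - x[dye_j], dy = y[dye_i] - y[dye_j],
               dz = z[dye_i] - z[dye_j];
        rec_dye[rec_idx] = std::sqrt(dx * dx + dy * dy + dz * dz);
      } else {
        rec_dye[rec_idx] = NA_REAL;
      }
      if (watch1.size() > 0) {
        double s1 = 0.0;
        for (int k = 0; k < watch1.size(); ++k)
          s1 += joint_theta(x, y, z, n, watch1[k]);
        rec_w1[rec_idx] = s1 / watch1.size();
      } else {
        rec_w1[rec_idx] = NA_REAL;
      }
      if (watch2.size() > 0) {
        double s2 = 0.0;
        for (int k = 0; k < watch2.size(); ++k)
          s2 += joint_theta(x, y, z, n, watch2[k]);
        rec_w2[rec_idx] = s2 / watch2.size();
      } else {
        rec_w2[rec_idx] = NA_REAL;
      }
      ++rec_idx;
    }
  }

  NumericMatrix out_pos(n, 3);
  for (int i = 0; i < n; ++i) {
    out_pos(i, 0) = x[i];
    out_pos(i, 1) = y[i];
    out_pos(i, 2) = z[i];
  }
  return List::create(
      _["energy_ds"] = rec_ds, _["energy_total"] = rec_total,
      _["dye_distance"] = rec_dye, _["watch1_angle"] = rec_w1,
      _["watch2_angle"] = rec_w2, _["accepted"] = (double)accepted,
      _["proposals"] = (double)proposals, _["positions"] = out_pos);
}
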