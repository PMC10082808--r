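#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler integration of one encounter.
//
// Agents relax toward their desired velocity with time constant tau. When
// `dyad` is true, agents 0 and 1 are bound by a linear cohesion spring of
// rest length `rest_sep`, and the optional central repulsion (potential
// k / r^beta between the dyad center and agent 2) pushes agent 2 away with
// the full acceleration and the dyad members with a reduced mobility
// factor. When `dyad` is false there are two lone agents and the repulsion
// acts symmetrically on both. Distances in the force law are floored at
// `floor_r` for numerical safety.
//
// Returns a (n_rec + 1) x (2 * n_agents) matrix of recorded positions
// (columns x_1..x_n, y_1..y_n), one row per sampling instant including the
// initial state; `substeps` Euler steps of length dt are taken per record.
// [[Rcpp::export]]
NumericMatrix integrate_encounter_cpp(NumericMatrix p0, NumericMatrix v_des,
                                      bool dyad, double rest_sep, double k_coh,
                                      bool repel, double k, double beta,
                                      double mob, double tau, double floor_r,
                                      double dt, int n_rec, int substeps) {
  const int na = p0.nrow();
  std::vector<double> px(na), py(na), vx(na), vy(na), ax(na), ay(na);
  for (int j = 0; j < na; ++j) {
    px[j] = p0(j, 0);
    py[j] = p0(j, 1);
    vx[j] = v_des(j, 0);
    vy[j] = v_des(j, 1);
  }
  NumericMatrix rec(n_rec + 1, 2 * na);
  for (int j = 0; j < na; ++j) {
    rec(0, j) = px[j];
    rec(0, na + j) = py[j];
  }
  for (int i = 1; i <= n_rec; ++i) {
    for (int s = 0; s < substeps; ++s) {
      for (int j = 0; j < na; ++j) {
        ax[j] = (v_des(j, 0) - vx[j]) / tau;
        ay[j] = (v_des(j, 1) - vy[j]) / tau;
      }
      if (dyad && k_coh > 0) {
        const double rx = px[0] - px[1], ry = py[0] - py[1];
        const double sep = std::sqrt(rx * rx + ry * ry);
        if (sep > 0) {
          const double f = -k_coh * (sep - rest_sep) / sep;
          ax[0] += f * rx;
          ay[0] += f * ry;
          ax[1] -= f * rx;
          ay[1] -= f * ry;
        }
      }
      if (repel) {
        double cx, cy;
        int tgt;
        if (dyad) {
          cx = 0.5 * (px[0] + px[1]);
          cy = 0.5 * (py[0] + py[1]);
          tgt = 2;
        } else {
          cx = px[0];
          cy = py[0];
          tgt = 1;
        }
        double rx = px[tgt] - cx, ry = py[tgt] - cy;
        double dist = std::sqrt(rx * rx + ry * ry);
        if (dist < floor_r) dist = floor_r;
        const double fmag = k * beta / std::pow(dist, beta + 2.0);
        const double fx = fmag * rx, fy = fmag * ry;
        if (dyad) {
          ax[2] += fx;
          ay[2] += fy;
          ax[0] -= mob * fx;
          ay[0] -= mob * fy;
          ax[1] -= mob * fx;
          ay[1] -= mob * fy;
        } else {
          ax[1] += fx;
          ay[1] += fy;
          ax[0] -= fx;
          ay[0] -= fy;
        }
      }
      for (int j = 0; j < na; ++j) {
        vx[j] += ax[j] * dt;
        vy[j] += ay[j] * dt;
        px[j] += vx[j] * dt;
        py[j] += vy[j] * dt;
      }
    }
    for (int j = 0; j < na; ++j) {
      if (!std::isfinite(px[j]) || !std::isfinite(py[j])) {
        stop("non-finite state at recording step %d", i);
      }
      rec(i, j) = px[j];
      rec(i, na + j) = py[j];
    }
  }
  return rec;
}
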