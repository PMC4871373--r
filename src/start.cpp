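// Start-transition standard component model: deterministic Euler integration
// and chemical-Langevin stochastic integration (lumped or explicit mRNA noise).
// State is in molecule numbers; V in fL grows exponentially unless frozen.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double soft_H(double x) {
  if (x > 500.0) return 1.0;
  if (x < -500.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct StartParams {
  double ka_g, kd_bf, kd_bS, kd_g, kd_hi5, kd_i5;
  double kd_mbS, kd_mhi5, kd_mi5, kd_mn3, kd_n3;
  double ks_bf, ks_bS, ks_hi5, ks_i5;
  double ks_mbS, ks_mhi5, ks_mi5, ks_mn3, ks_n3;
  double mmin_bS, mmin_hi5, mmin_i5, mmin_n3;
  double gamma, mu, sigma, om_dp, om_p, om_pp;
};

static StartParams load_start_params(const NumericVector& p) {
  StartParams q;
  q.ka_g = p["ka_g"]; q.kd_bf = p["kd_bf"]; q.kd_bS = p["kd_bS"];
  q.kd_g = p["kd_g"]; q.kd_hi5 = p["kd_hi5"]; q.kd_i5 = p["kd_i5"];
  q.kd_mbS = p["kd_mbS"]; q.kd_mhi5 = p["kd_mhi5"]; q.kd_mi5 = p["kd_mi5"];
  q.kd_mn3 = p["kd_mn3"]; q.kd_n3 = p["kd_n3"];
  q.ks_bf = p["ks_bf"]; q.ks_bS = p["ks_bS"]; q.ks_hi5 = p["ks_hi5"];
  q.ks_i5 = p["ks_i5"]; q.ks_mbS = p["ks_mbS"]; q.ks_mhi5 = p["ks_mhi5"];
  q.ks_mi5 = p["ks_mi5"]; q.ks_mn3 = p["ks_mn3"]; q.ks_n3 = p["ks_n3"];
  q.mmin_bS = p["mmin_bS"]; q.mmin_hi5 = p["mmin_hi5"];
  q.mmin_i5 = p["mmin_i5"]; q.mmin_n3 = p["mmin_n3"];
  q.gamma = p["gamma"]; q.mu = p["mu"]; q.sigma = p["sigma"];
  q.om_dp = p["om_dp"]; q.om_p = p["om_p"]; q.om_pp = p["om_pp"];
  return q;
}

// One protein CLE increment: protein noise always; mRNA-inherited noise when
// mbar >= 0 (pass mbar < 0 to disable, e.g. SBF which has no mRNA species).
static inline double cle_increment(double X, double A, double B,
                                   double mbar, double mmin, double kdm,
                                   double dt, double sqdt,
                                   std::normal_distribution<double>& nd,
                                   std::mt19937_64& rng) {
  double dX = (A - B * X) * dt;
  double amp1 = A + B * X;
  if (amp1 > 0.0) dX += std::sqrt(amp1) * nd(rng) * sqdt;
  if (mbar >= 0.0) {
    double M = 1.0 / (mbar + mmin);
    double amp2 = X * std::sqrt(2.0 * B) * std::sqrt(M * B / (B + kdm));
    dX += amp2 * nd(rng) * sqdt;
  }
  return dX;
}

// mode: 0 deterministic, 1 CLE with lumped mRNA noise, 2 CLE protein noise only,
//       3 CLE with explicit mRNA species.
// State order: Cln3, ClbS, Whi5A, Whi5T, Hi5, SBFT (+ m_n3, m_bS, m_i5, m_hi5
// in mode 3). Returned matrix columns: t, V, state..., SBF.
// [[Rcpp::export]]
NumericMatrix start_sim_cpp(NumericVector params, NumericVector init,
                            double v0, double tend, double dt,
                            double record_dt, int mode, bool fixed_v,
                            int seed) {
  StartParams q = load_start_params(params);
  const bool explicit_m = (mode == 3);
  const int ns = explicit_m ? 10 : 6;
  if (init.size() != ns) stop("init has wrong length for this mode");

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);

  std::vector<double> x(init.begin(), init.end());
  double V = v0;
  const double sqdt = std::sqrt(dt);
  const long nsteps = static_cast<long>(std::ceil(tend / dt));
  const long rec_every = std::max(1L, static_cast<long>(std::round(record_dt / dt)));
  const long nrec = nsteps / rec_every + 1;

  NumericMatrix out(nrec, ns + 3);
  long irow = 0;
  const double m_n3_ss = q.ks_mn3 / q.kd_mn3, m_i5_ss = q.ks_mi5 / q.kd_mi5;
  const double m_hi5_ss = q.ks_mhi5 / q.kd_mhi5, m_bS_cap = q.ks_mbS / q.kd_mbS;

  for (long step = 0; step <= nsteps; ++step) {
    double SBF = std::max(0.0, x[5] - x[2]);
    if (step % rec_every == 0 && irow < nrec) {
      out(irow, 0) = step * dt; out(irow, 1) = V;
      for (int k = 0; k < ns; ++k) out(irow, 2 + k) = x[k];
      out(irow, ns + 2) = SBF;
      ++irow;
    }
    if (step == nsteps) break;

    double Ga = SBF / (SBF + q.kd_g * V / q.ka_g);
    // mRNA levels entering synthesis rates
    double m_n3, m_bS, m_i5, m_hi5;
    if (explicit_m) { m_n3 = x[6]; m_bS = x[7]; m_i5 = x[8]; m_hi5 = x[9]; }
    else { m_n3 = m_n3_ss; m_bS = m_bS_cap * Ga; m_i5 = m_i5_ss; m_hi5 = m_hi5_ss; }

    double A_n3 = q.ks_n3 * V * V * m_n3;
    double A_bS = q.ks_bS * V * m_bS;
    double A_i5 = q.ks_i5 * V * m_i5;
    double A_hi5 = q.ks_hi5 * V * m_hi5;
    double A_bf = q.ks_bf * V;

    double W = (q.om_dp * x[4] - q.om_p * x[0] - q.om_pp * x[1]) / V;
    double dWhi5A = q.gamma * (x[3] * soft_H(q.sigma * W) - x[2]) * dt;

    std::vector<double> xn = x;
    if (mode == 0) {
      xn[0] += (A_n3 - q.kd_n3 * x[0]) * dt;
      xn[1] += (A_bS - q.kd_bS * x[1]) * dt;
      xn[3] += (A_i5 - q.kd_i5 * x[3]) * dt;
      xn[4] += (A_hi5 - q.kd_hi5 * x[4]) * dt;
      xn[5] += (A_bf - q.kd_bf * x[5]) * dt;
    } else if (mode == 1 || mode == 2) {
      bool mn = (mode == 1);
      xn[0] += cle_increment(x[0], A_n3, q.kd_n3, mn ? m_n3 : -1.0, q.mmin_n3,
                             q.kd_mn3, dt, sqdt, nd, rng);
      xn[1] += cle_increment(x[1], A_bS, q.kd_bS, mn ? m_bS : -1.0, q.mmin_bS,
                             q.kd_mbS, dt, sqdt, nd, rng);
      xn[3] += cle_increment(x[3], A_i5, q.kd_i5, mn ? m_i5 : -1.0, q.mmin_i5,
                             q.kd_mi5, dt, sqdt, nd, rng);
      xn[4] += cle_increment(x[4], A_hi5, q.kd_hi5, mn ? m_hi5 : -1.0, q.mmin_hi5,
                             q.kd_mhi5, dt, sqdt, nd, rng);
      xn[5] += cle_increment(x[5], A_bf, q.kd_bf, -1.0, 0.0, 1.0, dt, sqdt, nd, rng);
    } else { // explicit mRNA: proteins carry protein noise only, mRNAs are CLE species
      xn[0] += cle_increment(x[0], A_n3, q.kd_n3, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[1] += cle_increment(x[1], A_bS, q.kd_bS, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[3] += cle_increment(x[3], A_i5, q.kd_i5, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[4] += cle_increment(x[4], A_hi5, q.kd_hi5, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[5] += cle_increment(x[5], A_bf, q.kd_bf, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[6] += cle_increment(x[6], q.ks_mn3, q.kd_mn3, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[7] += cle_increment(x[7], q.ks_mbS * Ga, q.kd_mbS, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[8] += cle_increment(x[8], q.ks_mi5, q.kd_mi5, -1.0, 0, 1, dt, sqdt, nd, rng);
      xn[9] += cle_increment(x[9], q.ks_mhi5, q.kd_mhi5, -1.0, 0, 1, dt, sqdt, nd, rng);
    }
    xn[2] = x[2] + dWhi5A;

    // clamps: counts non-negative; active Whi5 within [0, total]
    for (int k = 0; k < ns; ++k) if (xn[k] < 0.0) xn[k] = 0.0;
    if (xn[2] > xn[3]) xn[2] = xn[3];
    x = xn;
    if (!fixed_v) V *= std::exp(q.mu * dt);

    for (int k = 0; k < ns; ++k)
      if (!std::isfinite(x[k])) stop("non-finite state at t = %f", step * dt);
  }
  return out;
}

// Relax to steady state at fixed V; returns the final 6-vector.
// [[Rcpp::export]]
NumericVector start_relax_cpp(NumericVector params, NumericVector init,
                              double v, double tend, double dt) {
  NumericMatrix tr = start_sim_cpp(params, init, v, tend, dt, tend, 0, true, 1L);
  int last = tr.nrow() - 1;
  NumericVector out(6);
  for (int k = 0; k < 6; ++k) out[k] = tr(last, 2 + k);
  return out;
}
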