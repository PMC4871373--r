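// Full budding-yeast cell-cycle standard component model in normalized
// concentration units: 24 dynamic variables (class 1, dynamic class 2 and the
// BUD/ORI/SPN progress variables), two quasi-steady class-2 activities and a
// chain of class-3 complexes, integrated by explicit Euler with event rules,
// asymmetric division and an optional chemical-Langevin noise layer in which
// class-1 species are propagated as molecule numbers.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double soft_H(double x) {
  if (x > 500.0) return 1.0;
  if (x < -500.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}
static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// dynamic state layout
enum {
  iCln3 = 0, iBck2, iCln2, iWhi5A, iSBFA, iBUD, iClb5T, iClb2T, iCKIT, iCKIP,
  iSwi5T, iORI, iCdh1A, iAPCP, iMad2A, iSPN, iCdc20T, iPds1T, iPPXA, iNet1A,
  iPoloT, iPoloA, iTem1A, iCdc15A, NDYN
};

// class-1 species (order used for noise, conversion and sampling)
static const int CL1[10] = { iCln3, iBck2, iCln2, iClb5T, iClb2T, iCKIT,
                             iSwi5T, iCdc20T, iPds1T, iPoloT };
static const double CS[10]   = { 40, 40, 40, 40, 40, 40, 57.5, 150, 3.3, 100 };

struct CCParams {
  double ks_bck2, kd_bck2, ks_bud_e, kd_bud;
  double ks_cdc20, ks_cdc20_m1, kd_cdc20;
  double ks_cki, ks_cki_swi5, kd_cki, kd_ckip, ks_cki_gal;
  double ks_clb2, ks_clb2_m1, kd_clb2, kd_clb2_20, kd_clb2_20_i, kd_clb2_h1;
  double ks_clb5, ks_clb5_bf, kd_clb5, kd_clb5_20, kd_clb5_20_i;
  double ks_cln2, ks_cln2_bf, kd_cln2;
  double ks_cln3, kd_cln3;
  double ks_ori_e, kd_ori;
  double ks_pds1, kd_pds1, kd_pds1_20, kd_pds1_20_i;
  double ks_polo_m1, kd_polo, kd_polo_h1;
  double ks_swi5, ks_swi5_m1, kd_swi5;
  double ks_spn, kd_spn;
  double mu, gamma, gamma_cki, gamma_apc, gamma_tem1;
  double om_a_apc_b2, om_i_apc;
  double om_a_cdc15_14, om_i_cdc15, om_i_cdc15_b2;
  double om_a_cdh1, om_a_cdh1_14, om_i_cdh1_e, om_i_cdh1_n3, om_i_cdh1_n2,
         om_i_cdh1_b5, om_i_cdh1_b2;
  double om_p_cki_n3, om_p_cki_k2, om_p_cki_n2, om_p_cki_b5, om_p_cki_b2,
         om_dp_cki, om_dp_cki_14;
  double om_a_mad2, om_i_mad2;
  double om_a_mcm1_b2, om_i_mcm1;
  double om_p_net1_b2, om_p_net1_en, om_p_net1_15, om_dp_net1, om_dp_net1_14,
         om_dp_net1_px;
  double om_a_polo_b2, om_i_polo;
  double om_a_ppx, om_i_ppx_p1;
  double om_p_sbf_b2, om_dp_sbf;
  double om_a_swi5_14, om_i_swi5_b2;
  double om_a_tem1_lo, om_i_tem1, om_i_tem1_px;
  double om_p_whi5_n2, om_p_whi5_n3, om_p_whi5_k2, om_p_whi5_b5, om_dp_whi5,
         om_dp_whi5_14;
  double apc_t, cdc14_t, cdc15_t, cdh1_t, esp1_t, mcm1_t, net1_t, ppx_t,
         sbf_t, tem1_t, whi5_t, mad2_t;
  double d_cln3, e_bud_b5, e_bud_n2, e_bud_n3, e_ori_b2, e_ori_b5;
  double j_cln3, j_spn, k_ez, k_ez2, rho_14_net1, sigma, sigma_net1;
  double k_flag, k_tr, k_dm, div_sd, c_vol;
  double mmin[10];
};

static CCParams load_cc(const NumericVector& p) {
  CCParams q;
#define G(f) q.f = p[#f]
  G(ks_bck2); G(kd_bck2); G(ks_bud_e); G(kd_bud);
  G(ks_cdc20); G(ks_cdc20_m1); G(kd_cdc20);
  G(ks_cki); G(ks_cki_swi5); G(kd_cki); G(kd_ckip); G(ks_cki_gal);
  G(ks_clb2); G(ks_clb2_m1); G(kd_clb2); G(kd_clb2_20); G(kd_clb2_20_i); G(kd_clb2_h1);
  G(ks_clb5); G(ks_clb5_bf); G(kd_clb5); G(kd_clb5_20); G(kd_clb5_20_i);
  G(ks_cln2); G(ks_cln2_bf); G(kd_cln2);
  G(ks_cln3); G(kd_cln3);
  G(ks_ori_e); G(kd_ori);
  G(ks_pds1); G(kd_pds1); G(kd_pds1_20); G(kd_pds1_20_i);
  G(ks_polo_m1); G(kd_polo); G(kd_polo_h1);
  G(ks_swi5); G(ks_swi5_m1); G(kd_swi5);
  G(ks_spn); G(kd_spn);
  G(mu); G(gamma); G(gamma_cki); G(gamma_apc); G(gamma_tem1);
  G(om_a_apc_b2); G(om_i_apc);
  G(om_a_cdc15_14); G(om_i_cdc15); G(om_i_cdc15_b2);
  G(om_a_cdh1); G(om_a_cdh1_14); G(om_i_cdh1_e); G(om_i_cdh1_n3); G(om_i_cdh1_n2);
  G(om_i_cdh1_b5); G(om_i_cdh1_b2);
  G(om_p_cki_n3); G(om_p_cki_k2); G(om_p_cki_n2); G(om_p_cki_b5); G(om_p_cki_b2);
  G(om_dp_cki); G(om_dp_cki_14);
  G(om_a_mad2); G(om_i_mad2);
  G(om_a_mcm1_b2); G(om_i_mcm1);
  G(om_p_net1_b2); G(om_p_net1_en); G(om_p_net1_15); G(om_dp_net1); G(om_dp_net1_14);
  G(om_dp_net1_px);
  G(om_a_polo_b2); G(om_i_polo);
  G(om_a_ppx); G(om_i_ppx_p1);
  G(om_p_sbf_b2); G(om_dp_sbf);
  G(om_a_swi5_14); G(om_i_swi5_b2);
  G(om_a_tem1_lo); G(om_i_tem1); G(om_i_tem1_px);
  G(om_p_whi5_n2); G(om_p_whi5_n3); G(om_p_whi5_k2); G(om_p_whi5_b5); G(om_dp_whi5);
  G(om_dp_whi5_14);
  G(apc_t); G(cdc14_t); G(cdc15_t); G(cdh1_t); G(esp1_t); G(mcm1_t); G(net1_t);
  G(ppx_t); G(sbf_t); G(tem1_t); G(whi5_t); G(mad2_t);
  G(d_cln3); G(e_bud_b5); G(e_bud_n2); G(e_bud_n3); G(e_ori_b2); G(e_ori_b5);
  G(j_cln3); G(j_spn); G(k_ez); G(k_ez2); G(rho_14_net1); G(sigma); G(sigma_net1);
  G(k_flag); G(k_tr); G(k_dm); G(div_sd); G(c_vol);
#undef G
  q.mmin[0] = p["mmin_cln3"]; q.mmin[1] = p["mmin_bck2"]; q.mmin[2] = p["mmin_cln2"];
  q.mmin[3] = p["mmin_clb5"]; q.mmin[4] = p["mmin_clb2"]; q.mmin[5] = p["mmin_cki"];
  q.mmin[6] = p["mmin_swi5"]; q.mmin[7] = p["mmin_cdc20"]; q.mmin[8] = p["mmin_pds1"];
  q.mmin[9] = p["mmin_polo"];
  return q;
}

struct Derived {
  double SBF, Clb5, Clb2, Cdc20A, C20APCP, C20APC, Esp1, Cdc14, Swi5A, Mcm1A,
         TemCdc15;
};

// Quasi-steady class-2 activities first (using the previous class-3 values),
// then the class-3 chain in fixed topological order.
static void update_derived(const CCParams& q, const std::vector<double>& x,
                           Derived& D) {
  D.Swi5A = x[iSwi5T] *
    soft_H(q.sigma * (q.om_a_swi5_14 * D.Cdc14 - q.om_i_swi5_b2 * D.Clb2));
  D.Mcm1A = q.mcm1_t *
    soft_H(q.sigma * (q.om_a_mcm1_b2 * D.Clb2 - q.om_i_mcm1));

  D.SBF = std::max(0.0, x[iSBFA] - x[iWhi5A]);
  double tot = x[iClb5T] + x[iClb2T];
  if (tot > 0.0) {
    double excess = tot - x[iCKIT];
    D.Clb5 = std::max(0.0, x[iClb5T] / tot * excess);
    D.Clb2 = std::max(0.0, x[iClb2T] / tot * excess);
  } else { D.Clb5 = 0.0; D.Clb2 = 0.0; }
  D.Cdc20A = std::max(0.0, x[iCdc20T] - x[iMad2A]);
  D.C20APCP = std::min(D.Cdc20A, x[iAPCP]);
  D.C20APC = std::min(D.Cdc20A - D.C20APCP, q.apc_t - x[iAPCP]);
  D.Esp1 = std::max(0.0, q.esp1_t - x[iPds1T]);
  D.Cdc14 = std::max(0.0, q.cdc14_t - q.rho_14_net1 * x[iNet1A]);
  D.TemCdc15 = std::min(x[iTem1A], x[iCdc15A]);
}

struct StepWork {
  double a1[10], b1[10]; // class-1 synthesis (normalized/min) and degradation (1/min)
};

// normalized-concentration derivatives of the dynamic variables
static void cc_rates(const CCParams& q, const std::vector<double>& x,
                     const Derived& D, double Vn, double budna, double spc,
                     std::vector<double>& dx, StepWork& w) {
  w.a1[0] = q.ks_cln3 * q.d_cln3 * Vn / (q.j_cln3 + q.d_cln3 * Vn);
  w.b1[0] = q.kd_cln3;
  w.a1[1] = q.ks_bck2 * Vn;                       w.b1[1] = q.kd_bck2;
  w.a1[2] = q.ks_cln2 + q.ks_cln2_bf * D.SBF;     w.b1[2] = q.kd_cln2;
  w.a1[3] = q.ks_clb5 + q.ks_clb5_bf * D.SBF;
  w.b1[3] = q.kd_clb5 + q.kd_clb5_20 * D.C20APCP + q.kd_clb5_20_i * D.C20APC;
  w.a1[4] = (q.ks_clb2 + q.ks_clb2_m1 * D.Mcm1A) * Vn;
  w.b1[4] = q.kd_clb2 + q.kd_clb2_20 * D.C20APCP + q.kd_clb2_20_i * D.C20APC +
            q.kd_clb2_h1 * x[iCdh1A];
  w.a1[5] = q.ks_cki + q.ks_cki_swi5 * D.Swi5A + q.ks_cki_gal;
  {
    double frac = (x[iCKIT] > 1e-12) ? x[iCKIP] / x[iCKIT] : 0.0;
    if (frac > 1.0) frac = 1.0;
    w.b1[5] = q.kd_cki * (1.0 - frac) + q.kd_ckip * frac;
  }
  w.a1[6] = q.ks_swi5 + q.ks_swi5_m1 * D.Mcm1A;   w.b1[6] = q.kd_swi5;
  w.a1[7] = q.ks_cdc20 + q.ks_cdc20_m1 * D.Mcm1A; w.b1[7] = q.kd_cdc20;
  w.a1[8] = q.ks_pds1;
  w.b1[8] = q.kd_pds1 + q.kd_pds1_20 * D.C20APCP + q.kd_pds1_20_i * D.C20APC;
  w.a1[9] = q.ks_polo_m1 * D.Mcm1A;
  w.b1[9] = q.kd_polo + q.kd_polo_h1 * x[iCdh1A];

  for (int k = 0; k < 10; ++k)
    dx[CL1[k]] = w.a1[k] - w.b1[k] * x[CL1[k]];

  // class-2 (dynamic)
  double W;
  W = q.om_dp_whi5 + q.om_dp_whi5_14 * D.Cdc14 - q.om_p_whi5_n3 * x[iCln3] -
      q.om_p_whi5_k2 * x[iBck2] - q.om_p_whi5_n2 * x[iCln2] -
      q.om_p_whi5_b5 * D.Clb5;
  dx[iWhi5A] = q.gamma * (q.whi5_t * soft_H(q.sigma * W) - x[iWhi5A]);
  W = q.om_dp_sbf - q.om_p_sbf_b2 * D.Clb2;
  dx[iSBFA] = q.gamma * (q.sbf_t * soft_H(q.sigma * W) - x[iSBFA]);
  W = q.om_p_cki_n3 * x[iCln3] + q.om_p_cki_k2 * x[iBck2] +
      q.om_p_cki_n2 * x[iCln2] + q.om_p_cki_b5 * D.Clb5 +
      q.om_p_cki_b2 * D.Clb2 - q.om_dp_cki - q.om_dp_cki_14 * D.Cdc14;
  dx[iCKIP] = q.gamma_cki * (x[iCKIT] * soft_H(q.sigma * W) - x[iCKIP]) -
              q.kd_ckip * x[iCKIP];
  W = q.om_a_cdh1 + q.om_a_cdh1_14 * D.Cdc14 -
      q.om_i_cdh1_e * (q.om_i_cdh1_n3 * x[iCln3] + q.om_i_cdh1_n2 * x[iCln2] +
                       q.om_i_cdh1_b5 * D.Clb5 + q.om_i_cdh1_b2 * D.Clb2);
  dx[iCdh1A] = q.gamma * (q.cdh1_t * soft_H(q.sigma * W) - x[iCdh1A]);
  W = q.om_a_apc_b2 * D.Clb2 - q.om_i_apc;
  dx[iAPCP] = q.gamma_apc * (q.apc_t * soft_H(q.sigma * W) - x[iAPCP]);
  W = q.om_a_mad2 * budna * (1.0 - spc) - q.om_i_mad2;
  dx[iMad2A] = q.gamma * (q.mad2_t * soft_H(q.sigma * W) - x[iMad2A]);
  W = q.om_a_ppx - q.om_i_ppx_p1 * D.Esp1;
  dx[iPPXA] = q.gamma * (q.ppx_t * soft_H(q.sigma * W) - x[iPPXA]);
  W = q.om_dp_net1 + q.om_dp_net1_14 * D.Cdc14 + q.om_dp_net1_px * x[iPPXA] -
      q.om_p_net1_b2 * D.Clb2 - q.om_p_net1_en * D.TemCdc15 -
      q.om_p_net1_15 * (x[iCdc15A] - D.TemCdc15);
  dx[iNet1A] = q.gamma * (q.net1_t * soft_H(q.sigma_net1 * W) - x[iNet1A]);
  W = q.om_a_polo_b2 * D.Clb2 - q.om_i_polo;
  dx[iPoloA] = q.gamma * (x[iPoloT] * soft_H(q.sigma * W) - x[iPoloA]);
  W = q.om_a_tem1_lo * x[iPoloA] - q.om_i_tem1 - q.om_i_tem1_px * x[iPPXA];
  dx[iTem1A] = q.gamma_tem1 * (q.tem1_t * soft_H(q.sigma * W) - x[iTem1A]);
  W = q.om_a_cdc15_14 * D.Cdc14 - q.om_i_cdc15 - q.om_i_cdc15_b2 * D.Clb2;
  dx[iCdc15A] = q.gamma * (q.cdc15_t * soft_H(q.sigma * W) - x[iCdc15A]);

  // progress variables
  dx[iBUD] = q.ks_bud_e * (q.e_bud_n3 * x[iCln3] + q.e_bud_n2 * x[iCln2] +
                           q.e_bud_b5 * D.Clb5) - q.kd_bud * x[iBUD];
  dx[iORI] = q.ks_ori_e * (q.e_ori_b5 * D.Clb5 + q.e_ori_b2 * D.Clb2) -
             q.kd_ori * x[iORI];
  dx[iSPN] = q.ks_spn * heav(D.Clb2 - q.j_spn) - q.kd_spn * x[iSPN];
}

// simulation modes
enum { MODE_DET = 0, MODE_FULL = 1, MODE_NO_MRNA = 2, MODE_EXTRINSIC = 3 };

struct CellBuf { // per-cycle ring buffer for Start backfill and age sampling
  std::vector<double> t, sbf, vn;
  std::vector<std::array<double, 10>> n1; // class-1 molecule numbers
  void clear() { t.clear(); sbf.clear(); vn.clear(); n1.clear(); }
};

struct CellRec {
  double gen, role, t_birth, v_birth, t_start, t_bud, t_ori, t_spn, t_div,
         v_div, divided, sbf_max, theta, v_sample, n_sample[10];
};

static double interp_start_time(const CellBuf& buf, double sbf_max) {
  double thr = 0.5 * sbf_max;
  for (size_t i = 0; i < buf.t.size(); ++i) {
    if (buf.sbf[i] >= thr) {
      if (i == 0) return buf.t[0];
      double f = (thr - buf.sbf[i - 1]) / (buf.sbf[i] - buf.sbf[i - 1]);
      return buf.t[i - 1] + f * (buf.t[i] - buf.t[i - 1]);
    }
  }
  return NA_REAL;
}

static void sample_age(const CellBuf& buf, double ts, CellRec& r) {
  size_t n = buf.t.size();
  if (n == 0) { r.v_sample = NA_REAL; for (int k = 0; k < 10; ++k) r.n_sample[k] = NA_REAL; return; }
  size_t i = 0;
  while (i + 1 < n && buf.t[i + 1] < ts) ++i;
  if (i + 1 >= n) {
    r.v_sample = buf.vn[n - 1];
    for (int k = 0; k < 10; ++k) r.n_sample[k] = buf.n1[n - 1][k];
    return;
  }
  double f = (ts - buf.t[i]) / std::max(1e-12, buf.t[i + 1] - buf.t[i]);
  r.v_sample = buf.vn[i] + f * (buf.vn[i + 1] - buf.vn[i]);
  for (int k = 0; k < 10; ++k)
    r.n_sample[k] = buf.n1[i][k] + f * (buf.n1[i + 1][k] - buf.n1[i][k]);
}

static uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Sim {
  CCParams q;
  int mode;
  double dt, sqdt;
  std::vector<double> x, dx;
  Derived D;
  double Vn, t;
  double budna, spc, oriflag, armed;
  long clamp_events = 0, steps = 0;
  std::mt19937_64 rng;
  std::normal_distribution<double> nd{0.0, 1.0};
  std::uniform_real_distribution<double> uni{0.0, 1.0};
  StepWork w;

  void init_derived() {
    D = Derived();
    D.Cdc14 = std::max(0.0, q.cdc14_t - q.rho_14_net1 * x[iNet1A]);
    double tot = x[iClb5T] + x[iClb2T];
    double excess = tot - x[iCKIT];
    D.Clb5 = tot > 0 ? std::max(0.0, x[iClb5T] / tot * excess) : 0.0;
    D.Clb2 = tot > 0 ? std::max(0.0, x[iClb2T] / tot * excess) : 0.0;
    update_derived(q, x, D);
  }

  // one Euler step; stochastic class-1 propagation in molecule numbers
  void step() {
    cc_rates(q, x, D, Vn, budna, spc, dx, w);
    bool intrinsic = (mode == MODE_FULL || mode == MODE_NO_MRNA);
    double Vfl = Vn * q.c_vol, phi = 0.6 * Vfl;
    double phi_new = phi * std::exp(q.mu * dt);
    if (intrinsic) {
      for (int k = 0; k < 10; ++k) {
        int idx = CL1[k];
        double N = x[idx] * CS[k] * phi;
        double A = phi * CS[k] * w.a1[k] + q.mu * N;
        double B = w.b1[k];
        double dN = (A - B * N) * dt;
        double amp = A + B * N;
        if (amp > 0.0) dN += std::sqrt(amp) * nd(rng) * sqdt;
        if (mode == MODE_FULL) {
          double mbar = A / (q.k_tr * Vfl);
          double M = 1.0 / (mbar + q.mmin[k]);
          dN += N * std::sqrt(2.0 * B) * std::sqrt(M * B / (B + q.k_dm)) *
                nd(rng) * sqdt;
        }
        double Nn = N + dN;
        if (Nn < 0.0) { Nn = 0.0; ++clamp_events; }
        x[idx] = Nn / (CS[k] * phi_new);
      }
    } else {
      for (int k = 0; k < 10; ++k) {
        int idx = CL1[k];
        x[idx] += dx[idx] * dt;
        if (x[idx] < 0.0) { x[idx] = 0.0; ++clamp_events; }
      }
    }
    // class-2 and progress variables (always deterministic)
    static const int OTH[14] = { iWhi5A, iSBFA, iBUD, iCKIP, iORI, iCdh1A,
                                 iAPCP, iMad2A, iSPN, iPPXA, iNet1A, iPoloA,
                                 iTem1A, iCdc15A };
    for (int k = 0; k < 14; ++k) {
      int idx = OTH[k];
      x[idx] += dx[idx] * dt;
      if (x[idx] < 0.0) x[idx] = 0.0;
    }
    // clamp class-2 to their totals
    if (x[iWhi5A] > q.whi5_t) x[iWhi5A] = q.whi5_t;
    if (x[iSBFA] > q.sbf_t) x[iSBFA] = q.sbf_t;
    if (x[iCKIP] > x[iCKIT]) x[iCKIP] = x[iCKIT];
    if (x[iCdh1A] > q.cdh1_t) x[iCdh1A] = q.cdh1_t;
    if (x[iAPCP] > q.apc_t) x[iAPCP] = q.apc_t;
    if (x[iMad2A] > q.mad2_t) x[iMad2A] = q.mad2_t;
    if (x[iPPXA] > q.ppx_t) x[iPPXA] = q.ppx_t;
    if (x[iNet1A] > q.net1_t) x[iNet1A] = q.net1_t;
    if (x[iPoloA] > x[iPoloT]) x[iPoloA] = x[iPoloT];
    if (x[iTem1A] > q.tem1_t) x[iTem1A] = q.tem1_t;
    if (x[iCdc15A] > q.cdc15_t) x[iCdc15A] = q.cdc15_t;

    Vn *= std::exp(q.mu * dt); // exact exponential growth
    t += dt;
    ++steps;
    update_derived(q, x, D);
    for (int k = 0; k < NDYN; ++k)
      if (!std::isfinite(x[k])) stop("non-finite state at t = %f", t);
  }

  double draw_fraction(double fmean) {
    if (mode == MODE_DET || q.div_sd <= 0.0) return fmean;
    for (int tries = 0; tries < 100; ++tries) {
      double f = fmean + q.div_sd * nd(rng);
      if (f > 0.05 && f < 0.95) return f;
    }
    return fmean;
  }
};

// Lineage simulation following one branch across divisions.
// follow: 2 = daughter, 1 = mother. Returns records + optional trajectory.
// [[Rcpp::export]]
List cc_lineage_cpp(NumericVector params, NumericVector init, double vn0,
                    int follow, int n_divisions, double horizon,
                    double t_max, double dt, int mode, int seed,
                    bool record_traj, double record_dt, double buf_dt,
                    double f_mean) {
  Sim S;
  S.q = load_cc(params);
  S.mode = mode;
  S.dt = dt; S.sqdt = std::sqrt(dt);
  S.x.assign(init.begin(), init.end());
  S.dx.assign(NDYN, 0.0);
  if ((int)S.x.size() != NDYN) stop("init must have length %d", NDYN);
  S.Vn = vn0; S.t = 0.0;
  S.budna = 0.0; S.spc = 0.0; S.oriflag = 1.0; S.armed = 0.0;
  S.rng.seed(splitmix64(static_cast<uint64_t>(seed)));
  S.init_derived();

  const long buf_every = std::max(1L, (long)std::round(buf_dt / dt));
  const long rec_every = std::max(1L, (long)std::round(record_dt / dt));

  std::vector<CellRec> recs;
  CellBuf buf;
  std::vector<double> traj; // flattened rows
  const int TRAJ_NC = 2 + NDYN + 11 + 3;

  auto push_buf = [&]() {
    buf.t.push_back(S.t);
    buf.sbf.push_back(S.D.SBF);
    buf.vn.push_back(S.Vn);
    std::array<double, 10> nn;
    double phi = 0.6 * S.Vn * S.q.c_vol;
    for (int k = 0; k < 10; ++k) nn[k] = S.x[CL1[k]] * CS[k] * phi;
    buf.n1.push_back(nn);
  };
  auto push_traj = [&]() {
    traj.push_back(S.t); traj.push_back(S.Vn);
    for (int k = 0; k < NDYN; ++k) traj.push_back(S.x[k]);
    traj.push_back(S.D.SBF); traj.push_back(S.D.Clb5); traj.push_back(S.D.Clb2);
    traj.push_back(S.D.Cdc20A); traj.push_back(S.D.C20APCP); traj.push_back(S.D.C20APC);
    traj.push_back(S.D.Esp1); traj.push_back(S.D.Cdc14); traj.push_back(S.D.Swi5A);
    traj.push_back(S.D.Mcm1A); traj.push_back(S.D.TemCdc15);
    traj.push_back(S.budna); traj.push_back(S.spc); traj.push_back(S.oriflag);
  };

  CellRec cur;
  auto new_cell = [&](double gen, double role) {
    cur = CellRec();
    cur.gen = gen; cur.role = role;
    cur.t_birth = S.t; cur.v_birth = S.Vn;
    cur.t_start = NA_REAL; cur.t_bud = NA_REAL; cur.t_ori = NA_REAL;
    cur.t_spn = NA_REAL; cur.t_div = NA_REAL; cur.v_div = NA_REAL;
    cur.divided = 0.0; cur.sbf_max = 0.0; cur.theta = NA_REAL;
    cur.v_sample = NA_REAL;
    for (int k = 0; k < 10; ++k) cur.n_sample[k] = NA_REAL;
    buf.clear();
    push_buf();
  };
  new_cell(0.0, follow == 1 ? 1.0 : 2.0);

  int divisions = 0;
  bool stochastic_gate = (mode != MODE_DET);

  while (divisions < n_divisions && S.t < t_max) {
    double clb2_prev = S.D.Clb2, clb52_prev = S.D.Clb2 + S.D.Clb5;
    double bud_prev = S.x[iBUD], ori_prev = S.x[iORI], spn_prev = S.x[iSPN];
    double t_prev = S.t;
    S.step();
    if (S.steps % buf_every == 0) push_buf();
    if (record_traj && S.steps % rec_every == 0) push_traj();

    auto xing = [&](double a, double b, double thr) {
      return t_prev + S.dt * (thr - a) / (b - a);
    };
    // Rule 1: bud emergence
    if (ISNA(cur.t_bud) && bud_prev < 1.0 && S.x[iBUD] >= 1.0)
      cur.t_bud = xing(bud_prev, S.x[iBUD], 1.0);
    // Rule 2: onset of DNA synthesis (licensed origins only)
    if (S.oriflag == 1.0 && ori_prev < 1.0 && S.x[iORI] >= 1.0) {
      if (ISNA(cur.t_ori)) cur.t_ori = xing(ori_prev, S.x[iORI], 1.0);
      S.oriflag = 0.0; S.budna = 1.0;
    }
    // Rule 3: spindle assembly complete
    if (S.spc == 0.0 && spn_prev < 1.0 && S.x[iSPN] >= 1.0) {
      if (ISNA(cur.t_spn)) cur.t_spn = xing(spn_prev, S.x[iSPN], 1.0);
      S.spc = 1.0;
    }
    // Rule 5: origin relicensing
    if (clb52_prev > S.q.k_ez2 && S.D.Clb2 + S.D.Clb5 <= S.q.k_ez2) {
      S.x[iORI] = 0.0; S.oriflag = 1.0;
    }
    // division gate arming (stochastic hysteresis): armed whenever Clb2
    // has been at or above K_flag since the last division
    if (stochastic_gate && (clb2_prev >= S.q.k_flag || S.D.Clb2 >= S.q.k_flag))
      S.armed = 1.0;
    // Rule 4: division
    bool downcross = (clb2_prev > S.q.k_ez && S.D.Clb2 <= S.q.k_ez);
    bool may_divide = stochastic_gate ? (S.armed == 1.0) : true;
    if (downcross && may_divide) {
      double tdiv = xing(clb2_prev, S.D.Clb2, S.q.k_ez);
      cur.t_div = tdiv; cur.v_div = S.Vn; cur.divided = 1.0;
      cur.sbf_max = 0.0;
      for (double v : buf.sbf) cur.sbf_max = std::max(cur.sbf_max, v);
      cur.t_start = interp_start_time(buf, cur.sbf_max);
      double u = S.uni(S.rng);
      cur.theta = 1.0 - std::log2(1.0 + u);
      sample_age(buf, cur.t_birth + (tdiv - cur.t_birth) * cur.theta, cur);
      recs.push_back(cur);

      double f = S.draw_fraction(f_mean);
      S.Vn *= (follow == 2) ? f : (1.0 - f);
      S.x[iBUD] = 0.0; S.x[iSPN] = 0.0;
      S.budna = 0.0; S.spc = 0.0; S.armed = 0.0;
      ++divisions;
      // per-cell independent stream
      S.rng.seed(splitmix64(static_cast<uint64_t>(seed) +
                            0x51ed2701ULL * (uint64_t)(divisions + 1)));
      new_cell(divisions, follow == 1 ? 1.0 : 2.0);
    }
    // arrest cutoff for the current cell
    if (S.t - cur.t_birth > horizon) break;
  }

  // finalize an arrested / unfinished cell
  if (cur.divided == 0.0) {
    cur.sbf_max = 0.0;
    for (double v : buf.sbf) cur.sbf_max = std::max(cur.sbf_max, v);
    cur.t_start = interp_start_time(buf, cur.sbf_max);
    recs.push_back(cur);
  }

  const int NREC_C = 24;
  NumericMatrix R((int)recs.size(), NREC_C);
  for (size_t i = 0; i < recs.size(); ++i) {
    const CellRec& r = recs[i];
    double row[NREC_C] = { r.gen, r.role, r.t_birth, r.v_birth, r.t_start,
                           r.t_bud, r.t_ori, r.t_spn, r.t_div, r.v_div,
                           r.divided, r.sbf_max, r.theta, r.v_sample,
                           r.n_sample[0], r.n_sample[1], r.n_sample[2],
                           r.n_sample[3], r.n_sample[4], r.n_sample[5],
                           r.n_sample[6], r.n_sample[7], r.n_sample[8],
                           r.n_sample[9] };
    for (int c = 0; c < NREC_C; ++c) R((int)i, c) = row[c];
  }

  List out = List::create(
    _["records"] = R,
    _["clamp_frac"] = (S.steps > 0) ? (double)S.clamp_events / (10.0 * S.steps) : 0.0,
    _["final_state"] = NumericVector(S.x.begin(), S.x.end()),
    _["final_vn"] = S.Vn, _["final_t"] = S.t);
  if (record_traj) {
    int nr = (int)(traj.size() / TRAJ_NC);
    NumericMatrix M(nr, TRAJ_NC);
    for (int i = 0; i < nr; ++i)
      for (int c = 0; c < TRAJ_NC; ++c) M(i, c) = traj[(size_t)i * TRAJ_NC + c];
    out["trajectory"] = M;
  }
  return out;
}

// Pedigree simulation: every division spawns both mother and daughter, each
// continued as an independent simulation from the division state with its own
// RNG stream (so population size does not perturb individual cells). Random
// thinning keeps the live population below `cap`, with weights scaled to
// keep weighted counts unbiased. Returns full cell records (same layout as
// the lineage driver) plus a weight column.
// [[Rcpp::export]]
NumericMatrix cc_pedigree_cpp(NumericVector params, NumericVector init,
                              double vn0, int n_founders, int max_gen,
                              double horizon, int cap, double dt, int mode,
                              int seed, double f_mean, double cell_horizon) {
  CCParams q = load_cc(params);
  struct Cell {
    std::vector<double> x; double vn, t_birth, weight, oriflag;
    int gen, role; uint64_t id;
  };
  std::vector<Cell> queue;
  uint64_t next_id = 1;
  for (int i = 0; i < n_founders; ++i) {
    Cell c; c.x.assign(init.begin(), init.end()); c.vn = vn0; c.t_birth = 0.0;
    c.weight = 1.0; c.oriflag = 1.0; c.gen = 0; c.role = 2; c.id = next_id++;
    queue.push_back(std::move(c));
  }
  std::mt19937_64 thin_rng(splitmix64((uint64_t)seed ^ 0xabcdef12ULL));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  const int NREC_C = 25; // 24 record fields + weight
  std::vector<std::array<double, 25>> rows;
  CellBuf buf;
  const long buf_every = std::max(1L, (long)std::round(0.1 / dt));
  bool stochastic_gate = (mode != MODE_DET);

  while (!queue.empty()) {
    if ((int)queue.size() > cap) {
      double keep = (double)cap / (double)queue.size();
      std::vector<Cell> kept;
      for (auto& c : queue)
        if (U(thin_rng) < keep) { c.weight /= keep; kept.push_back(std::move(c)); }
      queue = std::move(kept);
      if (queue.empty()) break;
    }
    Cell c = std::move(queue.back());
    queue.pop_back();

    Sim S;
    S.q = q; S.mode = mode; S.dt = dt; S.sqdt = std::sqrt(dt);
    S.x = c.x; S.dx.assign(NDYN, 0.0);
    S.Vn = c.vn; S.t = c.t_birth;
    S.budna = 0.0; S.spc = 0.0; S.oriflag = c.oriflag; S.armed = 0.0;
    S.rng.seed(splitmix64((uint64_t)seed + 0x9e3779b9ULL * c.id));
    S.init_derived();

    CellRec r = CellRec();
    r.gen = c.gen; r.role = c.role;
    r.t_birth = c.t_birth; r.v_birth = c.vn;
    r.t_start = NA_REAL; r.t_bud = NA_REAL; r.t_ori = NA_REAL;
    r.t_spn = NA_REAL; r.t_div = NA_REAL; r.v_div = NA_REAL;
    r.divided = 0.0; r.sbf_max = 0.0; r.theta = NA_REAL;
    r.v_sample = NA_REAL;
    for (int k = 0; k < 10; ++k) r.n_sample[k] = NA_REAL;

    buf.clear();
    auto push_buf = [&]() {
      buf.t.push_back(S.t);
      buf.sbf.push_back(S.D.SBF);
      buf.vn.push_back(S.Vn);
      std::array<double, 10> nn;
      double phi = 0.6 * S.Vn * S.q.c_vol;
      for (int k = 0; k < 10; ++k) nn[k] = S.x[CL1[k]] * CS[k] * phi;
      buf.n1.push_back(nn);
    };
    push_buf();

    while (S.t < horizon && S.t - c.t_birth < cell_horizon) {
      double clb2_prev = S.D.Clb2, clb52_prev = S.D.Clb2 + S.D.Clb5;
      double bud_prev = S.x[iBUD], ori_prev = S.x[iORI], spn_prev = S.x[iSPN];
      double t_prev = S.t;
      S.step();
      if (S.steps % buf_every == 0) push_buf();
      auto xing = [&](double a, double b, double thr) {
        return t_prev + dt * (thr - a) / (b - a);
      };
      if (ISNA(r.t_bud) && bud_prev < 1.0 && S.x[iBUD] >= 1.0)
        r.t_bud = xing(bud_prev, S.x[iBUD], 1.0);
      if (S.oriflag == 1.0 && ori_prev < 1.0 && S.x[iORI] >= 1.0) {
        if (ISNA(r.t_ori)) r.t_ori = xing(ori_prev, S.x[iORI], 1.0);
        S.oriflag = 0.0; S.budna = 1.0;
      }
      if (S.spc == 0.0 && spn_prev < 1.0 && S.x[iSPN] >= 1.0) {
        if (ISNA(r.t_spn)) r.t_spn = xing(spn_prev, S.x[iSPN], 1.0);
        S.spc = 1.0;
      }
      if (clb52_prev > q.k_ez2 && S.D.Clb2 + S.D.Clb5 <= q.k_ez2) {
        S.x[iORI] = 0.0; S.oriflag = 1.0;
      }
      if (stochastic_gate && (clb2_prev >= q.k_flag || S.D.Clb2 >= q.k_flag))
        S.armed = 1.0;
      bool downcross = (clb2_prev > q.k_ez && S.D.Clb2 <= q.k_ez);
      bool may_divide = stochastic_gate ? (S.armed == 1.0) : true;
      if (downcross && may_divide) {
        r.t_div = xing(clb2_prev, S.D.Clb2, q.k_ez);
        r.v_div = S.Vn; r.divided = 1.0;
        break;
      }
    }

    r.sbf_max = 0.0;
    for (double v : buf.sbf) r.sbf_max = std::max(r.sbf_max, v);
    r.t_start = interp_start_time(buf, r.sbf_max);
    if (r.divided == 1.0) {
      double u = S.uni(S.rng);
      r.theta = 1.0 - std::log2(1.0 + u);
      sample_age(buf, r.t_birth + (r.t_div - r.t_birth) * r.theta, r);
    }
    rows.push_back({ r.gen, r.role, r.t_birth, r.v_birth, r.t_start, r.t_bud,
                     r.t_ori, r.t_spn, r.t_div, r.v_div, r.divided, r.sbf_max,
                     r.theta, r.v_sample, r.n_sample[0], r.n_sample[1],
                     r.n_sample[2], r.n_sample[3], r.n_sample[4],
                     r.n_sample[5], r.n_sample[6], r.n_sample[7],
                     r.n_sample[8], r.n_sample[9], c.weight });

    if (r.divided == 1.0 && r.t_div < horizon && c.gen + 1 <= max_gen) {
      double f = S.draw_fraction(f_mean);
      Cell d, m;
      d.x = S.x; d.vn = S.Vn * f; d.t_birth = r.t_div; d.weight = c.weight;
      d.oriflag = S.oriflag; d.gen = c.gen + 1; d.role = 2; d.id = next_id++;
      m.x = S.x; m.vn = S.Vn * (1.0 - f); m.t_birth = r.t_div;
      m.weight = c.weight; m.oriflag = S.oriflag;
      m.gen = c.gen + 1; m.role = 1; m.id = next_id++;
      d.x[iBUD] = 0.0; d.x[iSPN] = 0.0;
      m.x[iBUD] = 0.0; m.x[iSPN] = 0.0;
      queue.push_back(std::move(d));
      queue.push_back(std::move(m));
    }
  }
  NumericMatrix M((int)rows.size(), NREC_C);
  for (size_t i = 0; i < rows.size(); ++i)
    for (int c2 = 0; c2 < NREC_C; ++c2) M((int)i, c2) = rows[i][c2];
  return M;
}

// Single-segment run without division (for steady-state scans / unit tests):
// integrates to t_end at fixed or growing volume; returns trajectory.
// [[Rcpp::export]]
NumericMatrix cc_segment_cpp(NumericVector params, NumericVector init,
                             double vn0, double t_end, double dt,
                             double record_dt, bool fixed_v, int mode,
                             int seed, double budna, double spc) {
  Sim S;
  S.q = load_cc(params);
  if (fixed_v) S.q.mu = 0.0;
  S.mode = mode; S.dt = dt; S.sqdt = std::sqrt(dt);
  S.x.assign(init.begin(), init.end());
  S.dx.assign(NDYN, 0.0);
  S.Vn = vn0; S.t = 0.0;
  S.budna = budna; S.spc = spc; S.oriflag = 1.0; S.armed = 0.0;
  S.rng.seed(splitmix64((uint64_t)seed));
  S.init_derived();
  const long rec_every = std::max(1L, (long)std::round(record_dt / dt));
  const long nsteps = (long)std::ceil(t_end / dt);
  const long nrec = nsteps / rec_every + 1;
  const int NC = 2 + NDYN + 11;
  NumericMatrix M(nrec, NC);
  long irow = 0;
  for (long s = 0; s <= nsteps; ++s) {
    if (s % rec_every == 0 && irow < nrec) {
      M(irow, 0) = S.t; M(irow, 1) = S.Vn;
      for (int k = 0; k < NDYN; ++k) M(irow, 2 + k) = S.x[k];
      int c = 2 + NDYN;
      M(irow, c++) = S.D.SBF; M(irow, c++) = S.D.Clb5; M(irow, c++) = S.D.Clb2;
      M(irow, c++) = S.D.Cdc20A; M(irow, c++) = S.D.C20APCP; M(irow, c++) = S.D.C20APC;
      M(irow, c++) = S.D.Esp1; M(irow, c++) = S.D.Cdc14; M(irow, c++) = S.D.Swi5A;
      M(irow, c++) = S.D.Mcm1A; M(irow, c++) = S.D.TemCdc15;
      ++irow;
    }
    if (s == nsteps) break;
    S.step();
  }
  return M;
}
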