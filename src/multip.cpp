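// Multisite-phosphorylation (MultiP) reference model of the Start transition:
// mass-action network with explicit mRNAs, seven Whi5 phospho-forms (sequential,
// distributive), SBF:Whi5P_i complexes (i = 0..2, dissociation rate 0; the
// triply phosphorylated complex releases SBF immediately) and gene switching
// G_i + SBF <-> G_a for the ClbS gene.  Deterministic Euler and Gillespie SSA.
//
// State order (19): m_n3, m_bS, m_i5, m_hi5, Cln3, ClbS, Hi5,
//                   W0..W6 (free Whi5, 7), C0, C1, C2, SBF, Ga

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

struct MpParams {
  double ka_g, kd_g, kd_bf, kd_bS, kd_hi5, kd_i5;
  double kd_mbS, kd_mhi5, kd_mi5, kd_mn3, kd_n3;
  double ks_bf, ks_bS, ks_hi5, ks_i5;
  double ks_mbS, ks_mhi5, ks_mi5, ks_mn3, ks_n3;
  double mu;
  double kp_n3, kp_bS, kdp, ka_cmp; // the four rate constants beyond the SCM set
};

static MpParams load_mp(const NumericVector& p) {
  MpParams q;
  q.ka_g = p["ka_g"]; q.kd_g = p["kd_g"]; q.kd_bf = p["kd_bf"];
  q.kd_bS = p["kd_bS"]; q.kd_hi5 = p["kd_hi5"]; q.kd_i5 = p["kd_i5"];
  q.kd_mbS = p["kd_mbS"]; q.kd_mhi5 = p["kd_mhi5"]; q.kd_mi5 = p["kd_mi5"];
  q.kd_mn3 = p["kd_mn3"]; q.kd_n3 = p["kd_n3"];
  q.ks_bf = p["ks_bf"]; q.ks_bS = p["ks_bS"]; q.ks_hi5 = p["ks_hi5"];
  q.ks_i5 = p["ks_i5"]; q.ks_mbS = p["ks_mbS"]; q.ks_mhi5 = p["ks_mhi5"];
  q.ks_mi5 = p["ks_mi5"]; q.ks_mn3 = p["ks_mn3"]; q.ks_n3 = p["ks_n3"];
  q.mu = p["mu"];
  q.kp_n3 = p["kp_n3"]; q.kp_bS = p["kp_bS"]; q.kdp = p["kdp"];
  q.ka_cmp = p["ka_cmp"];
  return q;
}

static void mp_deriv(const MpParams& q, const std::vector<double>& x, double V,
                     std::vector<double>& dx) {
  const double m_n3 = x[0], m_bS = x[1], m_i5 = x[2], m_hi5 = x[3];
  const double Cln3 = x[4], ClbS = x[5], Hi5 = x[6];
  const double* W = &x[7];   // W[0..6]
  const double C0 = x[14], C1 = x[15], C2 = x[16];
  const double SBF = x[17], Ga = x[18];

  const double kp = (q.kp_n3 * Cln3 + q.kp_bS * ClbS) / V; // per-site phosphorylation
  const double kd = q.kdp * Hi5 / V;                       // per-site dephosphorylation
  const double kac = q.ka_cmp / V;

  std::fill(dx.begin(), dx.end(), 0.0);
  dx[0] = q.ks_mn3 - q.kd_mn3 * m_n3;
  dx[1] = q.ks_mbS * Ga - q.kd_mbS * m_bS;
  dx[2] = q.ks_mi5 - q.kd_mi5 * m_i5;
  dx[3] = q.ks_mhi5 - q.kd_mhi5 * m_hi5;
  dx[4] = q.ks_n3 * V * V * m_n3 - q.kd_n3 * Cln3;
  dx[5] = q.ks_bS * V * m_bS - q.kd_bS * ClbS;
  dx[6] = q.ks_hi5 * V * m_hi5 - q.kd_hi5 * Hi5;

  // free Whi5 chain: synthesis into W0; degradation of every form;
  // phosphorylation W_i -> W_{i+1} (i<6); dephosphorylation W_i -> W_{i-1} (i>0)
  dx[7] += q.ks_i5 * V * m_i5;
  for (int i = 0; i < 7; ++i) {
    dx[7 + i] -= q.kd_i5 * W[i];
    if (i < 6) { dx[7 + i] -= kp * W[i]; dx[8 + i] += kp * W[i]; }
    if (i > 0) { dx[7 + i] -= kd * W[i]; dx[6 + i] += kd * W[i]; }
  }
  // complex formation SBF + W_i -> C_i (i = 0..2), no dissociation
  for (int i = 0; i < 3; ++i) {
    double rate = kac * SBF * W[i];
    dx[7 + i] -= rate; dx[14 + i] += rate; dx[17] -= rate;
  }
  // complex phosphorylation C0->C1->C2->(W3 + SBF); dephosphorylation C2->C1->C0
  dx[14] += -kp * C0 + kd * C1;
  dx[15] += kp * C0 - kp * C1 - kd * C1 + kd * C2;
  dx[16] += kp * C1 - kp * C2 - kd * C2;
  dx[10] += kp * C2;          // W3 released
  dx[17] += kp * C2;          // SBF released
  // degradation of complexes: Whi5 moiety decay releases SBF, SBF moiety decay
  // releases the Whi5 form (keeps SBF_T and Whi5_T kinetics uniform)
  const double Cc[3] = {C0, C1, C2};
  for (int i = 0; i < 3; ++i) {
    dx[14 + i] -= (q.kd_i5 + q.kd_bf) * Cc[i];
    dx[17] += q.kd_i5 * Cc[i];
    dx[7 + i] += q.kd_bf * Cc[i];
  }
  // free SBF synthesis/degradation
  dx[17] += q.ks_bf * V - q.kd_bf * SBF;
  // gene activity (single copy, continuous fraction in the deterministic model)
  dx[18] = (q.ka_g / V) * SBF * (1.0 - Ga) - q.kd_g * Ga;
}

// [[Rcpp::export]]
NumericMatrix multip_sim_cpp(NumericVector params, NumericVector init,
                             double v0, double tend, double dt,
                             double record_dt, bool fixed_v) {
  MpParams q = load_mp(params);
  if (init.size() != 19) stop("init must have length 19");
  std::vector<double> x(init.begin(), init.end()), dx(19);
  double V = v0;
  const long nsteps = static_cast<long>(std::ceil(tend / dt));
  const long rec_every = std::max(1L, static_cast<long>(std::round(record_dt / dt)));
  const long nrec = nsteps / rec_every + 1;
  NumericMatrix out(nrec, 21);
  long irow = 0;
  for (long step = 0; step <= nsteps; ++step) {
    if (step % rec_every == 0 && irow < nrec) {
      out(irow, 0) = step * dt; out(irow, 1) = V;
      for (int k = 0; k < 19; ++k) out(irow, 2 + k) = x[k];
      ++irow;
    }
    if (step == nsteps) break;
    mp_deriv(q, x, V, dx);
    for (int k = 0; k < 19; ++k) {
      x[k] += dx[k] * dt;
      if (x[k] < 0.0) x[k] = 0.0;
      if (!std::isfinite(x[k])) stop("non-finite state at t = %f", step * dt);
    }
    if (x[18] > 1.0) x[18] = 1.0;
    if (!fixed_v) V *= std::exp(q.mu * dt);
  }
  return out;
}

// Gillespie SSA for the same network (integer copy numbers, gene 0/1).
// Volume is updated quasi-statically at each firing. Records on a fixed grid.
// [[Rcpp::export]]
NumericMatrix multip_ssa_cpp(NumericVector params, NumericVector init,
                             double v0, double tend, double record_dt,
                             bool fixed_v, int seed) {
  MpParams q = load_mp(params);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> x(init.begin(), init.end());
  for (auto& v : x) v = std::round(v);
  double t = 0.0;
  const long nrec = static_cast<long>(std::floor(tend / record_dt)) + 1;
  NumericMatrix out(nrec, 21);
  long irow = 0;
  double tnext = 0.0;

  std::vector<double> a; a.reserve(64);
  std::vector<std::pair<int,int>> moves; // applied as list of (index, delta)

  while (true) {
    double V = fixed_v ? v0 : v0 * std::exp(q.mu * t);
    const double kp = (q.kp_n3 * x[4] + q.kp_bS * x[5]) / V;
    const double kd = q.kdp * x[6] / V;
    const double kac = q.ka_cmp / V;

    // build propensities; reaction effects encoded inline below
    a.clear();
    a.push_back(q.ks_mn3);              // 0 m_n3 +
    a.push_back(q.kd_mn3 * x[0]);       // 1 m_n3 -
    a.push_back(q.ks_mbS * x[18]);      // 2 m_bS + (gene active)
    a.push_back(q.kd_mbS * x[1]);       // 3 m_bS -
    a.push_back(q.ks_mi5);              // 4 m_i5 +
    a.push_back(q.kd_mi5 * x[2]);       // 5 m_i5 -
    a.push_back(q.ks_mhi5);             // 6 m_hi5 +
    a.push_back(q.kd_mhi5 * x[3]);      // 7 m_hi5 -
    a.push_back(q.ks_n3 * V * V * x[0]); // 8 Cln3 +
    a.push_back(q.kd_n3 * x[4]);        // 9 Cln3 -
    a.push_back(q.ks_bS * V * x[1]);    // 10 ClbS +
    a.push_back(q.kd_bS * x[5]);        // 11 ClbS -
    a.push_back(q.ks_hi5 * V * x[3]);   // 12 Hi5 +
    a.push_back(q.kd_hi5 * x[6]);       // 13 Hi5 -
    a.push_back(q.ks_i5 * V * x[2]);    // 14 W0 +
    for (int i = 0; i < 7; ++i) a.push_back(q.kd_i5 * x[7 + i]);   // 15..21 Wi -
    for (int i = 0; i < 6; ++i) a.push_back(kp * x[7 + i]);        // 22..27 Wi -> Wi+1
    for (int i = 1; i < 7; ++i) a.push_back(kd * x[7 + i]);        // 28..33 Wi -> Wi-1
    for (int i = 0; i < 3; ++i) a.push_back(kac * x[17] * x[7 + i]); // 34..36 SBF+Wi->Ci
    a.push_back(kp * x[14]);            // 37 C0 -> C1
    a.push_back(kp * x[15]);            // 38 C1 -> C2
    a.push_back(kp * x[16]);            // 39 C2 -> W3 + SBF
    a.push_back(kd * x[15]);            // 40 C1 -> C0
    a.push_back(kd * x[16]);            // 41 C2 -> C1
    for (int i = 0; i < 3; ++i) a.push_back(q.kd_i5 * x[14 + i]);  // 42..44 Ci -> SBF
    for (int i = 0; i < 3; ++i) a.push_back(q.kd_bf * x[14 + i]);  // 45..47 Ci -> Wi
    a.push_back(q.ks_bf * V);           // 48 SBF +
    a.push_back(q.kd_bf * x[17]);       // 49 SBF -
    a.push_back((q.ka_g / V) * x[17] * (1.0 - x[18])); // 50 gene on
    a.push_back(q.kd_g * x[18]);        // 51 gene off

    double a0 = 0.0; for (double ai : a) a0 += ai;
    double tau = (a0 > 0.0) ? -std::log(1.0 - U(rng)) / a0 : tend + 1.0;

    while (tnext <= std::min(t + tau, tend) + 1e-12 && irow < nrec) {
      out(irow, 0) = tnext;
      out(irow, 1) = fixed_v ? v0 : v0 * std::exp(q.mu * tnext);
      for (int k = 0; k < 19; ++k) out(irow, 2 + k) = x[k];
      ++irow; tnext += record_dt;
    }
    t += tau;
    if (t > tend || a0 <= 0.0 || irow >= nrec) break;

    double r = U(rng) * a0, cum = 0.0;
    int j = -1;
    for (size_t k = 0; k < a.size(); ++k) { cum += a[k]; if (r <= cum) { j = (int)k; break; } }
    if (j < 0) j = (int)a.size() - 1;

    switch (j) {
    case 0: x[0] += 1; break;   case 1: x[0] -= 1; break;
    case 2: x[1] += 1; break;   case 3: x[1] -= 1; break;
    case 4: x[2] += 1; break;   case 5: x[2] -= 1; break;
    case 6: x[3] += 1; break;   case 7: x[3] -= 1; break;
    case 8: x[4] += 1; break;   case 9: x[4] -= 1; break;
    case 10: x[5] += 1; break;  case 11: x[5] -= 1; break;
    case 12: x[6] += 1; break;  case 13: x[6] -= 1; break;
    case 14: x[7] += 1; break;
    default:
      if (j <= 21) { x[7 + (j - 15)] -= 1; }
      else if (j <= 27) { int i = j - 22; x[7 + i] -= 1; x[8 + i] += 1; }
      else if (j <= 33) { int i = j - 28 + 1; x[7 + i] -= 1; x[6 + i] += 1; }
      else if (j <= 36) { int i = j - 34; x[17] -= 1; x[7 + i] -= 1; x[14 + i] += 1; }
      else if (j == 37) { x[14] -= 1; x[15] += 1; }
      else if (j == 38) { x[15] -= 1; x[16] += 1; }
      else if (j == 39) { x[16] -= 1; x[10] += 1; x[17] += 1; }
      else if (j == 40) { x[15] -= 1; x[14] += 1; }
      else if (j == 41) { x[16] -= 1; x[15] += 1; }
      else if (j <= 44) { int i = j - 42; x[14 + i] -= 1; x[17] += 1; }
      else if (j <= 47) { int i = j - 45; x[14 + i] -= 1; x[7 + i] += 1; }
      else if (j == 48) { x[17] += 1; }
      else if (j == 49) { x[17] -= 1; }
      else if (j == 50) { x[17] -= 1; x[18] = 1; }
      else { x[18] = 0; x[17] += 1; }
    }
  }
  if (irow < nrec) {
    NumericMatrix out2(irow, 21);
    for (long r2 = 0; r2 < irow; ++r2)
      for (int c = 0; c < 21; ++c) out2(r2, c) = out(r2, c);
    return out2;
  }
  return out;
}
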