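// Birth-death reference simulators used to validate the chemical-Langevin
// layer: a one-stage CLE with optional mRNA-inherited noise term, a one-stage
// SSA (stationary law Poisson(A/B)), and a two-stage (mRNA + protein) SSA
// whose stationary protein CV^2 is 1/<N> + (1/<m>) * tau_m/(tau_m + tau_p).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector bd_cle_cpp(double A, double B, double mbar, double mmin,
                         double kdm, double x0, double dt, long n_steps,
                         long burn, long thin, int seed, bool mrna_noise) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  double x = x0, sqdt = std::sqrt(dt);
  std::vector<double> out;
  out.reserve((n_steps - burn) / thin + 1);
  for (long s = 0; s < n_steps; ++s) {
    double dX = (A - B * x) * dt;
    double amp = A + B * x;
    if (amp > 0) dX += std::sqrt(amp) * nd(rng) * sqdt;
    if (mrna_noise) {
      double M = 1.0 / (mbar + mmin);
      dX += x * std::sqrt(2.0 * B) * std::sqrt(M * B / (B + kdm)) * nd(rng) * sqdt;
    }
    x += dX;
    if (x < 0) x = 0;
    if (s >= burn && (s - burn) % thin == 0) out.push_back(x);
  }
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericVector bd_ssa_cpp(double A, double B, double tend, double sample_dt,
                         double burn, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double t = 0.0, x = A / B;
  x = std::round(x);
  double tnext = burn;
  std::vector<double> out;
  while (t < tend) {
    double a0 = A + B * x;
    double tau = -std::log(1.0 - U(rng)) / a0;
    while (tnext <= t + tau && tnext < tend) { out.push_back(x); tnext += sample_dt; }
    t += tau;
    if (U(rng) * a0 < A) x += 1; else x -= 1;
  }
  return NumericVector(out.begin(), out.end());
}

// Two-stage expression: 0 -> m (ksm), m -> 0 (kdm), m -> m + P (ksp per mRNA),
// P -> 0 (kdp). Samples the protein count on a regular grid after burn-in.
// [[Rcpp::export]]
NumericVector bd2_ssa_cpp(double ksm, double kdm, double ksp, double kdp,
                          double tend, double sample_dt, double burn, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double t = 0.0;
  double m = std::round(ksm / kdm);
  double P = std::round(ksm / kdm * ksp / kdp);
  double tnext = burn;
  std::vector<double> out;
  while (t < tend) {
    double a1 = ksm, a2 = kdm * m, a3 = ksp * m, a4 = kdp * P;
    double a0 = a1 + a2 + a3 + a4;
    double tau = -std::log(1.0 - U(rng)) / a0;
    while (tnext <= t + tau && tnext < tend) { out.push_back(P); tnext += sample_dt; }
    t += tau;
    double r = U(rng) * a0;
    if (r < a1) m += 1;
    else if (r < a1 + a2) m -= 1;
    else if (r < a1 + a2 + a3) P += 1;
    else P -= 1;
  }
  return NumericVector(out.begin(), out.end());
}
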