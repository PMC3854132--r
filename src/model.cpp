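#include <Rcpp.h>
using namespace Rcpp;

// Species layout (0-based): 0 EGFR*, 1 Raf*, 2 ERK*, 3 KinaseX*, 4 Rac*, 5 PAK*,
// 6 PI3K*, 7 AKT*, 8 cAMP, 9 PKA*, 10 CREB*, 11 pS112BAD, 12 pS136BAD, 13 apoptosis %.
//
// Reaction layout (0-based), one (V, K, n) triple each:
// 0 EGF->EGFR, 1 EGFR->Raf, 2 Raf->ERK, 3 ERK->KinaseX, 4 EGF->Rac, 5 Rac->PAK,
// 6 basal->PI3K, 7 PI3K->AKT, 8 stress->cAMP, 9 cAMP->PKA, 10 PKA->CREB,
// 11 (KinaseX + PKA + 0.5 AKT)->pS112, 12 PAK->pS136, 13 AKT->pS136.
//
// Inhibitor dose layout u[0..7]:
// 0 AG1478 (V0), 1 C4BRaf (V1), 2 DN-MEK1 (V2), 3 N17Rac (V4), 4 DN-PAK1 (V5),
// 5 LY294002 (V6), 6 PKI-GFP (V9), 7 BADS112A (pS112 dephosphorylation rate).

static const double AKT_S112_WEIGHT = 0.5; // "partially dependent on Akt"

static inline double hill(double x, double k, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n);
  return xn / (std::pow(k, n) + xn);
}

static inline double dfac(double u) { return 1.0 / (1.0 + u); }

static void rhs_core(double t, const double* y, double* dy,
                     const double* V, const double* K, const double* N,
                     const double* d, const double* ap, int variant,
                     double egf, double stress, const double* u,
                     double egf_clock) {
  // EGFR branch: time-dependent dephosphorylation d_i * tb * x_i, where the
  // desensitization clock tb starts at EGF exposure (short-term receptor
  // signaling), so a delayed stimulus still fires the cascade
  double tb = t - egf_clock;
  if (tb < 0.0) tb = 0.0;
  dy[0] = V[0] * dfac(u[0]) * hill(egf, K[0], N[0]) - d[0] * tb * y[0];
  dy[1] = V[1] * dfac(u[1]) * hill(y[0], K[1], N[1]) - d[1] * tb * y[1];
  dy[2] = V[2] * dfac(u[2]) * hill(y[1], K[2], N[2]) - d[2] * tb * y[2];
  dy[3] = V[3] * hill(y[2], K[3], N[3]) - d[3] * tb * y[3];
  // Rac/PAK branch
  dy[4] = V[4] * dfac(u[3]) * hill(egf, K[4], N[4]) - d[4] * y[4];
  dy[5] = V[5] * dfac(u[4]) * hill(y[4], K[5], N[5]) - d[5] * y[5];
  // PI3K/AKT branch (PI3K constitutively active; LY294002 on its velocity)
  dy[6] = V[6] * dfac(u[5]) * hill(1.0, K[6], N[6]) - d[6] * y[6];
  dy[7] = V[7] * hill(y[6], K[7], N[7]) - d[7] * y[7];
  // stress -> cAMP -> PKA -> CREB
  dy[8]  = V[8] * hill(stress, K[8], N[8]) - d[8] * y[8];
  dy[9]  = V[9] * dfac(u[6]) * hill(y[8], K[9], N[9]) - d[9] * y[9];
  dy[10] = V[10] * hill(y[9], K[10], N[10]) - d[10] * y[10];
  // BAD phosphorylation sites; BADS112A raises the pS112 dephosphorylation rate
  double s112_in = y[3] + y[9] + AKT_S112_WEIGHT * y[7];
  dy[11] = V[11] * hill(s112_in, K[11], N[11]) - d[11] * (1.0 + u[7]) * y[11];
  dy[12] = V[12] * hill(y[5], K[12], N[12]) + V[13] * hill(y[7], K[13], N[13])
           - d[12] * y[12];
  // apoptosis percentage Ca; survival complement (100 - Ca) gates the rate
  double r = (y[11] + y[12]) / ap[1];
  double g_bad = 1.0 - hill(r, ap[2], ap[3]);
  double g_mcl = 1.0;
  if (variant == 2) g_mcl = 1.0 - ap[6] * hill(y[10], ap[4], ap[5]);
  double ca = y[13] > 100.0 ? 100.0 : y[13];
  dy[13] = ap[0] * t * g_bad * g_mcl * (100.0 - ca);
  if (dy[13] < 0.0) dy[13] = 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector y, double t,
                      NumericVector vmax, NumericVector km, NumericVector hilln,
                      NumericVector decay, NumericVector apop, int variant,
                      double egf, double stress, NumericVector u,
                      double egf_clock) {
  NumericVector dy(14);
  rhs_core(t, y.begin(), dy.begin(), vmax.begin(), km.begin(), hilln.begin(),
           decay.begin(), apop.begin(), variant, egf, stress, u.begin(),
           egf_clock);
  return dy;
}

static inline void rk4_step(double t, double h, double* y,
                            const double* V, const double* K, const double* N,
                            const double* d, const double* ap, int variant,
                            double egf, double stress, const double* u,
                            double egf_clock) {
  double k1[14], k2[14], k3[14], k4[14], yt[14];
  rhs_core(t, y, k1, V, K, N, d, ap, variant, egf, stress, u, egf_clock);
  for (int i = 0; i < 14; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
  rhs_core(t + 0.5 * h, yt, k2, V, K, N, d, ap, variant, egf, stress, u, egf_clock);
  for (int i = 0; i < 14; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
  rhs_core(t + 0.5 * h, yt, k3, V, K, N, d, ap, variant, egf, stress, u, egf_clock);
  for (int i = 0; i < 14; ++i) yt[i] = y[i] + h * k3[i];
  rhs_core(t + h, yt, k4, V, K, N, d, ap, variant, egf, stress, u, egf_clock);
  for (int i = 0; i < 14; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Integrates one schedule segment [t0, t1] with constant inputs, recording the
// state at the requested absolute times (all within (t0, t1]).  Distinguishes
// float noise (tiny negative excursions, clipped) from model error (raised).
// [[Rcpp::export]]
List cpp_integrate_segment(NumericVector y0, double t0, double t1, double h,
                           NumericVector record,
                           NumericVector vmax, NumericVector km,
                           NumericVector hilln, NumericVector decay,
                           NumericVector apop, int variant,
                           double egf, double stress, NumericVector u,
                           double egf_clock) {
  const double neg_tol = 1e-9;
  double y[14];
  for (int i = 0; i < 14; ++i) y[i] = y0[i];
  int nrec = record.size();
  NumericMatrix out(nrec, 14);
  double t = t0;
  int ir = 0;
  while (true) {
    double target = (ir < nrec) ? record[ir] : t1;
    while (t < target - 1e-12) {
      double step = std::min(h, target - t);
      rk4_step(t, step, y, vmax.begin(), km.begin(), hilln.begin(),
               decay.begin(), apop.begin(), variant, egf, stress, u.begin(),
               egf_clock);
      t += step;
      for (int i = 0; i < 14; ++i) {
        if (!std::isfinite(y[i]))
          stop("integration failure: non-finite state (component %d) at t = %f",
               i + 1, t);
        if (y[i] < 0.0) {
          if (y[i] > -neg_tol) y[i] = 0.0;
          else stop("integration failure: negative state (component %d, value %e) at t = %f",
                    i + 1, y[i], t);
        }
      }
      if (y[13] > 100.0) y[13] = 100.0;
    }
    if (ir < nrec) {
      for (int i = 0; i < 14; ++i) out(ir, i) = y[i];
      ++ir;
    } else break;
    if (ir == nrec && t >= t1 - 1e-12) break;
  }
  NumericVector yend(14);
  for (int i = 0; i < 14; ++i) yend[i] = y[i];
  return List::create(_["states"] = out, _["yend"] = yend);
}
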