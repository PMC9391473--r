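#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cd;

// Batch EPG simulation of gradient-spoiled fingerprints.
// One column per (t1, t2, b1, m0) tuple; rows are the per-pulse complex
// signal F+_0 sampled at TE. States beyond kmax are truncated.
// [[Rcpp::export]]
ComplexMatrix cpp_epg_fingerprints(NumericVector t1, NumericVector t2,
                                   NumericVector b1, NumericVector m0,
                                   NumericVector flip_deg,
                                   NumericVector phase_deg,
                                   NumericVector pre_delay_ms,
                                   double tr, double te, int kmax,
                                   bool inversion_prep,
                                   double inversion_delay_ms) {
  const int na = t1.size();
  const int np = flip_deg.size();
  if (t2.size() != na || b1.size() != na || m0.size() != na)
    stop("parameter vectors must share length");
  if (phase_deg.size() != np || pre_delay_ms.size() != np)
    stop("train vectors must share length");
  if (kmax < 1) stop("kmax must be >= 1");
  if (!(tr > te && te > 0)) stop("require tr > te > 0");

  const double deg = M_PI / 180.0;
  ComplexMatrix out(np, na);
  std::vector<cd> Fp(kmax + 1), Fm(kmax + 1), Z(kmax + 1);

  for (int a = 0; a < na; ++a) {
    const double T1 = t1[a], T2 = t2[a], B1 = b1[a], M0 = m0[a];
    if (!(T1 > 0.0) || !(T2 > 0.0)) stop("t1 and t2 must be positive");
    if (!(B1 > 0.0) || M0 < 0.0) stop("b1 must be positive, m0 non-negative");
    const double e1_te = std::exp(-te / T1), e2_te = std::exp(-te / T2);
    const double e1_rr = std::exp(-(tr - te) / T1), e2_rr = std::exp(-(tr - te) / T2);

    std::fill(Fp.begin(), Fp.end(), cd(0, 0));
    std::fill(Fm.begin(), Fm.end(), cd(0, 0));
    std::fill(Z.begin(), Z.end(), cd(0, 0));
    Z[0] = cd(M0, 0);

    // lambda-free helpers inlined below to keep the hot loop simple
    if (inversion_prep) {
      Z[0] = -Z[0]; // 180 deg on equilibrium state
      const double e1 = std::exp(-inversion_delay_ms / T1);
      const double e2 = std::exp(-inversion_delay_ms / T2);
      for (int k = 0; k <= kmax; ++k) { Fp[k] *= e2; Fm[k] *= e2; Z[k] *= e1; }
      Z[0] += M0 * (1.0 - e1);
    }

    for (int j = 0; j < np; ++j) {
      if (pre_delay_ms[j] > 0.0) {
        const double e1 = std::exp(-pre_delay_ms[j] / T1);
        const double e2 = std::exp(-pre_delay_ms[j] / T2);
        for (int k = 0; k <= kmax; ++k) { Fp[k] *= e2; Fm[k] *= e2; Z[k] *= e1; }
        Z[0] += M0 * (1.0 - e1);
      }
      // RF rotation at effective flip b1 * nominal
      const double al = B1 * flip_deg[j] * deg;
      const double ph = phase_deg[j] * deg;
      const double ca2 = std::cos(al / 2) * std::cos(al / 2);
      const double sa2 = std::sin(al / 2) * std::sin(al / 2);
      const double sa = std::sin(al), ca = std::cos(al);
      const cd eip = std::polar(1.0, ph), ei2p = std::polar(1.0, 2 * ph);
      const cd i1(0, 1);
      for (int k = 0; k <= kmax; ++k) {
        const cd fp = Fp[k], fm = Fm[k], z = Z[k];
        Fp[k] = ca2 * fp + ei2p * sa2 * fm - i1 * eip * sa * z;
        Fm[k] = std::conj(ei2p) * sa2 * fp + ca2 * fm + i1 * std::conj(eip) * sa * z;
        Z[k] = -0.5 * i1 * std::conj(eip) * sa * fp + 0.5 * i1 * eip * sa * fm + ca * z;
      }
      // relax over TE, sample F+_0
      for (int k = 0; k <= kmax; ++k) { Fp[k] *= e2_te; Fm[k] *= e2_te; Z[k] *= e1_te; }
      Z[0] += M0 * (1.0 - e1_te);
      out(j, a) = Rcomplex{Fp[0].real(), Fp[0].imag()};
      // relax over TR - TE
      for (int k = 0; k <= kmax; ++k) { Fp[k] *= e2_rr; Fm[k] *= e2_rr; Z[k] *= e1_rr; }
      Z[0] += M0 * (1.0 - e1_rr);
      // gradient spoiler shift: F+ up, F- down, conjugate transfer at zero
      for (int k = kmax; k >= 1; --k) Fp[k] = Fp[k - 1];
      for (int k = 0; k < kmax; ++k) Fm[k] = Fm[k + 1];
      Fm[kmax] = cd(0, 0);
      Fp[0] = std::conj(Fm[0]);
    }
  }
  return out;
}
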