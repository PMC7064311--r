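#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional wave-reflection (Kelly-Lochbaum) propagation through a
// time-varying tubelet area function. Sections are half an audio sample
// long, so each full sample performs two half-step scattering passes.
// Waves are pressure waves; the glottal end is an ideal flow source with
// reflection r_glottis, the lip end reflects with r_lip and radiates the
// transmitted flow. Areas are linearly interpolated between modulation
// frames; areas below `floor_area` are clamped for scattering, which makes
// occluded sections behave as (nearly) fully reflecting closed junctions.
// Turbulence noise is injected as a forward pressure wave immediately
// downstream of the most constricted section whose Reynolds number
// exceeds re_c.
// [[Rcpp::export]]
List waveguide_synth(NumericMatrix frames, double frame_rate,
                     NumericVector ug, NumericVector noise_supra,
                     double fs, double rho, double c0, double nu,
                     double re_c, double noise_gain,
                     double r_glottis, double r_lip, double atten,
                     double floor_area) {
  const int n_frames = frames.nrow();
  const int nx = frames.ncol();
  const int ns = ug.size();

  std::vector<double> A(nx), Zc(nx), r(nx - 1);
  std::vector<double> f(nx, 0.0), b(nx, 0.0), nf(nx, 0.0), nb(nx, 0.0);
  NumericVector lip_flow(ns), re_supra(ns), min_area(ns);

  for (int t = 0; t < ns; ++t) {
    // area interpolation at this sample
    double pos = t * frame_rate / fs;
    int i0 = (int)std::floor(pos);
    double frac = pos - i0;
    if (i0 >= n_frames - 1) { i0 = n_frames - 1; frac = 0.0; }
    double amin = R_PosInf;
    for (int i = 0; i < nx; ++i) {
      double a = (frac == 0.0) ? frames(i0, i)
                               : (1.0 - frac) * frames(i0, i) + frac * frames(i0 + 1, i);
      if (a < amin) amin = a;
      if (a < floor_area) a = floor_area;
      A[i] = a;
      Zc[i] = rho * c0 / a;
    }
    min_area[t] = amin;
    for (int i = 0; i < nx - 1; ++i)
      r[i] = (A[i] - A[i + 1]) / (A[i] + A[i + 1]);

    // supraglottal turbulence: most constricted super-threshold junction
    double re_best = 0.0;
    int inj = -1;
    if (noise_gain > 0.0) {
      double a_best = R_PosInf;
      for (int i = 0; i < nx - 1; ++i) {
        double u = (f[i] - b[i]) / Zc[i];
        double dh = 2.0 * std::sqrt(A[i] / M_PI);
        double re = std::fabs(u) * dh / (A[i] * nu);
        if (re > re_c && A[i] < a_best) { a_best = A[i]; inj = i + 1; re_best = re; }
      }
      re_supra[t] = re_best;
      if (inj >= 0) {
        double unois = noise_supra[t] * (re_best * re_best - re_c * re_c) * noise_gain;
        f[inj] += 0.5 * Zc[inj] * unois;
      }
    }

    for (int half = 0; half < 2; ++half) {
      nf[0] = r_glottis * b[0] + Zc[0] * ug[t];
      for (int i = 0; i < nx - 1; ++i) {
        nf[i + 1] = (1.0 + r[i]) * f[i] - r[i] * b[i + 1];
        nb[i] = r[i] * f[i] + (1.0 - r[i]) * b[i + 1];
      }
      nb[nx - 1] = r_lip * f[nx - 1];
      for (int i = 0; i < nx; ++i) {
        f[i] = atten * nf[i];
        b[i] = atten * nb[i];
      }
    }
    lip_flow[t] = (1.0 - r_lip) * f[nx - 1] / Zc[nx - 1];
  }
  return List::create(_["lip_flow"] = lip_flow, _["re_supra"] = re_supra,
                      _["min_area"] = min_area);
}
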