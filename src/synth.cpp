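#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled-oscillator surrogate EEG.  Each channel carries a primary phase
// oscillator pulled toward a common reference oscillator with a per-sample
// coupling gain kappa (rad/s), plus a weaker secondary oscillator, 50 Hz line
// contamination and white noise.  During ictal samples all channels lock to a
// common low-frequency rhythm at boosted amplitude.  Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix gen_signal_cpp(int n, double dt, NumericVector base_freqs,
                             double drift_hz_per_hr, NumericVector kappa,
                             double ref_freq, double phase_noise_sd,
                             NumericVector amp_scale, double amp,
                             double sec_amp_frac, double line_amp,
                             double line_freq, double noise_sd,
                             LogicalVector ictal, double ictal_freq) {
  const int d = base_freqs.size();
  const double twopi = 2.0 * M_PI;
  NumericMatrix out(n, d);
  std::vector<double> th(d), th2(d);
  for (int j = 0; j < d; ++j) { th[j] = R::runif(0.0, twopi); th2[j] = R::runif(0.0, twopi); }
  double th_ref = R::runif(0.0, twopi);
  double th_ict = R::runif(0.0, twopi);
  const double sn = phase_noise_sd * std::sqrt(dt);

  for (int i = 0; i < n; ++i) {
    const double t = i * dt;
    const double drift = drift_hz_per_hr * (t / 3600.0);
    th_ref += twopi * (ref_freq + drift) * dt + sn * R::norm_rand();
    th_ict += twopi * ictal_freq * dt + sn * R::norm_rand();
    const double line = line_amp * std::cos(twopi * line_freq * t);
    const double a = amp * amp_scale[i];
    for (int j = 0; j < d; ++j) {
      const double fj = base_freqs[j] + drift;
      th[j] += twopi * fj * dt + kappa[i] * std::sin(th_ref - th[j]) * dt +
               sn * R::norm_rand();
      th2[j] += twopi * (2.3 * fj) * dt + sn * R::norm_rand();
      double sig;
      if (ictal[i]) sig = a * std::cos(th_ict + 0.15 * j);
      else sig = a * std::cos(th[j]) + sec_amp_frac * a * std::cos(th2[j]);
      out(i, j) = sig + line + noise_sd * R::norm_rand();
    }
  }
  return out;
}
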