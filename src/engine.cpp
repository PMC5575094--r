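#include <Rcpp.h>
using namespace Rcpp;

// Compiled inner loop of the population engine. Consumes R's global RNG
// stream in exactly the same order as the pure-R reference path (dg_step):
// per step, n-1 uniforms for the Fisher-Yates matching, n/2 uniforms for
// role assignment, then one normal deviate per non-frozen recipient in pair
// order (only when noise_scale > 0). Keeping the streams aligned lets tests
// assert bitwise-identical trajectories between the two engines.

// [[Rcpp::export]]
List run_steps_cpp(NumericVector aspirations, NumericVector donations,
                   LogicalVector envious, LogicalVector frozen,
                   int n_steps, double endowment, double learning_rate,
                   double habituation, double noise_scale, bool record) {
  const int n = aspirations.size();
  const int half = n / 2;
  const double phi = endowment, l = learning_rate, h = habituation;
  const bool noisy = noise_scale > 0.0;

  NumericVector asp = clone(aspirations);
  NumericVector don = clone(donations);
  NumericVector means(record ? n_steps : 0);
  std::vector<int> perm(n);
  std::vector<double> role(half);

  for (int step = 0; step < n_steps; ++step) {
    // Fisher-Yates: for i = n-1 .. 1, swap with j in 0..i
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i >= 1; --i) {
      int j = (int)(unif_rand() * (i + 1));
      int tmp = perm[i]; perm[i] = perm[j]; perm[j] = tmp;
    }
    for (int k = 0; k < half; ++k) role[k] = unif_rand();

    for (int k = 0; k < half; ++k) {
      int first = perm[2 * k], second = perm[2 * k + 1];
      int dict = (role[k] < 0.5) ? first : second;
      int rec = (role[k] < 0.5) ? second : first;
      if (frozen[rec]) continue;  // frozen recipients never update, no draws

      double a = asp[rec], d = don[rec], pi = don[dict];
      double s = (phi == a) ? 0.0 : (pi - a) / (phi - a);
      if (s > 1.0) s = 1.0; else if (s < -1.0) s = -1.0;
      double a2 = (s >= 0.0) ? a + (phi - a) * l * s : a + a * l * s;
      double d2 = (1.0 - h) * d + h * pi;
      double cap = phi - a2;
      if (d2 > cap) d2 = cap;
      if (d2 < 0.0) d2 = 0.0;
      if (noisy) {
        double eps = norm_rand() * noise_scale;
        d2 *= (1.0 + eps);
        if (d2 < 0.0) d2 = 0.0; else if (d2 > phi) d2 = phi;
      }
      if (envious[rec] && d2 > 0.5 * phi) d2 = 0.5 * phi;
      if (d2 < 0.0) d2 = 0.0; else if (d2 > phi) d2 = phi;
      asp[rec] = a2;
      don[rec] = d2;
    }

    if (record) {
      // long double accumulation, as base R's mean() uses
      long double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += don[i];
      means[step] = (double)(tot / n);
    }
  }

  return List::create(_["aspirations"] = asp, _["donations"] = don,
                      _["mean_donations"] = means);
}
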