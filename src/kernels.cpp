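// Low-level numerical kernels for the synthetic-session generator.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Narrowband carrier synthesis: linearly upsample a complex baseband
// (re, im; sampled every L output samples) and rotate it to the band center
// frequency f0. Returns Re(z) and, when components = true, Im(z) so callers
// can read the exact instantaneous phase without a Hilbert transform.
// The rotation phasor is advanced by complex multiplication and renormalized
// periodically so magnitude drift stays at machine precision.
// [[Rcpp::export]]
List upsample_rotate_cpp(NumericVector re, NumericVector im, int L,
                         double f0, double fs, double n_out,
                         bool components) {
  const R_xlen_t n = (R_xlen_t)n_out;
  const R_xlen_t m = re.size();
  if (im.size() != m) stop("re/im length mismatch");
  if ((R_xlen_t)((n - 1) / L) + 2 > m) stop("baseband too short for n_out");
  NumericVector out_re(n);
  NumericVector out_im = components ? NumericVector(n) : NumericVector(0);
  const double w = 2.0 * M_PI * f0 / fs;
  const double cw = std::cos(w), sw = std::sin(w);
  double cr = 1.0, ci = 0.0;
  const double invL = 1.0 / L;
  for (R_xlen_t t = 0; t < n; ++t) {
    const R_xlen_t j = t / L;
    const double frac = (t - j * (R_xlen_t)L) * invL;
    const double rb = re[j] + (re[j + 1] - re[j]) * frac;
    const double ib = im[j] + (im[j + 1] - im[j]) * frac;
    out_re[t] = rb * cr - ib * ci;
    if (components) out_im[t] = rb * ci + ib * cr;
    const double cr2 = cr * cw - ci * sw;
    ci = cr * sw + ci * cw;
    cr = cr2;
    if ((t & 8191) == 8191) {
      const double s = 1.0 / std::sqrt(cr * cr + ci * ci);
      cr *= s; ci *= s;
    }
  }
  if (components) return List::create(_["re"] = out_re, _["im"] = out_im);
  return List::create(_["re"] = out_re);
}

// Discrete-time (one step per LFP sample) thinned point process with an
// absolute/relative refractory recovery profile g (indexed by samples since
// the last spike) and optional von Mises phase-dependent thinning
// exp(kappa * (cos(phase - mu) - 1)) <= 1.
// h is the per-state per-sample base hazard. Returns 1-based spike samples.
// [[Rcpp::export]]
IntegerVector spike_thin_cpp(IntegerVector state_per_bin, int bin_len,
                             NumericVector h, NumericVector g,
                             NumericVector phase,
                             NumericVector kappa, NumericVector mu,
                             double n_samples, int seed) {
  const R_xlen_t n = (R_xlen_t)n_samples;
  const R_xlen_t G = g.size();
  const bool has_phase = phase.size() > 0;
  if (has_phase && phase.size() < n) stop("phase shorter than n_samples");
  std::mt19937_64 gen(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> cos_mu(kappa.size()), sin_mu(kappa.size());
  for (int s = 0; s < kappa.size(); ++s) {
    cos_mu[s] = std::cos(mu[s]);
    sin_mu[s] = std::sin(mu[s]);
  }
  std::vector<int> spikes;
  R_xlen_t since = G; // start fully recovered
  for (R_xlen_t t = 0; t < n; ++t) {
    const R_xlen_t b = t / bin_len;
    if (b >= state_per_bin.size()) break;
    const int s = state_per_bin[b];
    double p = h[s];
    if (p > 0.0) {
      if (since < G) p *= g[since];
      if (p > 0.0 && has_phase && kappa[s] > 0.0) {
        // cos(phi - mu) = cos(phi) cos(mu) + sin(phi) sin(mu)
        const double c = std::cos(phase[t]) * cos_mu[s] +
                         std::sin(phase[t]) * sin_mu[s];
        p *= std::exp(kappa[s] * (c - 1.0));
      }
      if (p > 1.0) p = 1.0;
      if (p > 0.0 && unif(gen) < p) {
        spikes.push_back((int)(t + 1));
        since = 0;
        continue;
      }
    }
    if (since < G) ++since;
  }
  return wrap(spikes);
}

// Mean Euclidean distance from each row of X to all rows (used by the
// outlier-excluding k-means initialization). Blocked BLAS formulation:
// ||xi - xj||^2 = |xi|^2 + |xj|^2 - 2 xi.xj.
// [[Rcpp::export]]
NumericVector mean_pairwise_dist_cpp(NumericMatrix X) {
  const arma::uword n = X.nrow(), d = X.ncol();
  arma::mat M(X.begin(), n, d, false);
  arma::vec sq = arma::sum(arma::square(M), 1);
  arma::vec acc(n, arma::fill::zeros);
  const arma::uword block = 1024;
  for (arma::uword i0 = 0; i0 < n; i0 += block) {
    const arma::uword i1 = std::min(i0 + block, n) - 1;
    arma::mat D = -2.0 * (M.rows(i0, i1) * M.t());
    D.each_row() += sq.t();
    D.each_col() += sq.subvec(i0, i1);
    D.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });
    acc.subvec(i0, i1) = arma::sum(D, 1);
  }
  acc /= (double)(n - 1);
  return wrap(acc);
}
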