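// Pairwise AMD functional-connectivity z-scores.
//
// For each ordered pair (i, j) the AMD of train i against reference train
// j is standardized either by the analytic uniform-placement null (mean
// sum(L^2)/4T, second moment sum(L^3)/12T over the reference train's
// inter-spike intervals) or by a jitter-surrogate null: the reference
// train is perturbed B times with Gaussian jitter and the observed AMD is
// z-scored against the surrogate AMDs.  The surrogate null retains any
// slow common rate modulation, so only spike locking at a timescale finer
// than the jitter SD registers as significant.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double amd_sorted(const std::vector<double> &si,
                         const std::vector<double> &sj) {
  double acc = 0.0;
  const size_t nj = sj.size();
  size_t lo = 0;
  for (size_t k = 0; k < si.size(); ++k) {
    const double t = si[k];
    while (lo + 1 < nj && sj[lo + 1] <= t) ++lo;
    double d = std::fabs(t - sj[lo]);
    if (lo + 1 < nj) d = std::min(d, sj[lo + 1] - t);
    acc += d;
  }
  return acc / si.size();
}

// [[Rcpp::export(name = ".fc_zmat")]]
NumericMatrix fc_zmat(List trains, int min_spikes, bool literal_sign,
                      bool jitter, double jitter_sd, int n_surrogates) {
  const int n = trains.size();
  std::vector<std::vector<double>> tr(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = trains[i];
    tr[i].assign(v.begin(), v.end());
    std::sort(tr[i].begin(), tr[i].end());
  }
  NumericMatrix z(n, n);
  std::fill(z.begin(), z.end(), NA_REAL);
  const int need = std::max(2, min_spikes);

  for (int j = 0; j < n; ++j) {
    const std::vector<double> &sj = tr[j];
    if ((int)sj.size() < need) continue;

    double mu = 0.0, sigma = 0.0;
    std::vector<std::vector<double>> surr;
    if (!jitter) {
      double T = sj.back() - sj.front(), s2 = 0.0, s3 = 0.0;
      if (T <= 0) continue;
      for (size_t k = 1; k < sj.size(); ++k) {
        const double L = sj[k] - sj[k - 1];
        s2 += L * L;
        s3 += L * L * L;
      }
      mu = s2 / (4.0 * T);
      const double var = s3 / (12.0 * T) - mu * mu;
      if (var <= 0) continue;
      sigma = std::sqrt(var);
    } else {
      surr.resize(n_surrogates);
      for (int b = 0; b < n_surrogates; ++b) {
        surr[b].resize(sj.size());
        for (size_t k = 0; k < sj.size(); ++k)
          surr[b][k] = sj[k] + norm_rand() * jitter_sd;
        std::sort(surr[b].begin(), surr[b].end());
      }
    }

    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      const std::vector<double> &si = tr[i];
      if ((int)si.size() < need) continue;
      double zij;
      if (!jitter) {
        // restrict to spikes inside the reference span (the analytic
        // null describes points placed there); the AMD then averages
        // n_in distances, so the null SD is sigma/sqrt(n_in)
        std::vector<double> si_in;
        si_in.reserve(si.size());
        for (size_t k = 0; k < si.size(); ++k)
          if (si[k] >= sj.front() && si[k] <= sj.back())
            si_in.push_back(si[k]);
        if ((int)si_in.size() < 1) continue;
        const double a = amd_sorted(si_in, sj);
        zij = std::sqrt((double)si_in.size()) * (mu - a) / sigma;
      } else {
        const double a = amd_sorted(si, sj);
        double m = 0.0, ss = 0.0;
        for (int b = 0; b < n_surrogates; ++b) {
          const double ab = amd_sorted(si, surr[b]);
          m += ab;
          ss += ab * ab;
        }
        m /= n_surrogates;
        const double var = (ss - n_surrogates * m * m) / (n_surrogates - 1);
        if (var <= 0) continue;
        zij = (m - a) / std::sqrt(var);
      }
      z(i, j) = literal_sign ? -zij : zij;
    }
  }
  return z;
}
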