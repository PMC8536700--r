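// Renormalised-permutation ("ReBoot") null scoring for pairwise
// co-occurrence measures. For a candidate OTU pair (i, j) each permutation
// shuffles the two count vectors independently across samples and
// recomputes each sample's relative abundances with the permuted counts in
// place of the originals (denominator = rest + xi' + xj'), attenuating the
// spurious correlation induced by the compositional constraint. Measures:
// Pearson, Spearman (average-tie ranks), Bray-Curtis between the two
// relative-abundance profiles, and symmetric Kullback-Leibler divergence on
// pseudocount-smoothed, per-OTU-normalised profiles.
//
// Uses R's RNG (set.seed on the R side makes every draw reproducible).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int N_MEASURES = 4;  // pearson, spearman, bray_curtis, kld

static void shuffle_inplace(std::vector<double> &v) {
  const int n = v.size();
  for (int i = n - 1; i > 0; --i) {
    int k = (int)std::floor(unif_rand() * (i + 1));
    if (k > i) k = i;
    std::swap(v[i], v[k]);
  }
}

static double pearson(const std::vector<double> &a, const std::vector<double> &b) {
  const int n = a.size();
  double ma = 0, mb = 0;
  for (int k = 0; k < n; ++k) { ma += a[k]; mb += b[k]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (int k = 0; k < n; ++k) {
    const double da = a[k] - ma, db = b[k] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

static std::vector<double> avg_ranks(const std::vector<double> &v) {
  const int n = v.size();
  std::vector<int> idx(n);
  for (int k = 0; k < n; ++k) idx[k] = k;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  std::vector<double> r(n);
  int k = 0;
  while (k < n) {
    int j = k;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[k]]) ++j;
    const double avg = (k + j) / 2.0 + 1.0;
    for (int t = k; t <= j; ++t) r[idx[t]] = avg;
    k = j + 1;
  }
  return r;
}

static double spearman(const std::vector<double> &a, const std::vector<double> &b) {
  return pearson(avg_ranks(a), avg_ranks(b));
}

static double bray(const std::vector<double> &a, const std::vector<double> &b) {
  double num = 0, den = 0;
  for (size_t k = 0; k < a.size(); ++k) {
    num += std::fabs(a[k] - b[k]);
    den += a[k] + b[k];
  }
  if (den <= 0) return NA_REAL;
  return num / den;
}

static double kld_sym(const std::vector<double> &a, const std::vector<double> &b,
                      double eps) {
  const int n = a.size();
  double sa = 0, sb = 0;
  for (int k = 0; k < n; ++k) { sa += a[k] + eps; sb += b[k] + eps; }
  double d = 0;
  for (int k = 0; k < n; ++k) {
    const double p = (a[k] + eps) / sa, q = (b[k] + eps) / sb;
    d += (p - q) * (std::log(p) - std::log(q));
  }
  return d;
}

// relative abundances of the pair given (possibly permuted) counts
static void pair_rel(const std::vector<double> &xi, const std::vector<double> &xj,
                     const std::vector<double> &rest,
                     std::vector<double> &ai, std::vector<double> &aj) {
  const int n = xi.size();
  for (int k = 0; k < n; ++k) {
    const double tot = rest[k] + xi[k] + xj[k];
    ai[k] = tot > 0 ? xi[k] / tot : 0.0;
    aj[k] = tot > 0 ? xj[k] / tot : 0.0;
  }
}

static void score_all(const std::vector<double> &ai, const std::vector<double> &aj,
                      double eps, double *out) {
  out[0] = pearson(ai, aj);
  out[1] = spearman(ai, aj);
  out[2] = bray(ai, aj);
  out[3] = kld_sym(ai, aj, eps);
}

// Null score matrix (nperm x 4) for one pair.
// [[Rcpp::export(name = ".reboot_null_pair")]]
NumericMatrix reboot_null_pair(NumericVector xi, NumericVector xj,
                               NumericVector rest, int nperm, double eps) {
  const int n = xi.size();
  std::vector<double> pi(xi.begin(), xi.end()), pj(xj.begin(), xj.end()),
      rst(rest.begin(), rest.end()), ai(n), aj(n);
  NumericMatrix out(nperm, N_MEASURES);
  double s[N_MEASURES];
  for (int b = 0; b < nperm; ++b) {
    shuffle_inplace(pi);
    shuffle_inplace(pj);
    pair_rel(pi, pj, rst, ai, aj);
    score_all(ai, aj, eps, s);
    for (int m = 0; m < N_MEASURES; ++m) out(b, m) = s[m];
  }
  return out;
}

// Batch driver: for each candidate pair return, per measure, the observed
// score (original denominators), the null mean, the two-sided empirical
// permutation p-value p = (1 + #{|null - mean| >= |obs - mean|}) /
// (1 + n_valid), the normalised null rank u = (1 + #{null <= obs}) /
// (1 + n_valid), and the null standard deviation (for the Gaussian-tail
// p-value computed on the R side).
// For Brown's method the dependence between the measures is estimated from
// the pair's own null: each null draw is converted to a Gaussian-tail
// p-value against the null mean/sd, and the covariance matrix of
// -2 log p across draws is returned (flattened, 16 extra columns) — the
// covariance of the merge statistic under the very null the p-values are
// computed from, uncontaminated by signal heterogeneity across candidates.
// Columns: obs[4], null_mean[4], p[4], u[4], null_sd[4], Lcov[16].
// [[Rcpp::export(name = ".reboot_batch")]]
NumericMatrix reboot_batch(NumericMatrix counts, NumericVector lib,
                           IntegerVector pairI, IntegerVector pairJ,
                           int nperm, double eps) {
  const int n = counts.ncol();
  const int P = pairI.size();
  NumericMatrix out(P, 5 * N_MEASURES + N_MEASURES * N_MEASURES);
  std::vector<double> xi(n), xj(n), rest(n), pi(n), pj(n), ai(n), aj(n);
  std::vector<double> nullsc(N_MEASURES * (size_t)nperm);
  double obs[N_MEASURES], s[N_MEASURES];

  for (int p = 0; p < P; ++p) {
    const int i = pairI[p] - 1, j = pairJ[p] - 1;
    for (int k = 0; k < n; ++k) {
      xi[k] = counts(i, k);
      xj[k] = counts(j, k);
      rest[k] = lib[k] - xi[k] - xj[k];
    }
    pair_rel(xi, xj, rest, ai, aj);  // = counts / lib
    score_all(ai, aj, eps, obs);

    pi = xi; pj = xj;
    for (int b = 0; b < nperm; ++b) {
      shuffle_inplace(pi);
      shuffle_inplace(pj);
      pair_rel(pi, pj, rest, ai, aj);
      score_all(ai, aj, eps, s);
      for (int m = 0; m < N_MEASURES; ++m)
        nullsc[(size_t)m * nperm + b] = s[m];
    }

    for (int m = 0; m < N_MEASURES; ++m) {
      double mean = 0;
      int nvalid = 0;
      for (int b = 0; b < nperm; ++b) {
        const double v = nullsc[(size_t)m * nperm + b];
        if (!ISNAN(v)) { mean += v; ++nvalid; }
      }
      if (nvalid == 0 || ISNAN(obs[m])) {
        out(p, m) = obs[m];
        out(p, N_MEASURES + m) = NA_REAL;
        out(p, 2 * N_MEASURES + m) = NA_REAL;
        out(p, 3 * N_MEASURES + m) = NA_REAL;
        out(p, 4 * N_MEASURES + m) = NA_REAL;
        continue;
      }
      mean /= nvalid;
      const double dev = std::fabs(obs[m] - mean);
      int ge = 0, le = 0;
      double ss = 0;
      for (int b = 0; b < nperm; ++b) {
        const double v = nullsc[(size_t)m * nperm + b];
        if (ISNAN(v)) continue;
        if (std::fabs(v - mean) >= dev - 1e-12) ++ge;
        if (v <= obs[m] + 1e-12) ++le;
        ss += (v - mean) * (v - mean);
      }
      out(p, m) = obs[m];
      out(p, N_MEASURES + m) = mean;
      out(p, 2 * N_MEASURES + m) = (1.0 + ge) / (1.0 + nvalid);
      out(p, 3 * N_MEASURES + m) = (1.0 + le) / (1.0 + nvalid);
      out(p, 4 * N_MEASURES + m) =
          nvalid > 1 ? std::sqrt(ss / (nvalid - 1)) : NA_REAL;
    }

    // covariance of -2 log p across the null draws (pairwise complete)
    std::vector<double> L(N_MEASURES * (size_t)nperm, NA_REAL);
    for (int m = 0; m < N_MEASURES; ++m) {
      const double mean = out(p, N_MEASURES + m), sd = out(p, 4 * N_MEASURES + m);
      if (ISNAN(mean) || ISNAN(sd) || sd <= 0) continue;
      for (int b = 0; b < nperm; ++b) {
        const double v = nullsc[(size_t)m * nperm + b];
        if (ISNAN(v)) continue;
        double pv = 2.0 * R::pnorm(-std::fabs((v - mean) / sd), 0.0, 1.0, 1, 0);
        if (pv < 1e-300) pv = 1e-300;
        L[(size_t)m * nperm + b] = -2.0 * std::log(pv);
      }
    }
    for (int m1 = 0; m1 < N_MEASURES; ++m1)
      for (int m2 = m1; m2 < N_MEASURES; ++m2) {
        double s1 = 0, s2 = 0, s12 = 0;
        int nv = 0;
        for (int b = 0; b < nperm; ++b) {
          const double a = L[(size_t)m1 * nperm + b];
          const double c = L[(size_t)m2 * nperm + b];
          if (ISNAN(a) || ISNAN(c)) continue;
          s1 += a; s2 += c; s12 += a * c; ++nv;
        }
        double cv = NA_REAL;
        if (nv > 1) cv = (s12 - s1 * s2 / nv) / (nv - 1);
        out(p, 5 * N_MEASURES + m1 * N_MEASURES + m2) = cv;
        out(p, 5 * N_MEASURES + m2 * N_MEASURES + m1) = cv;
      }
  }
  return out;
}
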