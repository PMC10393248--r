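#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Time-delay embedding: row k is (x[k], x[k+tau], ..., x[k+(m-1)tau]).
// All kernels below index embedded vectors this way; n_e = N - (m-1)*tau.

static inline double embed_dist2(const double *x, int i, int j, int m, int tau) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = x[i + k * tau] - x[j + k * tau];
    s += d * d;
  }
  return s;
}

// Condensed upper-triangular Euclidean distances between embedded vectors.
// [[Rcpp::export]]
NumericVector cpp_embed_dists(NumericVector x, int m, int tau) {
  int N = x.size();
  int ne = N - (m - 1) * tau;
  if (ne < 2) stop("series too short for embedding");
  R_xlen_t P = (R_xlen_t)ne * (ne - 1) / 2;
  NumericVector out(P);
  const double *px = x.begin();
  R_xlen_t k = 0;
  for (int i = 0; i < ne - 1; ++i)
    for (int j = i + 1; j < ne; ++j)
      out[k++] = std::sqrt(embed_dist2(px, i, j, m, tau));
  return out;
}

// Template-match counts for sample entropy: B over m-length templates, A over
// (m+1)-length, both restricted to the first N-m start indices (Richman-Moorman),
// Chebyshev distance <= r, self-matches excluded.
// [[Rcpp::export]]
List cpp_sampen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int nt = N - m;  // number of templates at both lengths
  if (nt < 2) stop("series too short for sample entropy");
  const double *px = x.begin();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(px[i + k] - px[j + k]);
        if (d > dmax) dmax = d;
      }
      if (dmax <= r) {
        B += 1.0;
        double d = std::fabs(px[i + m] - px[j + m]);
        if (std::max(dmax, d) <= r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// Symmetric recurrence matrix from a condensed distance vector.
// [[Rcpp::export]]
LogicalMatrix cpp_recurrence_from_dists(NumericVector d, int n, double eps) {
  LogicalMatrix rp(n, n);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) rp(i, i) = true;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      bool rec = d[k++] <= eps;
      rp(i, j) = rec;
      rp(j, i) = rec;
    }
  return rp;
}

// Run lengths of recurrent points along diagonals (offsets |i-j| >= theiler),
// recurrent vertical runs (full columns), and non-recurrent ("white") vertical
// runs (full columns). Returned as raw run-length vectors.
// [[Rcpp::export]]
List cpp_line_runs(LogicalMatrix rp, int theiler) {
  int n = rp.nrow();
  std::vector<int> diag_runs, vert_runs, white_runs;
  // diagonals
  for (int off = -(n - 1); off <= n - 1; ++off) {
    if (std::abs(off) < theiler) continue;
    int i0 = off < 0 ? -off : 0;
    int j0 = off < 0 ? 0 : off;
    int len = n - std::abs(off);
    int run = 0;
    for (int k = 0; k < len; ++k) {
      if (rp(i0 + k, j0 + k)) {
        ++run;
      } else if (run > 0) {
        diag_runs.push_back(run);
        run = 0;
      }
    }
    if (run > 0) diag_runs.push_back(run);
  }
  // verticals (columns, full)
  for (int j = 0; j < n; ++j) {
    int run = 0, wrun = 0;
    for (int i = 0; i < n; ++i) {
      if (rp(i, j)) {
        ++run;
        if (wrun > 0) { white_runs.push_back(wrun); wrun = 0; }
      } else {
        ++wrun;
        if (run > 0) { vert_runs.push_back(run); run = 0; }
      }
    }
    if (run > 0) vert_runs.push_back(run);
    if (wrun > 0) white_runs.push_back(wrun);
  }
  return List::create(_["diagonal"] = wrap(diag_runs),
                      _["vertical"] = wrap(vert_runs),
                      _["white_vertical"] = wrap(white_runs));
}

// All recurrence line-structure histograms straight from the series, without
// materializing the N x N plot: computes embedded distances, the fixed-RR
// threshold (k-th smallest off-diagonal distance), and run-length histograms
// of diagonal lines (offsets >= theiler, both triangles), recurrent vertical
// lines and white vertical lines (full columns, diagonal recurrent by
// construction). Mirrors cpp_line_runs() on the materialized plot exactly.
// [[Rcpp::export]]
List cpp_rqa_from_series(NumericVector x, int m, int tau, double target_rr,
                         int theiler) {
  int N = x.size();
  int ne = N - (m - 1) * tau;
  if (ne < 3) stop("series too short for embedding");
  if ((double)ne * (ne - 1) / 2 > 6.0e7) {
    stop("embedded series too long for recurrence analysis; analyse a ",
         "shorter segment");
  }
  R_xlen_t P = (R_xlen_t)ne * (ne - 1) / 2;
  std::vector<float> d((size_t)P);  // squared distances
  const double *px = x.begin();
  std::vector<R_xlen_t> rowstart0(ne);
  for (int i = 0; i < ne; ++i)
    rowstart0[i] = (R_xlen_t)i * (2 * ne - i - 1) / 2 - i - 1;
  if (tau == 1) {
    // slide along each diagonal offset: O(ne^2) total
    int span = m;  // window length in samples when tau == 1
    for (int o = 1; o < ne; ++o) {
      double d2 = embed_dist2(px, 0, o, m, tau);
      d[rowstart0[0] + o] = (float)d2;
      int len = ne - o;
      for (int i = 1; i < len; ++i) {
        double drop = px[i - 1] - px[i - 1 + o];
        double add = px[i - 1 + span] - px[i - 1 + span + o];
        d2 += add * add - drop * drop;
        d[rowstart0[i] + (i + o)] = (float)(d2 < 0 ? 0 : d2);
      }
    }
  } else {
    R_xlen_t k = 0;
    for (int i = 0; i < ne - 1; ++i)
      for (int j = i + 1; j < ne; ++j)
        d[k++] = (float)embed_dist2(px, i, j, m, tau);
  }
  R_xlen_t kth = (R_xlen_t)std::lround(target_rr * (double)P);
  if (kth < 1) kth = 1;
  float eps;  // squared threshold
  {
    std::vector<float> dc(d);
    std::nth_element(dc.begin(), dc.begin() + (kth - 1), dc.end());
    eps = dc[kth - 1];
  }
  double nrec = 0;
  for (R_xlen_t k = 0; k < P; ++k) if (d[k] <= eps) nrec += 1;
  double attained = nrec / (double)P;

  const std::vector<R_xlen_t> &rowstart = rowstart0;
  // d index for (i,j): rowstart[i] + j
  std::vector<double> diag_hist(ne + 1, 0.0), vert_hist(ne + 1, 0.0),
      white_hist(ne + 1, 0.0);
  // diagonals: offsets o >= theiler, counted twice (symmetry)
  for (int o = std::max(theiler, 1); o < ne; ++o) {
    int len = ne - o;
    int run = 0;
    for (int i = 0; i < len; ++i) {
      bool rec = d[rowstart[i] + (i + o)] <= eps;
      if (rec) {
        ++run;
      } else if (run > 0) {
        diag_hist[run] += 2;
        run = 0;
      }
    }
    if (run > 0) diag_hist[run] += 2;
  }
  // verticals: full columns; cell (i, j) recurrent iff i == j or d <= eps
  for (int j = 0; j < ne; ++j) {
    int run = 0, wrun = 0;
    for (int i = 0; i < ne; ++i) {
      bool rec = (i == j) ||
        (i < j ? d[rowstart[i] + j] : d[rowstart[j] + i]) <= eps;
      if (rec) {
        ++run;
        if (wrun > 0) { white_hist[wrun] += 1; wrun = 0; }
      } else {
        ++wrun;
        if (run > 0) { vert_hist[run] += 1; run = 0; }
      }
    }
    if (run > 0) vert_hist[run] += 1;
    if (wrun > 0) white_hist[wrun] += 1;
  }
  return List::create(_["epsilon"] = std::sqrt((double)eps),
                      _["attained_rr"] = attained,
                      _["diag_hist"] = wrap(diag_hist),
                      _["vert_hist"] = wrap(vert_hist),
                      _["white_hist"] = wrap(white_hist));
}

// Pair counts for the correlation sum: number of embedded pairs with
// |i-j| >= theiler and Euclidean distance <= each radius (radii ascending).
// [[Rcpp::export]]
List cpp_corr_counts(NumericVector x, int m, int tau, NumericVector radii,
                     int theiler) {
  int N = x.size();
  int ne = N - (m - 1) * tau;
  if (ne < 2) stop("series too short for embedding");
  int nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  std::vector<double> bins(nr + 1, 0.0);
  const double *px = x.begin();
  double npairs = 0.0;
  int omin = std::max(theiler, 1);
  if (tau == 1) {
    int span = m;
    for (int o = omin; o < ne; ++o) {
      double d2 = embed_dist2(px, 0, o, m, tau);
      int len = ne - o;
      npairs += len;
      bins[std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin()] += 1.0;
      for (int i = 1; i < len; ++i) {
        double drop = px[i - 1] - px[i - 1 + o];
        double add = px[i - 1 + span] - px[i - 1 + span + o];
        d2 += add * add - drop * drop;
        double v = d2 < 0 ? 0 : d2;
        bins[std::lower_bound(r2.begin(), r2.end(), v) - r2.begin()] += 1.0;
      }
    }
  } else {
    for (int i = 0; i < ne - 1; ++i) {
      for (int j = i + omin; j < ne; ++j) {
        npairs += 1.0;
        double d2 = embed_dist2(px, i, j, m, tau);
        bins[std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin()] += 1.0;
      }
    }
  }
  // cumulative: count of pairs with distance <= each radius
  std::vector<double> counts(nr, 0.0);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) {
    acc += bins[k];
    counts[k] = acc;
  }
  return List::create(_["counts"] = wrap(counts), _["n_pairs"] = npairs);
}
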