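// Compiled hot path: per-trial band x window covariance accumulation and the
// sliding-window CSP -> Fisher -> naive-Bayes cross-validation sweep that the
// permutation null repeats hundreds of times per subject. All randomness
// (fold assignments, label permutations) is generated in R and passed in, so
// this code is deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// covs slices are ordered window-major: slice(w * n_bands + b).

// Two-stage accumulation: per-timepoint band cross-products are computed
// once, then summed over each (overlapping) window.
// [[Rcpp::export]]
NumericVector cpp_window_band_covs(ComplexVector coef, IntegerVector dims,
                                   List bins, List tps) {
  const int n = dims[0], d = dims[1], F = dims[2], T = dims[3];
  const int B = bins.size(), W = tps.size();
  const int d2u = d * (d + 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(n) * d * d * W * B);
  out.attr("dim") = IntegerVector::create(n, d * d, W * B);
  const Rcomplex* z = coef.begin();
  std::vector<double> xr(d), xi(d);
  std::vector<double> P;   // per-timepoint band cross-products: T x n x d2u
  for (int b = 0; b < B; ++b) {
    IntegerVector fb = bins[b];
    P.assign(static_cast<size_t>(T) * n * d2u, 0.0);
    for (int t = 0; t < T; ++t) {
      double* Pt = P.data() + static_cast<size_t>(t) * n * d2u;
      for (int fi = 0; fi < fb.size(); ++fi) {
        const R_xlen_t f0 = static_cast<R_xlen_t>(fb[fi] - 1);
        const R_xlen_t plane = static_cast<R_xlen_t>(n) * d *
          (f0 + static_cast<R_xlen_t>(F) * t);
        for (int tr = 0; tr < n; ++tr) {
          for (int c = 0; c < d; ++c) {
            const Rcomplex v = z[plane + tr + static_cast<R_xlen_t>(n) * c];
            xr[c] = v.r; xi[c] = v.i;
          }
          double* acc = Pt + static_cast<size_t>(tr) * d2u;
          int u = 0;
          for (int j = 0; j < d; ++j) {
            const double ar = xr[j], ai = xi[j];
            for (int i = 0; i <= j; ++i, ++u)
              acc[u] += xr[i] * ar + xi[i] * ai;
          }
        }
      }
    }
    for (int w = 0; w < W; ++w) {
      IntegerVector tpw = tps[w];
      const int m = fb.size() * tpw.size();
      double* slice = out.begin() +
        static_cast<R_xlen_t>(w * B + b) * n * d * d;
      for (int tr = 0; tr < n; ++tr) {
        std::vector<double> acc(d2u, 0.0);
        for (int ti = 0; ti < tpw.size(); ++ti) {
          const double* Pt = P.data() +
            (static_cast<size_t>(tpw[ti] - 1) * n + tr) * d2u;
          for (int u = 0; u < d2u; ++u) acc[u] += Pt[u];
        }
        int u = 0;
        for (int j = 0; j < d; ++j)
          for (int i = 0; i <= j; ++i, ++u) {
            const double v = acc[u] / m;
            slice[tr + static_cast<R_xlen_t>(n) * (i + j * d)] = v;
            slice[tr + static_cast<R_xlen_t>(n) * (j + i * d)] = v;
          }
      }
    }
  }
  return out;
}

static arma::mat csp_filters(const arma::mat& C1in, const arma::mat& C2in,
                             double shrink, int d) {
  arma::mat C1 = 0.5 * (C1in + C1in.t());
  arma::mat C2 = 0.5 * (C2in + C2in.t());
  if (shrink > 0) {
    C1 = (1 - shrink) * C1 +
      shrink * (arma::trace(C1) / d) * arma::eye(d, d);
    C2 = (1 - shrink) * C2 +
      shrink * (arma::trace(C2) / d) * arma::eye(d, d);
  }
  arma::mat R;
  if (!arma::chol(R, C2))
    stop("class-2 covariance is singular; use a nonzero shrinkage");
  arma::mat Rinv = arma::inv(arma::trimatu(R));
  arma::mat M = Rinv.t() * C1 * Rinv;
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, 0.5 * (M + M.t()));
  arma::mat Wf = Rinv * evec;           // columns = filters, eval ascending
  return arma::fliplr(Wf);              // descending eigenvalue order
}

// One full sliding-window timecourse for a single label assignment.
static arma::rowvec decode_one(const arma::cube& covs, int n_windows,
                               int n_bands, const arma::ivec& labels,
                               const arma::ivec& folds, int k_folds,
                               int n_select, double shrink) {
  const int n = covs.n_rows;
  const int d2 = covs.n_cols;
  const int d = static_cast<int>(std::lround(std::sqrt((double)d2)));
  const int n_feat = n_bands * d;
  arma::rowvec acc_out(n_windows, arma::fill::zeros);

  // per-fold-class row index lists
  std::vector<std::vector<arma::uword>> fold_idx(k_folds);
  for (int i = 0; i < n; ++i) fold_idx[folds[i]].push_back(i);

  arma::mat Feat(n, n_feat);
  for (int w = 0; w < n_windows; ++w) {
    double acc_sum = 0.0;
    for (int f = 0; f < k_folds; ++f) {
      // CSP per band on training trials, features for all trials
      for (int b = 0; b < n_bands; ++b) {
        const arma::mat& X = covs.slice(w * n_bands + b);
        arma::vec s0(d2, arma::fill::zeros), s1(d2, arma::fill::zeros);
        int n0 = 0, n1 = 0;
        for (int i = 0; i < n; ++i) {
          if (folds[i] == f) continue;
          if (labels[i] == 0) { s0 += X.row(i).t(); ++n0; }
          else               { s1 += X.row(i).t(); ++n1; }
        }
        arma::mat C1(s0.memptr(), d, d);
        arma::mat C2(s1.memptr(), d, d);
        C1 /= n0; C2 /= n1;
        arma::mat Wf = csp_filters(C1, C2, shrink, d);
        arma::mat Wouter(d2, d);
        for (int j = 0; j < d; ++j) {
          arma::mat O = Wf.col(j) * Wf.col(j).t();
          Wouter.col(j) = arma::vectorise(O);
        }
        Feat.cols(b * d, b * d + d - 1) = X * Wouter;
      }
      // Fisher scores on training trials
      arma::rowvec m0(n_feat, arma::fill::zeros), m1(n_feat, arma::fill::zeros);
      arma::rowvec q0(n_feat, arma::fill::zeros), q1(n_feat, arma::fill::zeros);
      int n0 = 0, n1 = 0;
      for (int i = 0; i < n; ++i) {
        if (folds[i] == f) continue;
        if (labels[i] == 0) { m0 += Feat.row(i); q0 += arma::square(Feat.row(i)); ++n0; }
        else                { m1 += Feat.row(i); q1 += arma::square(Feat.row(i)); ++n1; }
      }
      m0 /= n0; m1 /= n1;
      arma::rowvec v0 = (q0 - n0 * arma::square(m0)) / (n0 - 1);
      arma::rowvec v1 = (q1 - n1 * arma::square(m1)) / (n1 - 1);
      arma::rowvec score(n_feat);
      for (int j = 0; j < n_feat; ++j) {
        const double num = (m0[j] - m1[j]) * (m0[j] - m1[j]);
        const double den = v0[j] + v1[j];
        if (den > 0) score[j] = num / den;
        else score[j] = (num > 0) ? std::numeric_limits<double>::max() : 0.0;
      }
      // stable top-k (ties -> lower index)
      std::vector<int> sel;
      std::vector<bool> used(n_feat, false);
      const int k_sel = std::min(n_select, n_feat);
      for (int s = 0; s < k_sel; ++s) {
        int best = -1; double bv = -1.0;
        for (int j = 0; j < n_feat; ++j)
          if (!used[j] && score[j] > bv) { bv = score[j]; best = j; }
        used[best] = true; sel.push_back(best);
      }
      // Gaussian naive Bayes on the selected features
      arma::vec mu0(k_sel), mu1(k_sel), va0(k_sel), va1(k_sel);
      for (int s = 0; s < k_sel; ++s) {
        const int j = sel[s];
        mu0[s] = m0[j]; mu1[s] = m1[j];
        const double mall = (n0 * m0[j] + n1 * m1[j]) / (n0 + n1);
        const double qall = q0[j] + q1[j];
        const double pooled = (qall - (n0 + n1) * mall * mall) /
          std::max(n0 + n1 - 1, 1);
        double vfloor = 1e-9 * pooled;
        if (!(vfloor > 0)) vfloor = 1e-12;
        va0[s] = std::max(v0[j], vfloor);
        va1[s] = std::max(v1[j], vfloor);
      }
      const double lp0 = std::log((double)n0 / (n0 + n1));
      const double lp1 = std::log((double)n1 / (n0 + n1));
      int correct = 0, n_test = 0;
      for (arma::uword ii = 0; ii < fold_idx[f].size(); ++ii) {
        const int i = fold_idx[f][ii];
        double l0 = lp0, l1 = lp1;
        for (int s = 0; s < k_sel; ++s) {
          const double x = Feat(i, sel[s]);
          l0 += -0.5 * std::log(2 * M_PI * va0[s]) -
            (x - mu0[s]) * (x - mu0[s]) / (2 * va0[s]);
          l1 += -0.5 * std::log(2 * M_PI * va1[s]) -
            (x - mu1[s]) * (x - mu1[s]) / (2 * va1[s]);
        }
        const int pred = (l1 > l0) ? 1 : 0;   // tie -> first class
        if (pred == labels[i]) ++correct;
        ++n_test;
      }
      acc_sum += (double)correct / n_test;
    }
    acc_out[w] = 100.0 * acc_sum / k_folds;
  }
  return acc_out;
}

// [[Rcpp::export]]
NumericVector cpp_decode_timecourse(NumericVector covs_flat, int n_windows,
                                    int n_bands, IntegerVector labels,
                                    IntegerVector folds, int n_select,
                                    double shrink) {
  IntegerVector dm = covs_flat.attr("dim");
  arma::cube covs(covs_flat.begin(), dm[0], dm[1], dm[2], false);
  arma::ivec lab(labels.size());
  arma::ivec fld(folds.size());
  int k_folds = 0;
  for (int i = 0; i < labels.size(); ++i) {
    lab[i] = labels[i]; fld[i] = folds[i];
    k_folds = std::max(k_folds, folds[i] + 1);
  }
  arma::rowvec acc = decode_one(covs, n_windows, n_bands, lab, fld,
                                k_folds, n_select, shrink);
  return NumericVector(acc.begin(), acc.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_permutation_null(NumericVector covs_flat, int n_windows,
                                   int n_bands, IntegerMatrix labels_mat,
                                   IntegerMatrix folds_mat, int n_select,
                                   double shrink) {
  IntegerVector dm = covs_flat.attr("dim");
  arma::cube covs(covs_flat.begin(), dm[0], dm[1], dm[2], false);
  const int n_perm = labels_mat.nrow();
  const int n = labels_mat.ncol();
  NumericMatrix out(n_perm, n_windows);
  for (int r = 0; r < n_perm; ++r) {
    arma::ivec lab(n), fld(n);
    int k_folds = 0;
    for (int i = 0; i < n; ++i) {
      lab[i] = labels_mat(r, i);
      fld[i] = folds_mat(r, i);
      k_folds = std::max(k_folds, fld[i] + 1);
    }
    arma::rowvec acc = decode_one(covs, n_windows, n_bands, lab, fld,
                                  (int)k_folds, n_select, shrink);
    for (int w = 0; w < n_windows; ++w) out(r, w) = acc[w];
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Direct Morlet convolution evaluated only at the requested (cropped,
// decimated) output samples; mathematically identical to zero-padded FFT
// convolution with "same" alignment.
// [[Rcpp::export]]
ComplexVector cpp_morlet_conv(NumericVector data, IntegerVector dims,
                              List kernels, IntegerVector keep, double fs) {
  const int n_tr = dims[0], n_ch = dims[1], n = dims[2];
  const int F = kernels.size(), T = keep.size();
  ComplexVector out(static_cast<R_xlen_t>(n_tr) * n_ch * F * T);
  out.attr("dim") = IntegerVector::create(n_tr, n_ch, F, T);
  std::vector<double> x(n);
  for (int tr = 0; tr < n_tr; ++tr) {
    for (int ch = 0; ch < n_ch; ++ch) {
      for (int i = 0; i < n; ++i)
        x[i] = data[tr + static_cast<R_xlen_t>(n_tr) * (ch + static_cast<R_xlen_t>(n_ch) * i)];
      for (int f = 0; f < F; ++f) {
        ComplexVector ker = kernels[f];
        const int klen = ker.size();
        const int half = (klen - 1) / 2;
        for (int ti = 0; ti < T; ++ti) {
          const int k = keep[ti] - 1;             // 0-based output sample
          // y[k] = sum_m x[m] * w[k + half - m]
          int m_lo = std::max(0, k + half - (klen - 1));
          int m_hi = std::min(n - 1, k + half);
          double re = 0.0, im = 0.0;
          for (int m = m_lo; m <= m_hi; ++m) {
            const Rcomplex w = ker[k + half - m];
            re += x[m] * w.r;
            im += x[m] * w.i;
          }
          Rcomplex v; v.r = re / fs; v.i = im / fs;
          out[tr + static_cast<R_xlen_t>(n_tr) *
              (ch + static_cast<R_xlen_t>(n_ch) *
               (f + static_cast<R_xlen_t>(F) * ti))] = v;
        }
      }
    }
  }
  return out;
}
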