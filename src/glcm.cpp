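// Gray-level co-occurrence texture statistics. Hot path of the cropland
// feature bank (called per pixel window per stage), hence C++.
//
// Conventions (shared with the R-level documentation and the brute-force
// test oracle): symmetric normalized GLCM; statistics computed on the
// submatrix of levels actually present (marginals strictly positive);
// correlation of a zero-variance matrix is 1; MCC of a single-level matrix
// is 1. The maximal correlation coefficient uses the similarity
// D^{1/2} Q D^{-1/2} = A^2 with A = D^{-1/2} P D^{-1/2} symmetric, so the
// second-largest eigenvalue of Q is the squared second-largest |eigenvalue|
// of A.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// 18 statistics of one compacted normalized symmetric GLCM with level
// values lv (1-based gray levels).
arma::vec glcm_stats(const arma::mat &p, const arma::vec &lv) {
  const int G = (int)p.n_rows;
  arma::vec out(18);
  arma::vec px = arma::sum(p, 1);
  double mux = arma::dot(lv, px);
  double varx = 0.0;
  for (int i = 0; i < G; ++i) varx += (lv[i] - mux) * (lv[i] - mux) * px[i];

  double asm_ = 0, contrast = 0, idm = 0, corr_num = 0, variance = 0,
         entropy = 0, dissim = 0, shade = 0, prom = 0, hxy1 = 0;
  for (int i = 0; i < G; ++i) {
    for (int j = 0; j < G; ++j) {
      double v = p(i, j);
      double di = lv[i] - lv[j], si = lv[i] + lv[j];
      asm_ += v * v;
      contrast += di * di * v;
      idm += v / (1.0 + di * di);
      corr_num += lv[i] * lv[j] * v;
      variance += (lv[i] - mux) * (lv[i] - mux) * v;
      dissim += std::fabs(di) * v;
      double cs = si - 2.0 * mux;
      shade += cs * cs * cs * v;
      prom += cs * cs * cs * cs * v;
      if (v > 0) entropy -= v * std::log(v);
      if (v > 0) hxy1 -= v * std::log(px[i] * px[j]);
    }
  }
  double correlation = varx == 0 ? 1.0 : (corr_num - mux * mux) / varx;

  // sum/diff distributions over actual (non-contiguous) level values
  double sum_avg, sum_var, sum_ent;
  std::map<double, double> msum, mdiff;
  for (int i = 0; i < G; ++i)
    for (int j = 0; j < G; ++j) {
      double v = p(i, j);
      if (v <= 0) continue;
      msum[lv[i] + lv[j]] += v;
      mdiff[std::fabs(lv[i] - lv[j])] += v;
    }
  sum_avg = 0; sum_ent = 0;
  for (auto &kv : msum) {
    sum_avg += kv.first * kv.second;
    sum_ent -= kv.second * std::log(kv.second);
  }
  sum_var = 0;
  for (auto &kv : msum)
    sum_var += (kv.first - sum_avg) * (kv.first - sum_avg) * kv.second;
  double diff_mean = 0, diff_var = 0, diff_ent = 0;
  for (auto &kv : mdiff) {
    diff_mean += kv.first * kv.second;
    diff_ent -= kv.second * std::log(kv.second);
  }
  for (auto &kv : mdiff)
    diff_var += (kv.first - diff_mean) * (kv.first - diff_mean) * kv.second;

  double hx = 0, hxy2 = 0;
  for (int i = 0; i < G; ++i) {
    if (px[i] > 0) hx -= px[i] * std::log(px[i]);
    for (int j = 0; j < G; ++j) {
      double w = px[i] * px[j];
      if (w > 0) hxy2 -= w * std::log(w);
    }
  }
  double imc1 = hx == 0 ? 0.0 : (entropy - hxy1) / hx;
  double imc2 = std::sqrt(std::max(0.0, 1.0 - std::exp(-2.0 * (hxy2 - entropy))));

  double mcc = 1.0;
  if (G > 1) {
    arma::vec d = arma::sqrt(px);
    arma::mat A = p;
    for (int i = 0; i < G; ++i)
      for (int j = 0; j < G; ++j) A(i, j) /= d[i] * d[j];
    arma::vec ev;
    arma::eig_sym(ev, A);
    arma::vec mags = arma::sort(arma::abs(ev), "descend");
    mcc = mags[1];
  }

  out[0] = asm_; out[1] = contrast; out[2] = correlation; out[3] = variance;
  out[4] = idm; out[5] = sum_avg; out[6] = sum_var; out[7] = sum_ent;
  out[8] = entropy; out[9] = diff_var; out[10] = diff_ent; out[11] = imc1;
  out[12] = imc2; out[13] = mcc; out[14] = dissim; out[15] = contrast;
  out[16] = shade; out[17] = prom;
  return out;
}

} // namespace

// [[Rcpp::export]]
NumericVector glcm_features_cpp(IntegerMatrix q, int levels) {
  const int nr = q.nrow(), nc = q.ncol();
  const int offsets[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}};
  arma::vec acc(18, arma::fill::zeros);
  for (int o = 0; o < 4; ++o) {
    int dr = offsets[o][0], dc = offsets[o][1];
    arma::mat P(levels, levels, arma::fill::zeros);
    double tot = 0;
    for (int r = 0; r < nr; ++r) {
      int r2 = r + dr;
      if (r2 < 0 || r2 >= nr) continue;
      for (int c = 0; c < nc; ++c) {
        int c2 = c + dc;
        if (c2 < 0 || c2 >= nc) continue;
        int a = q(r, c), b = q(r2, c2);
        if (a == NA_INTEGER || b == NA_INTEGER) continue;
        P(a - 1, b - 1) += 1; P(b - 1, a - 1) += 1;
        tot += 2;
      }
    }
    if (tot == 0) { acc.fill(NA_REAL); break; }
    P /= tot;
    // compact to present levels
    arma::uvec keep = arma::find(arma::sum(P, 1) > 0);
    arma::mat p = P.submat(keep, keep);
    arma::vec lv = arma::conv_to<arma::vec>::from(keep) + 1.0;
    acc += glcm_stats(p, lv);
  }
  NumericVector out(18);
  for (int i = 0; i < 18; ++i) out[i] = acc[i] / 4.0;
  return out;
}
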