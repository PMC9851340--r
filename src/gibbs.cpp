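#include <Rcpp.h>
using namespace Rcpp;

static inline double logc(double p) {
  return std::log(std::max(p, 1e-300));
}

// One systematic-scan sweep over the binary latents, in the fixed order
// R, Z, W, Lambda.  Blocks can be toggled so each full conditional is
// testable in isolation.  Inputs are copied; the updated state is returned.
// labels are 0-based here (the R wrapper shifts).
//
// When ret_extra is true the return value also carries the complete-data
// log-likelihood of the updated latents (under the parameters used for the
// sweep) and the sufficient statistics consumed by the continuous-parameter
// conditionals: sum(R), #(Z == R), sum(W), membership counts, and per
// emission component (x|z=0, x|z=1, y|phi=0, y|phi=1) the count, sum and
// sum of squares.
// [[Rcpp::export]]
List gibbs_sweep_cpp(NumericMatrix X, NumericMatrix Y,
                     IntegerVector R, IntegerMatrix Z, IntegerMatrix W,
                     IntegerVector labels,
                     double gamma, double delta, double beta,
                     NumericVector p,
                     double mu0, double mu1, double sigma0, double sigma1,
                     double alpha0, double alpha1, double eta0, double eta1,
                     bool do_R, bool do_Z, bool do_W, bool do_L,
                     bool ret_extra = false) {
  const int n = X.nrow(), m = X.ncol(), s = W.nrow();
  IntegerVector r = clone(R);
  IntegerMatrix z = clone(Z), w = clone(W);
  IntegerVector lab = clone(labels);

  const double lg1 = logc(gamma), lg0 = logc(1.0 - gamma);
  const double ld1 = logc(delta), ld0 = logc(1.0 - delta);
  const double lb1 = logc(beta),  lb0 = logc(1.0 - beta);

  // cache the tumor-side Gaussian log-densities under both methylation
  // components; reused by the Z, W and Lambda blocks and the likelihood
  // (densities do not depend on the latents).  Normal-side densities are
  // only needed once (Z block) and are computed inline there.
  const double LN_SQRT_2PI = 0.918938533204672741780329736406;
  const double cx0 = -LN_SQRT_2PI - std::log(sigma0), ix0 = 1.0 / sigma0;
  const double cx1 = -LN_SQRT_2PI - std::log(sigma1), ix1 = 1.0 / sigma1;
  const double cy0 = -LN_SQRT_2PI - std::log(eta0),   iy0 = 1.0 / eta0;
  const double cy1 = -LN_SQRT_2PI - std::log(eta1),   iy1 = 1.0 / eta1;
  NumericMatrix ly0(n, m), ly1(n, m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double yv = Y(i, j);
      double c = (yv - alpha0) * iy0, d = (yv - alpha1) * iy1;
      ly0(i, j) = cy0 - 0.5 * c * c;
      ly1(i, j) = cy1 - 0.5 * d * d;
    }

  if (do_R) {
    for (int j = 0; j < m; ++j) {
      int c1 = 0;
      for (int i = 0; i < n; ++i) c1 += z(i, j);
      // log-odds of r_j = 1 vs 0 given the retain/flip channel to Z
      double d = (lg1 - lg0) + (2 * c1 - n) * (ld1 - ld0);
      double p1 = 1.0 / (1.0 + std::exp(-d));
      r[j] = (unif_rand() < p1) ? 1 : 0;
    }
  }

  if (do_Z) {
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) {
        int wk = w(lab[i], j);
        double xv = X(i, j);
        double a = (xv - mu0) * ix0, b = (xv - mu1) * ix1;
        // z = 1: channel vs r_j, x under component 1, y under phi = 1 xor w
        double l1 = (r[j] == 1 ? ld1 : ld0) + (cx1 - 0.5 * b * b) +
                    (wk == 1 ? ly0(i, j) : ly1(i, j));
        double l0 = (r[j] == 0 ? ld1 : ld0) + (cx0 - 0.5 * a * a) +
                    (wk == 1 ? ly1(i, j) : ly0(i, j));
        double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
        z(i, j) = (unif_rand() < p1) ? 1 : 0;
      }
  }

  if (do_W) {
    // per column, accumulate each subtype's members' evidence for w = 1
    // (column scans keep the access pattern cache-friendly)
    std::vector<double> d(s);
    for (int j = 0; j < m; ++j) {
      for (int k = 0; k < s; ++k) d[k] = lb1 - lb0;
      for (int i = 0; i < n; ++i) {
        // w = 1 flips phi away from z_ij; w = 0 keeps phi = z_ij
        double t = (z(i, j) == 1) ? ly0(i, j) - ly1(i, j)
                                  : ly1(i, j) - ly0(i, j);
        d[lab[i]] += t;
      }
      for (int k = 0; k < s; ++k) {
        double p1 = 1.0 / (1.0 + std::exp(-d[k]));
        w(k, j) = (unif_rand() < p1) ? 1 : 0;
      }
    }
  }

  if (do_L) {
    NumericMatrix A(n, s);   // A(i, k) = sum_j log N(y_ij | phi under path k)
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < s; ++k) {
        int wk = w(k, j);
        for (int i = 0; i < n; ++i) {
          int phi = z(i, j) ^ wk;
          A(i, k) += (phi == 1) ? ly1(i, j) : ly0(i, j);
        }
      }
    std::vector<double> lp(s);
    for (int i = 0; i < n; ++i) {
      double hi = R_NegInf;
      for (int k = 0; k < s; ++k) {
        lp[k] = logc(p[k]) + A(i, k);
        hi = std::max(hi, lp[k]);
      }
      double tot = 0.0;
      for (int k = 0; k < s; ++k) { lp[k] = std::exp(lp[k] - hi); tot += lp[k]; }
      double u = unif_rand() * tot, cum = 0.0;
      int pick = s - 1;
      for (int k = 0; k < s; ++k) { cum += lp[k]; if (u < cum) { pick = k; break; } }
      lab[i] = pick;
    }
  }

  if (!ret_extra)
    return List::create(_["R"] = r, _["Z"] = z, _["W"] = w, _["labels"] = lab);

  double ll = 0.0;
  int sumR = 0, agree = 0, sumW = 0;
  for (int j = 0; j < m; ++j) { sumR += r[j]; ll += (r[j] == 1) ? lg1 : lg0; }
  for (int k = 0; k < s; ++k)
    for (int j = 0; j < m; ++j) {
      sumW += w(k, j);
      ll += (w(k, j) == 1) ? lb1 : lb0;
    }
  NumericVector nk(s);
  for (int i = 0; i < n; ++i) { nk[lab[i]] += 1.0; ll += logc(p[lab[i]]); }
  // per emission component: count, sum, sum of squares
  double cnt[4] = {0, 0, 0, 0}, sum[4] = {0, 0, 0, 0}, ssq[4] = {0, 0, 0, 0};
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      int zi = z(i, j);
      int phi = zi ^ w(lab[i], j);
      if (zi == r[j]) { agree += 1; ll += ld1; } else ll += ld0;
      double xv = X(i, j), yv = Y(i, j);
      if (zi == 1) { double t = (xv - mu1) * ix1; ll += cx1 - 0.5 * t * t; }
      else         { double t = (xv - mu0) * ix0; ll += cx0 - 0.5 * t * t; }
      ll += phi ? ly1(i, j) : ly0(i, j);
      cnt[zi] += 1.0; sum[zi] += xv; ssq[zi] += xv * xv;
      cnt[2 + phi] += 1.0; sum[2 + phi] += yv; ssq[2 + phi] += yv * yv;
    }
  return List::create(_["R"] = r, _["Z"] = z, _["W"] = w, _["labels"] = lab,
                      _["loglik"] = ll,
                      _["sumR"] = sumR, _["agree"] = agree, _["sumW"] = sumW,
                      _["label_counts"] = nk,
                      _["count"] = NumericVector::create(cnt[0], cnt[1], cnt[2], cnt[3]),
                      _["sum"] = NumericVector::create(sum[0], sum[1], sum[2], sum[3]),
                      _["sumsq"] = NumericVector::create(ssq[0], ssq[1], ssq[2], ssq[3]));
}

// Complete-data log-likelihood; mirrors the R implementation and backs the
// per-iteration trace.
// [[Rcpp::export]]
double complete_loglik_cpp(NumericMatrix X, NumericMatrix Y,
                           IntegerVector R, IntegerMatrix Z, IntegerMatrix W,
                           IntegerVector labels,
                           double gamma, double delta, double beta,
                           NumericVector p,
                           double mu0, double mu1, double sigma0, double sigma1,
                           double alpha0, double alpha1, double eta0, double eta1) {
  const int n = X.nrow(), m = X.ncol();
  double ll = 0.0;
  const double lg1 = logc(gamma), lg0 = logc(1.0 - gamma);
  const double ld1 = logc(delta), ld0 = logc(1.0 - delta);
  const double lb1 = logc(beta),  lb0 = logc(1.0 - beta);
  const double LN_SQRT_2PI = 0.918938533204672741780329736406;
  const double cx0 = -LN_SQRT_2PI - std::log(sigma0), ix0 = 1.0 / sigma0;
  const double cx1 = -LN_SQRT_2PI - std::log(sigma1), ix1 = 1.0 / sigma1;
  const double cy0 = -LN_SQRT_2PI - std::log(eta0),   iy0 = 1.0 / eta0;
  const double cy1 = -LN_SQRT_2PI - std::log(eta1),   iy1 = 1.0 / eta1;
  for (int j = 0; j < m; ++j) ll += (R[j] == 1) ? lg1 : lg0;
  for (int k = 0; k < W.nrow(); ++k)
    for (int j = 0; j < m; ++j) ll += (W(k, j) == 1) ? lb1 : lb0;
  for (int i = 0; i < n; ++i) ll += logc(p[labels[i]]);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      ll += (Z(i, j) == R[j]) ? ld1 : ld0;
      if (Z(i, j) == 1) { double t = (X(i, j) - mu1) * ix1; ll += cx1 - 0.5 * t * t; }
      else              { double t = (X(i, j) - mu0) * ix0; ll += cx0 - 0.5 * t * t; }
      int phi = Z(i, j) ^ W(labels[i], j);
      if (phi == 1) { double t = (Y(i, j) - alpha1) * iy1; ll += cy1 - 0.5 * t * t; }
      else          { double t = (Y(i, j) - alpha0) * iy0; ll += cy0 - 0.5 * t * t; }
    }
  return ll;
}
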