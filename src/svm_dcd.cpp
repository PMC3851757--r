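#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Linear SVM solved in the dual by coordinate descent (the LIBLINEAR solver
// for the L2-regularised, L1-loss problem), with random coordinate
// permutations and active-set shrinking.  The bias is carried as an augmented
// constant feature, so it is regularised together with the weights.  The
// permutation comes from an internal LCG seeded with a fixed constant, so a
// fit is bit-reproducible independently of R's RNG.  A learning iteration
// ("step") is one coordinate visit, matching the iteration count of the
// LIBSVM-family solvers; max_iter caps the total number of steps.

static inline unsigned lcg_next(unsigned& state) {
  state = state * 1103515245u + 12345u;
  return (state >> 16) & 0x7fffu;
}

static int dcd_fit(const std::vector<double>& x, const std::vector<double>& y,
                   int n, int dim, double C, int max_iter, double tol,
                   std::vector<double>& w) {
  std::vector<double> alpha((size_t)n, 0.0), qd((size_t)n);
  std::vector<int> index((size_t)n);
  std::fill(w.begin(), w.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    const double* xi = &x[(size_t)i * dim];
    double s = 0.0;
    for (int j = 0; j < dim; ++j) s += xi[j] * xi[j];
    qd[i] = s;
    index[i] = i;
  }
  unsigned rng = 1u;
  int active = n;
  double pgmax_old = R_PosInf, pgmin_old = R_NegInf;
  int steps = 0;
  bool capped = false;
  while (!capped) {
    double pgmax_new = R_NegInf, pgmin_new = R_PosInf;
    for (int i = 0; i < active; ++i) {
      int j = i + (int)(lcg_next(rng) % (unsigned)(active - i));
      std::swap(index[i], index[j]);
    }
    for (int s = 0; s < active; ++s) {
      int i = index[s];
      const double* xi = &x[(size_t)i * dim];
      double g = 0.0;
      for (int j = 0; j < dim; ++j) g += w[j] * xi[j];
      g = g * y[i] - 1.0;
      double pg = 0.0;
      if (alpha[i] == 0.0) {
        if (g > pgmax_old) {          // shrink
          --active; std::swap(index[s], index[active]); --s; continue;
        } else if (g < 0.0) pg = g;
      } else if (alpha[i] == C) {
        if (g < pgmin_old) {
          --active; std::swap(index[s], index[active]); --s; continue;
        } else if (g > 0.0) pg = g;
      } else pg = g;
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (++steps >= max_iter) capped = true;
      if (std::fabs(pg) > 1e-12 && qd[i] > 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - g / qd[i];
        if (a_new < 0.0) a_new = 0.0; else if (a_new > C) a_new = C;
        if (a_new != a_old) {
          alpha[i] = a_new;
          double d = (a_new - a_old) * y[i];
          for (int j = 0; j < dim; ++j) w[j] += d * xi[j];
        }
      }
      if (capped) break;
    }
    if (capped) break;
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) break;
      active = n; pgmax_old = R_PosInf; pgmin_old = R_NegInf;
      continue;
    }
    pgmax_old = pgmax_new > 0.0 ? pgmax_new : R_PosInf;
    pgmin_old = pgmin_new < 0.0 ? pgmin_new : R_NegInf;
  }
  return steps;
}

// One-vs-one multiclass machinery.  Class labels are 0-based indices
// 0..nclass-1.  Pairs are enumerated (a, b) with a < b, a-major.  A pair with
// one class absent from the training rows casts a constant vote for the
// present class (const_vote = that class); a pair with both classes absent is
// inert (const_vote = -2); a normally trained pair has const_vote = -1.

struct OvoModel {
  int nclass, dim;                 // dim includes the bias column
  std::vector<int> pa, pb, const_vote, iters;
  std::vector<double> W;           // dim x npairs, column per pair
};

// xs: row-major standardised matrix WITH bias column, n x dim
static void ovo_fit(const std::vector<double>& xs, const std::vector<int>& y,
                    int n, int dim, int nclass, double C, int max_iter,
                    double tol, OvoModel& m) {
  m.nclass = nclass; m.dim = dim;
  m.pa.clear(); m.pb.clear(); m.const_vote.clear(); m.iters.clear();
  int npairs = nclass * (nclass - 1) / 2;
  m.W.assign((size_t)dim * npairs, 0.0);
  std::vector<double> xbuf, ybuf, w((size_t)dim);
  int p = 0;
  for (int a = 0; a < nclass; ++a) {
    for (int b = a + 1; b < nclass; ++b, ++p) {
      xbuf.clear(); ybuf.clear();
      int na = 0, nb = 0;
      for (int i = 0; i < n; ++i) {
        if (y[i] == a || y[i] == b) {
          const double* xi = &xs[(size_t)i * dim];
          xbuf.insert(xbuf.end(), xi, xi + dim);
          ybuf.push_back(y[i] == a ? 1.0 : -1.0);
          if (y[i] == a) ++na; else ++nb;
        }
      }
      m.pa.push_back(a); m.pb.push_back(b);
      if (na == 0 && nb == 0) { m.const_vote.push_back(-2); m.iters.push_back(0); continue; }
      if (na == 0) { m.const_vote.push_back(b); m.iters.push_back(0); continue; }
      if (nb == 0) { m.const_vote.push_back(a); m.iters.push_back(0); continue; }
      int it = dcd_fit(xbuf, ybuf, na + nb, dim, C, max_iter, tol, w);
      m.const_vote.push_back(-1);
      m.iters.push_back(it);
      std::copy(w.begin(), w.end(), m.W.begin() + (size_t)p * dim);
    }
  }
}

// Majority vote over pairwise decisions; ties broken by the summed signed
// decision values accumulated for each class, then by the lower class index.
static int ovo_vote(const OvoModel& m, const double* xi) {
  std::vector<int> votes(m.nclass, 0);
  std::vector<double> score(m.nclass, 0.0);
  int npairs = (int)m.pa.size();
  for (int p = 0; p < npairs; ++p) {
    int cv = m.const_vote[p];
    if (cv == -2) continue;
    if (cv >= 0) { votes[cv]++; score[cv] += 1.0; continue; }
    const double* wp = &m.W[(size_t)p * m.dim];
    double dec = 0.0;
    for (int j = 0; j < m.dim; ++j) dec += wp[j] * xi[j];
    if (dec > 0) { votes[m.pa[p]]++; score[m.pa[p]] += dec; }
    else         { votes[m.pb[p]]++; score[m.pb[p]] -= dec; }
  }
  int best = 0;
  for (int c = 1; c < m.nclass; ++c) {
    if (votes[c] > votes[best] ||
        (votes[c] == votes[best] && score[c] > score[best]))
      best = c;
  }
  return best;
}

// [[Rcpp::export(name = ".ovo_train_cpp")]]
List ovo_train_cpp(NumericMatrix X, IntegerVector y, int nclass,
                   double C, int max_iter, double tol) {
  int n = X.nrow(), d = X.ncol(), dim = d + 1;
  std::vector<double> xs((size_t)n * dim);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xs[(size_t)i * dim + j] = X(i, j);
    xs[(size_t)i * dim + d] = 1.0;
  }
  std::vector<int> yy(y.begin(), y.end());
  OvoModel m;
  ovo_fit(xs, yy, n, dim, nclass, C, max_iter, tol, m);
  int npairs = (int)m.pa.size();
  NumericMatrix W(dim, npairs);
  IntegerMatrix pairs(2, npairs);
  IntegerVector cvote(npairs), iters(npairs);
  for (int p = 0; p < npairs; ++p) {
    for (int j = 0; j < dim; ++j) W(j, p) = m.W[(size_t)p * dim + j];
    pairs(0, p) = m.pa[p]; pairs(1, p) = m.pb[p];
    cvote[p] = m.const_vote[p]; iters[p] = m.iters[p];
  }
  return List::create(_["W"] = W, _["pairs"] = pairs,
                      _["const_vote"] = cvote, _["iterations"] = iters);
}

// [[Rcpp::export(name = ".ovo_predict_cpp")]]
IntegerVector ovo_predict_cpp(NumericMatrix W, IntegerMatrix pairs,
                              IntegerVector const_vote, int nclass,
                              NumericMatrix X) {
  int n = X.nrow(), d = X.ncol(), dim = d + 1, npairs = W.ncol();
  OvoModel m;
  m.nclass = nclass; m.dim = dim;
  m.W.assign((size_t)dim * npairs, 0.0);
  for (int p = 0; p < npairs; ++p) {
    m.pa.push_back(pairs(0, p)); m.pb.push_back(pairs(1, p));
    m.const_vote.push_back(const_vote[p]);
    for (int j = 0; j < dim; ++j) m.W[(size_t)p * dim + j] = W(j, p);
  }
  IntegerVector out(n);
  std::vector<double> xi((size_t)dim);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xi[j] = X(i, j);
    xi[d] = 1.0;
    out[i] = ovo_vote(m, xi.data());
  }
  return out;
}

// Cross-validated predictions.  folds is an n x repeats matrix of fold ids
// (1..k); for each repeat and fold, per-feature standardisation (mean /
// population sd, sd <= 0 guarded to 1) is fitted on the training rows only,
// a one-vs-one linear SVM is trained and the left-out rows are predicted.
// Returns the n x repeats matrix of predicted class indices (0-based).
// [[Rcpp::export(name = ".cv_predict_cpp")]]
IntegerMatrix cv_predict_cpp(NumericMatrix X, IntegerVector y,
                             IntegerMatrix folds, int nclass,
                             double C, int max_iter, double tol) {
  int n = X.nrow(), d = X.ncol(), dim = d + 1;
  int repeats = folds.ncol();
  IntegerMatrix preds(n, repeats);
  std::vector<int> yy(y.begin(), y.end());
  std::vector<double> xs;
  std::vector<int> ytr, tr_rows, te_rows;
  std::vector<double> mu((size_t)d), sd((size_t)d), xi((size_t)dim);
  for (int r = 0; r < repeats; ++r) {
    int kf = 0;
    for (int i = 0; i < n; ++i) kf = std::max(kf, folds(i, r));
    for (int f = 1; f <= kf; ++f) {
      tr_rows.clear(); te_rows.clear();
      for (int i = 0; i < n; ++i)
        (folds(i, r) == f ? te_rows : tr_rows).push_back(i);
      if (te_rows.empty()) continue;
      int ntr = (int)tr_rows.size();
      for (int j = 0; j < d; ++j) {
        double s = 0.0;
        for (int i : tr_rows) s += X(i, j);
        mu[j] = s / ntr;
        double v = 0.0;
        for (int i : tr_rows) { double e = X(i, j) - mu[j]; v += e * e; }
        v /= ntr;
        sd[j] = v > 0.0 ? std::sqrt(v) : 1.0;
      }
      xs.assign((size_t)ntr * dim, 0.0);
      ytr.clear();
      for (int ii = 0; ii < ntr; ++ii) {
        int i = tr_rows[ii];
        for (int j = 0; j < d; ++j)
          xs[(size_t)ii * dim + j] = (X(i, j) - mu[j]) / sd[j];
        xs[(size_t)ii * dim + d] = 1.0;
        ytr.push_back(yy[i]);
      }
      OvoModel m;
      ovo_fit(xs, ytr, ntr, dim, nclass, C, max_iter, tol, m);
      for (int i : te_rows) {
        for (int j = 0; j < d; ++j) xi[j] = (X(i, j) - mu[j]) / sd[j];
        xi[d] = 1.0;
        preds(i, r) = ovo_vote(m, xi.data());
      }
    }
  }
  return preds;
}
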