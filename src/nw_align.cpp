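#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment. A gap of length l costs open + ext * l.
// Three-state DP (M: diagonal, X: gap in b / consume a, Y: gap in a /
// consume b) with deterministic traceback preference M > X > Y.
//
// free_ends = false: global alignment, end gaps charged; identity is
//   matches / total alignment columns (end-gap columns included).
// free_ends = true: overlap (ends-free) alignment; identity is matches /
//   columns of the aligned core, terminal overhangs excluded.

static const double NEG = -1e30;

struct AlnResult {
  double score;
  int matches;
  int columns;
};

// workspace reused across pairs to avoid per-alignment allocation churn
struct AlignWorkspace {
  std::vector<double> M, X, Y;
  std::vector<signed char> tM, tX, tY;
  void reserve(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells);
      X.resize(cells);
      Y.resize(cells);
      tM.resize(cells);
      tX.resize(cells);
      tY.resize(cells);
    }
  }
};

// canonicalise argument order so the reported identity is symmetric in its
// arguments even when co-optimal alignments with different match counts
// exist (the traceback preference would otherwise pick order-dependent ones)
static AlnResult align_pair_sym(const std::string &a, const std::string &b,
                                double match, double mismatch, double open,
                                double ext, bool free_ends,
                                AlignWorkspace &ws);

static AlnResult align_pair(const std::string &a, const std::string &b,
                            double match, double mismatch, double open,
                            double ext, bool free_ends, AlignWorkspace &ws) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  const size_t cells = (size_t)(n + 1) * W;
  ws.reserve(cells);
  double *M = ws.M.data(), *X = ws.X.data(), *Y = ws.Y.data();
  signed char *tM = ws.tM.data(), *tX = ws.tX.data(), *tY = ws.tY.data();

  M[0] = 0.0;
  X[0] = Y[0] = NEG;
  for (int i = 1; i <= n; ++i) {
    M[i * W] = Y[i * W] = NEG;
    X[i * W] = free_ends ? 0.0 : -(open + ext * i);
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M[j] = X[j] = NEG;
    Y[j] = free_ends ? 0.0 : -(open + ext * j);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    const int row = i * W, prow = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const int c = row + j, d = prow + (j - 1), u = prow + j, l = row + (j - 1);
      const double s = (ai == b[j - 1]) ? match : mismatch;
      double best = M[d];
      signed char who = 0;
      if (X[d] > best) { best = X[d]; who = 1; }
      if (Y[d] > best) { best = Y[d]; who = 2; }
      M[c] = best + s;
      tM[c] = who;

      best = M[u] - open - ext;
      who = 0;
      if (X[u] - ext > best) { best = X[u] - ext; who = 1; }
      if (Y[u] - open - ext > best) { best = Y[u] - open - ext; who = 2; }
      X[c] = best;
      tX[c] = who;

      best = M[l] - open - ext;
      who = 0;
      if (X[l] - open - ext > best) { best = X[l] - open - ext; who = 1; }
      if (Y[l] - ext > best) { best = Y[l] - ext; who = 2; }
      Y[c] = best;
      tY[c] = who;
    }
  }

  int ei = n, ej = m, estate = 0;
  double score;
  if (!free_ends) {
    score = M[n * W + m];
    estate = 0;
    if (X[n * W + m] > score) { score = X[n * W + m]; estate = 1; }
    if (Y[n * W + m] > score) { score = Y[n * W + m]; estate = 2; }
  } else {
    score = NEG;
    for (int i = 0; i <= n; ++i) {
      const double vals[3] = {M[i * W + m], X[i * W + m], Y[i * W + m]};
      for (int s = 0; s < 3; ++s) {
        if (vals[s] > score) { score = vals[s]; ei = i; ej = m; estate = s; }
      }
    }
    for (int j = 0; j <= m; ++j) {
      const double vals[3] = {M[n * W + j], X[n * W + j], Y[n * W + j]};
      for (int s = 0; s < 3; ++s) {
        if (vals[s] > score) { score = vals[s]; ei = n; ej = j; estate = s; }
      }
    }
  }

  int i = ei, j = ej, state = estate;
  int matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (free_ends && ((state == 1 && j == 0) || (state == 2 && i == 0))) {
      break; // leading overhang: outside the aligned core
    }
    const int c = i * W + j;
    if (state == 0) {
      const signed char who = tM[c];
      if (a[i - 1] == b[j - 1]) ++matches;
      ++columns;
      --i;
      --j;
      state = who;
    } else if (state == 1) {
      const signed char who = tX[c];
      ++columns;
      --i;
      state = who;
    } else {
      const signed char who = tY[c];
      ++columns;
      --j;
      state = who;
    }
  }

  AlnResult r;
  r.score = score;
  r.matches = matches;
  r.columns = columns;
  return r;
}

static AlnResult align_pair_sym(const std::string &a, const std::string &b,
                                double match, double mismatch, double open,
                                double ext, bool free_ends,
                                AlignWorkspace &ws) {
  if (a <= b) return align_pair(a, b, match, mismatch, open, ext, free_ends, ws);
  return align_pair(b, a, match, mismatch, open, ext, free_ends, ws);
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(CharacterVector a, std::string b, double match = 1.0,
              double mismatch = -1.0, double gap_open = 2.0,
              double gap_ext = 0.5, bool free_ends = false) {
  const int n = a.size();
  NumericVector score(n), identity(n);
  IntegerVector matches(n), columns(n);
  AlignWorkspace ws;
  for (int t = 0; t < n; ++t) {
    const std::string as = Rcpp::as<std::string>(a[t]);
    AlnResult r = align_pair_sym(as, b, match, mismatch, gap_open, gap_ext,
                                 free_ends, ws);
    score[t] = r.score;
    matches[t] = r.matches;
    columns[t] = r.columns;
    identity[t] = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = columns, _["identity"] = identity);
}

// Greedy-scan helper: 1-based index of the first centroid whose identity to
// `query` reaches `threshold`, or 0. A cheap length-ratio bound
// (identity <= min_len / max_len, since columns >= max and matches <= min)
// skips hopeless pairs without changing the result.
// [[Rcpp::export(name = ".nw_first_hit")]]
int nw_first_hit(CharacterVector centroids, std::string query,
                 double threshold, double match = 1.0, double mismatch = -1.0,
                 double gap_open = 2.0, double gap_ext = 0.5,
                 bool free_ends = false) {
  AlignWorkspace ws;
  const int nq = query.size();
  for (int t = 0; t < centroids.size(); ++t) {
    const std::string c = Rcpp::as<std::string>(centroids[t]);
    const int nc = c.size();
    if (!free_ends) {
      const double bound =
          (double)std::min(nc, nq) / (double)std::max(nc, nq);
      if (bound < threshold) continue;
    }
    AlnResult r = align_pair_sym(c, query, match, mismatch, gap_open,
                                 gap_ext, free_ends, ws);
    const double ident = r.columns > 0 ? (double)r.matches / r.columns : 0.0;
    if (ident >= threshold) return t + 1;
  }
  return 0;
}
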