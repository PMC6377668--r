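#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// Strategy codes; must match match(label, agent_strategies()) - 1 on the R side.
enum Strat { HEIDER = 0, FRIEND = 1, ENEMY = 2, INCOMPLETE = 3, DEFECTOR = 4 };

// Weighted-opinion relationship score of agent x toward partner y:
// sum over opinion holders i != y of w(s_xi) * s_iy.  `row_x` holds the
// focal agent's relationships s_xi, `col_y` the opinions s_iy, both as
// contiguous length-n buffers.  The partner's self-opinion (i == y, weight
// s_xy on s_yy = 1) is excluded so the focal agent's own opinion enters
// exactly once, through the i == x term (s_xx = 1).  Enemy-focused agents
// keep the own-opinion weight of 1: direct experience is not "the opinion
// of a friend".
double score_raw(const double* row_x, const double* col_y, int n, int x,
                 int y, int strat) {
  double rs = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == y) continue;
    const double sxi = row_x[i], siy = col_y[i];
    double w = 0.0;
    switch (strat) {
      case HEIDER:
        w = sxi;
        break;
      case FRIEND:
        w = sxi > 0.0 ? sxi : 0.0;
        break;
      case ENEMY:
        w = (i == x) ? 1.0 : (sxi < 0.0 ? sxi : 0.0);
        break;
      case INCOMPLETE:
        if (sxi < 0.0 && siy < 0.0) continue;  // "enemy of an enemy" suppressed
        w = sxi;
        break;
      default:
        stop("defectors do not compute relationship scores");
    }
    rs += w * siy;
  }
  return rs;
}

inline double clip1(double v) {
  return v > 1.0 ? 1.0 : (v < -1.0 ? -1.0 : v);
}

// uniform integer on 0..m-1 from R's RNG
inline int rand_int(int m) {
  int v;
  do {
    v = static_cast<int>(unif_rand() * m);
  } while (v >= m);
  return v;
}

void shuffle_agents(std::vector<int>& idx) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    const int j = rand_int(i + 1);
    std::swap(idx[i], idx[j]);
  }
}

// Memory constraint on one relationship row (contiguous length-n buffer,
// diagonal position x untouched): keep the k off-diagonal entries of
// largest magnitude ("best friends and worst enemies"), forget the rest to
// neutral 0.  Exact-magnitude ties at the retention boundary are resolved
// uniformly at random.  A zero threshold means every non-zero entry
// already fits in memory (forgetting a neutral opinion is a no-op).
void forget_raw(double* row, int n, int x, int k) {
  if (k >= n - 1) return;
  std::vector<double> mag;
  mag.reserve(n - 1);
  for (int i = 0; i < n; ++i)
    if (i != x) mag.push_back(std::fabs(row[i]));
  std::vector<double> srt(mag);
  std::nth_element(srt.begin(), srt.begin() + (k - 1), srt.end(),
                   std::greater<double>());
  const double thr = srt[k - 1];
  if (thr == 0.0) return;
  int ngt = 0, neq = 0;
  for (double v : mag) {
    if (v > thr) ++ngt;
    else if (v == thr) ++neq;
  }
  const int keep_eq = k - ngt;
  std::vector<int> kept;
  const bool random_ties = neq > keep_eq;
  if (random_ties) {
    for (int i = 0; i < n; ++i)
      if (i != x && std::fabs(row[i]) == thr) kept.push_back(i);
    for (int j = 0; j < keep_eq; ++j) {
      const int pick = j + rand_int(static_cast<int>(kept.size()) - j);
      std::swap(kept[j], kept[pick]);
    }
    kept.resize(keep_eq);
  }
  for (int i = 0; i < n; ++i) {
    if (i == x) continue;
    const double v = std::fabs(row[i]);
    if (v < thr) {
      row[i] = 0.0;
    } else if (v == thr && random_ties &&
               std::find(kept.begin(), kept.end(), i) == kept.end()) {
      row[i] = 0.0;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
double cpp_relationship_score(const NumericMatrix& S, int x, int y,
                              int strat) {
  const int n = S.nrow();
  std::vector<double> row_x(n), col_y(n);
  for (int i = 0; i < n; ++i) {
    row_x[i] = S(x, i);
    col_y[i] = S(i, y);
  }
  return score_raw(row_x.data(), col_y.data(), n, x, y, strat);
}

// [[Rcpp::export]]
NumericMatrix cpp_forget_row(const NumericMatrix& S, int x, int k) {
  NumericMatrix out = clone(S);
  const int n = out.nrow();
  std::vector<double> row(n);
  for (int i = 0; i < n; ++i) row[i] = out(x, i);
  forget_raw(row.data(), n, x, k);
  for (int i = 0; i < n; ++i) out(x, i) = row[i];
  return out;
}

// Run n_iter iterations of the three-stage loop (random matching,
// simultaneous action choice from the iteration-start snapshot,
// relationship updating, then the memory constraint on every row).
// Payoffs accumulate into the returned copy of `payoffs_in`; cooperation
// counts are returned for the whole block.  For odd n the unmatched agent
// idles.  Internally the matrix is held twice (column-major and
// row-major) so both the opinion column of a partner and the relationship
// row of a focal agent are contiguous.
// [[Rcpp::export]]
List cpp_iterate(const NumericMatrix& S_in, const IntegerVector& strategy,
                 const NumericVector& payoffs_in, int n_iter, double r,
                 double temperature, int k, double b, double c,
                 bool normalize_rs) {
  const int n = S_in.nrow();
  // Scol[y * n + i] = s_iy (column-major); Srow[x * n + i] = s_xi
  std::vector<double> Scol(n * n), Srow(n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      Scol[j * n + i] = S_in(i, j);
      Srow[i * n + j] = S_in(i, j);
    }
  NumericVector payoffs = clone(payoffs_in);
  const int npairs = n / 2;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> action(n, 0);
  double coop = 0.0, total = 0.0;
  const bool limited = k < n - 1;

  for (int t = 0; t < n_iter; ++t) {
    shuffle_agents(idx);
    // stage 2: all decisions from the current snapshot
    for (int p = 0; p < npairs; ++p) {
      for (int side = 0; side < 2; ++side) {
        const int a = idx[2 * p + side];
        const int partner = idx[2 * p + 1 - side];
        if (strategy[a] == DEFECTOR) {
          action[a] = 0;
          continue;
        }
        double rs = score_raw(&Srow[a * n], &Scol[partner * n], n, a,
                              partner, strategy[a]);
        if (normalize_rs) rs /= (n - 1);
        const double p_c = 1.0 / (1.0 + std::exp(-rs / temperature));
        action[a] = (unif_rand() < p_c) ? 1 : 0;
      }
    }
    // stage 3: payoffs and relationship updates (disjoint pairs commute)
    for (int p = 0; p < npairs; ++p) {
      const int x = idx[2 * p], y = idx[2 * p + 1];
      const int ax = action[x], ay = action[y];
      payoffs[x] += b * ay - c * ax;
      payoffs[y] += b * ax - c * ay;
      coop += ax + ay;
      total += 2.0;
      if (strategy[x] != DEFECTOR) {
        double v = Srow[x * n + y];
        if (ay == 0) v = clip1(v - r);            // partner defected
        else if (ax == 1) v = clip1(v + r);       // mutual cooperation
        Srow[x * n + y] = v;
        Scol[y * n + x] = v;
      }
      if (strategy[y] != DEFECTOR) {
        double v = Srow[y * n + x];
        if (ax == 0) v = clip1(v - r);
        else if (ay == 1) v = clip1(v + r);
        Srow[y * n + x] = v;
        Scol[x * n + y] = v;
      }
    }
    if (limited) {
      for (int a = 0; a < n; ++a) {
        forget_raw(&Srow[a * n], n, a, k);
        for (int i = 0; i < n; ++i) Scol[i * n + a] = Srow[a * n + i];
      }
    }
  }

  NumericMatrix S(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) S(i, j) = Scol[j * n + i];
  return List::create(_["S"] = S, _["payoffs"] = payoffs, _["n_coop"] = coop,
                      _["n_actions"] = total);
}
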