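// Compiled inner loop of the volumetric denoiser: for each reference
// cube, match the m nearest cubes in an L^3 window, stack them into a
// p x p x p x m tensor, truncate its HOSVD at the adaptive multilinear
// rank given by the log-penalty threshold on mode singular values, and
// accumulate the projected cubes into numerator/denominator volumes.
//
// Unfolding convention matches the R layer: rows indexed by the mode,
// columns enumerate remaining indices with the lowest-numbered index
// varying fastest (plain column-major order when mode == 1).

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Corner { int x, y, z; };

arma::mat unfold4(const std::vector<double>& t, const int d[4], int mode) {
  int others[3];
  int oi = 0;
  for (int k = 0; k < 4; ++k) if (k != mode) others[oi++] = k;
  const int nc = d[others[0]] * d[others[1]] * d[others[2]];
  arma::mat M(d[mode], nc);
  int idx[4];
  int col = 0;
  for (int c2 = 0; c2 < d[others[2]]; ++c2)
    for (int c1 = 0; c1 < d[others[1]]; ++c1)
      for (int c0 = 0; c0 < d[others[0]]; ++c0) {
        idx[others[0]] = c0;
        idx[others[1]] = c1;
        idx[others[2]] = c2;
        for (int r = 0; r < d[mode]; ++r) {
          idx[mode] = r;
          M(r, col) = t[idx[0] + (size_t)d[0] *
                        (idx[1] + (size_t)d[1] * (idx[2] + (size_t)d[2] * idx[3]))];
        }
        ++col;
      }
  return M;
}

void fold4(const arma::mat& M, const int d[4], int mode, std::vector<double>& t) {
  int others[3];
  int oi = 0;
  for (int k = 0; k < 4; ++k) if (k != mode) others[oi++] = k;
  int idx[4];
  int col = 0;
  for (int c2 = 0; c2 < d[others[2]]; ++c2)
    for (int c1 = 0; c1 < d[others[1]]; ++c1)
      for (int c0 = 0; c0 < d[others[0]]; ++c0) {
        idx[others[0]] = c0;
        idx[others[1]] = c1;
        idx[others[2]] = c2;
        for (int r = 0; r < d[mode]; ++r) {
          idx[mode] = r;
          t[idx[0] + (size_t)d[0] *
            (idx[1] + (size_t)d[1] * (idx[2] + (size_t)d[2] * idx[3]))] = M(r, col);
        }
        ++col;
      }
}

// positions 0, stride, 2*stride, ..., with the last snapped to dim - p
std::vector<int> axis_positions(int dim, int p, int stride) {
  std::vector<int> pos;
  for (int c = 0; c + p <= dim; c += stride) pos.push_back(c);
  if (pos.back() != dim - p) pos.push_back(dim - p);
  return pos;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_denoise_pass(const arma::cube& vol, int p, int m, int L,
                            int stride, double lam, int match_stride) {
  const int n1 = vol.n_rows, n2 = vol.n_cols, n3 = vol.n_slices;
  if (p > n1 || p > n2 || p > n3)
    Rcpp::stop("cube edge `p` exceeds a volume dimension");
  if (L % 2 != 1) Rcpp::stop("`L` must be odd");
  const int half = (L - 1) / 2;
  const int pc = p * p * p;

  arma::cube num(n1, n2, n3, arma::fill::zeros);
  arma::cube den(n1, n2, n3, arma::fill::zeros);
  double rank_sum[4] = {0, 0, 0, 0};
  long n_groups = 0;

  const std::vector<int> pos1 = axis_positions(n1, p, stride);
  const std::vector<int> pos2 = axis_positions(n2, p, stride);
  const std::vector<int> pos3 = axis_positions(n3, p, stride);

  std::vector<Corner> cand;
  std::vector<double> dist;
  std::vector<int> ord;
  arma::vec refv(pc);
  std::vector<double> group, work;
  arma::mat U, V;
  arma::vec s;

  for (int r1 : pos1) for (int r2 : pos2) for (int r3 : pos3) {
    // reference cube, column-major over (p, p, p)
    {
      int q = 0;
      for (int k = 0; k < p; ++k)
        for (int j = 0; j < p; ++j)
          for (int i = 0; i < p; ++i)
            refv[q++] = vol(r1 + i, r2 + j, r3 + k);
    }

    // candidates inside the clipped window, lexicographic corner order;
    // the reference is entered first with distance -1 so it always wins
    cand.clear();
    dist.clear();
    cand.push_back({r1, r2, r3});
    dist.push_back(-1.0);
    const int lo1 = std::max(0, r1 - half), hi1 = std::min(n1 - p, r1 + half);
    const int lo2 = std::max(0, r2 - half), hi2 = std::min(n2 - p, r2 + half);
    const int lo3 = std::max(0, r3 - half), hi3 = std::min(n3 - p, r3 + half);
    for (int c1 = lo1; c1 <= hi1; c1 += match_stride)
      for (int c2 = lo2; c2 <= hi2; c2 += match_stride)
        for (int c3 = lo3; c3 <= hi3; c3 += match_stride) {
          if (c1 == r1 && c2 == r2 && c3 == r3) continue;
          double d = 0;
          int q = 0;
          for (int k = 0; k < p; ++k)
            for (int j = 0; j < p; ++j)
              for (int i = 0; i < p; ++i) {
                const double e = vol(c1 + i, c2 + j, c3 + k) - refv[q++];
                d += e * e;
              }
          cand.push_back({c1, c2, c3});
          dist.push_back(d);
        }
    const int ncand = (int)cand.size();
    const int k_eff = std::min(m, ncand);
    ord.resize(ncand);
    for (int i = 0; i < ncand; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return dist[a] < dist[b]; });

    // stack the group tensor (p, p, p, k_eff), reference in slot 0
    const int d4[4] = {p, p, p, k_eff};
    group.assign((size_t)pc * k_eff, 0.0);
    for (int jj = 0; jj < k_eff; ++jj) {
      const Corner& c = cand[ord[jj]];
      int q = 0;
      for (int k = 0; k < p; ++k)
        for (int j = 0; j < p; ++j)
          for (int i = 0; i < p; ++i)
            group[(size_t)jj * pc + q++] = vol(c.x + i, c.y + j, c.z + k);
    }

    // per-mode SVD, adaptive rank, projection onto retained factors
    work = group;
    int ranks[4];
    for (int mode = 0; mode < 4; ++mode) {
      arma::mat M = unfold4(group, d4, mode);
      if (!arma::svd_econ(U, s, V, M, "left"))
        Rcpp::stop("SVD failed in group at corner (%d, %d, %d)", r1, r2, r3);
      int r = 0;
      for (arma::uword i = 0; i < s.n_elem; ++i) if (s[i] > lam) ++r;
      if (r < 1) r = 1;
      if (r > (int)U.n_cols) r = (int)U.n_cols;
      ranks[mode] = r;
      rank_sum[mode] += r;
      if (r < d4[mode]) {
        const arma::mat Ur = U.cols(0, r - 1);
        arma::mat W = unfold4(work, d4, mode);
        W = Ur * (Ur.t() * W);
        fold4(W, d4, mode, work);
      }
    }
    (void)ranks;

    // aggregate
    for (int jj = 0; jj < k_eff; ++jj) {
      const Corner& c = cand[ord[jj]];
      int q = 0;
      for (int k = 0; k < p; ++k)
        for (int j = 0; j < p; ++j)
          for (int i = 0; i < p; ++i) {
            num(c.x + i, c.y + j, c.z + k) += work[(size_t)jj * pc + q];
            den(c.x + i, c.y + j, c.z + k) += 1.0;
            ++q;
          }
    }
    ++n_groups;
    if (n_groups % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  if (den.min() <= 0)
    Rcpp::stop("some voxels received no cube contribution");
  arma::cube out = num / den;
  return Rcpp::List::create(
      Rcpp::Named("volume") = out,
      Rcpp::Named("n_groups") = (double)n_groups,
      Rcpp::Named("mean_ranks") = Rcpp::NumericVector::create(
          rank_sum[0] / n_groups, rank_sum[1] / n_groups,
          rank_sum[2] / n_groups, rank_sum[3] / n_groups));
}
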