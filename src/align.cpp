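// Affine-gap global/local alignment over profile-profile column scores,
// and the all-pairs combined-score matrices used by the noise reducer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Gotoh affine-gap alignment on a precomputed column-pair score matrix S
// (n x m). A gap of length L costs open + (L-1) * extend; switching gap
// type opens a new gap. Global mode penalises end gaps; local mode floors
// at zero and takes the best cell.
static double gotoh(const arma::mat& S, double gap_open, double gap_extend,
                    bool local) {
  const arma::uword n = S.n_rows, m = S.n_cols;
  arma::mat M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  M.fill(NEG_INF); Ix.fill(NEG_INF); Iy.fill(NEG_INF);
  M(0, 0) = 0.0;
  if (!local) {
    for (arma::uword i = 1; i <= n; ++i)
      Ix(i, 0) = -(gap_open + (i - 1) * gap_extend);
    for (arma::uword j = 1; j <= m; ++j)
      Iy(0, j) = -(gap_open + (j - 1) * gap_extend);
  } else {
    for (arma::uword i = 0; i <= n; ++i) M(i, 0) = 0.0;
    for (arma::uword j = 0; j <= m; ++j) M(0, j) = 0.0;
  }
  double best = 0.0;
  for (arma::uword i = 1; i <= n; ++i) {
    for (arma::uword j = 1; j <= m; ++j) {
      double diag = max3(M(i - 1, j - 1), Ix(i - 1, j - 1), Iy(i - 1, j - 1));
      double mm = diag + S(i - 1, j - 1);
      if (local && mm < 0.0) mm = 0.0;
      M(i, j) = mm;
      Ix(i, j) = max3(M(i - 1, j) - gap_open,
                      Ix(i - 1, j) - gap_extend,
                      Iy(i - 1, j) - gap_open);
      Iy(i, j) = max3(M(i, j - 1) - gap_open,
                      Ix(i, j - 1) - gap_open,
                      Iy(i, j - 1) - gap_extend);
      if (local && M(i, j) > best) best = M(i, j);
    }
  }
  if (local) return best;
  return max3(M(n, m), Ix(n, m), Iy(n, m));
}

// [[Rcpp::export]]
double affine_align_cpp(const arma::mat& S, double gap_open,
                        double gap_extend, bool local) {
  return gotoh(S, gap_open, gap_extend, local);
}

// Column-pair score matrix between two profiles:
// P(i,j) = 0.5 * (fA_i . sB_j + fB_j . sA_i)
static arma::mat ppa_matrix(const arma::mat& Fa, const arma::mat& Sa,
                            const arma::mat& Fb, const arma::mat& Sb) {
  return 0.5 * (Fa * Sb.t() + Sa * Fb.t());
}

// [[Rcpp::export]]
arma::mat ppa_matrix_cpp(const arma::mat& Fa, const arma::mat& Sa,
                         const arma::mat& Fb, const arma::mat& Sb) {
  return ppa_matrix(Fa, Sa, Fb, Sb);
}

static double blosum_window(const arma::imat& pep7, arma::uword a,
                            arma::uword b, const arma::mat& subm) {
  double s = 0.0;
  for (arma::uword k = 0; k < pep7.n_cols; ++k)
    s += subm(pep7(a, k), pep7(b, k));
  return s;
}

static inline double combine(double sb, double sp) {
  return (sb > 0.0 && sp > 0.0) ? sb * sp : 0.0;
}

// All-pairs s_blosum / s_profile / s_combined for one peptide collection.
// freq, score: lists of L x 20 matrices; pep7: n x 7 0-based indices into
// subm (21 x 21, X = 20).
// [[Rcpp::export]]
List pairwise_scores_cpp(List freq, List score, const arma::imat& pep7,
                         const arma::mat& subm, double gap_open,
                         double gap_extend, bool local) {
  const int n = freq.size();
  std::vector<arma::mat> F(n), S(n);
  for (int i = 0; i < n; ++i) {
    F[i] = as<arma::mat>(freq[i]);
    S[i] = as<arma::mat>(score[i]);
  }
  arma::mat sb(n, n), sp(n, n), sc(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double b = blosum_window(pep7, i, j, subm);
      double p = gotoh(ppa_matrix(F[i], S[i], F[j], S[j]),
                       gap_open, gap_extend, local);
      sb(i, j) = sb(j, i) = b;
      sp(i, j) = sp(j, i) = p;
      sc(i, j) = sc(j, i) = combine(b, p);
    }
  }
  return List::create(Named("s_blosum") = sb, Named("s_profile") = sp,
                      Named("s_combined") = sc);
}

// Query-vs-reference scores (rows = queries, cols = reference peptides).
// [[Rcpp::export]]
List query_scores_cpp(List qfreq, List qscore, const arma::imat& qpep7,
                      List rfreq, List rscore, const arma::imat& rpep7,
                      const arma::mat& subm, double gap_open,
                      double gap_extend, bool local) {
  const int nq = qfreq.size(), nr = rfreq.size();
  std::vector<arma::mat> Fq(nq), Sq(nq), Fr(nr), Sr(nr);
  for (int i = 0; i < nq; ++i) {
    Fq[i] = as<arma::mat>(qfreq[i]);
    Sq[i] = as<arma::mat>(qscore[i]);
  }
  for (int j = 0; j < nr; ++j) {
    Fr[j] = as<arma::mat>(rfreq[j]);
    Sr[j] = as<arma::mat>(rscore[j]);
  }
  arma::mat sb(nq, nr), sp(nq, nr), sc(nq, nr);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      double b = 0.0;
      for (arma::uword k = 0; k < qpep7.n_cols; ++k)
        b += subm(qpep7(i, k), rpep7(j, k));
      double p = gotoh(ppa_matrix(Fq[i], Sq[i], Fr[j], Sr[j]),
                       gap_open, gap_extend, local);
      sb(i, j) = b;
      sp(i, j) = p;
      sc(i, j) = combine(b, p);
    }
  }
  return List::create(Named("s_blosum") = sb, Named("s_profile") = sp,
                      Named("s_combined") = sc);
}
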