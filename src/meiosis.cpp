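#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One meiotic gamete from a diploid parent, sampled at the mapped loci only.
// Crossing over follows the Haldane (no-interference) model, realised as a
// Markov phase walk: at the first locus of each linkage group the parental
// phase is drawn with probability 1/2; between consecutive loci the phase
// switches with the pre-computed recombination probability r = (1-e^{-2d})/2.
// With no interference this is exactly the marginal law of the Poisson
// crossover process at the loci.
static inline void one_gamete(const int* h1, const int* h2, const int* first,
                              const double* r, const int L, int* out) {
  int phase = 0;
  for (int l = 0; l < L; ++l) {
    if (first[l]) {
      phase = (unif_rand() < 0.5) ? 1 : 0;
    } else if (unif_rand() < r[l]) {
      phase = 1 - phase;
    }
    out[l] = phase ? h2[l] : h1[l];
  }
}

// Gametes from parents of a population. H1/H2 are L x n haplotype matrices
// (0 = founder allele A, 1 = founder allele B); parent gives, per requested
// gamete, the 1-based column of the contributing parent.
// [[Rcpp::export]]
IntegerMatrix cpp_meiosis(const IntegerMatrix& H1, const IntegerMatrix& H2,
                          const IntegerVector& parent,
                          const IntegerVector& first, const NumericVector& r) {
  const int L = H1.nrow();
  const int n = parent.size();
  IntegerMatrix out(L, n);
  const int* p1 = INTEGER(H1);
  const int* p2 = INTEGER(H2);
  for (int i = 0; i < n; ++i) {
    const int p = parent[i] - 1;
    one_gamete(p1 + (R_xlen_t)p * L, p2 + (R_xlen_t)p * L,
               first.begin(), r.begin(), L, &out(0, i));
  }
  return out;
}

// Advance every individual of a population by `rounds` generations of
// single-seed-descent selfing (one offspring per individual per round).
// [[Rcpp::export]]
List cpp_self_rounds(const IntegerMatrix& H1, const IntegerMatrix& H2,
                     const IntegerVector& first, const NumericVector& r,
                     const int rounds) {
  const int L = H1.nrow();
  const int n = H1.ncol();
  IntegerMatrix A = clone(H1), B = clone(H2);
  IntegerMatrix A2(L, n), B2(L, n);
  for (int t = 0; t < rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      one_gamete(&A(0, i), &B(0, i), first.begin(), r.begin(), L, &A2(0, i));
      one_gamete(&A(0, i), &B(0, i), first.begin(), r.begin(), L, &B2(0, i));
    }
    std::swap(A, A2);
    std::swap(B, B2);
  }
  return List::create(_["hap1"] = A, _["hap2"] = B);
}

// Simulate F2 progeny of one cross and score their prediction values.
// n_f1 F1 genotypes are drawn from the parent pair; each is selfed
// n_f2 times; PV = mu + sum_j beta_j * code_j with code = 1 - g1 - g2.
static void progeny_pvs(const int* a1, const int* a2, const int* b1,
                        const int* b2, const int* first, const double* r,
                        const double* beta, const double mu, const int L,
                        const int n_f1, const int n_f2, double* out,
                        int* geno) {
  std::vector<int> f1a(L), f1b(L), g1(L), g2(L);
  int idx = 0;
  for (int i = 0; i < n_f1; ++i) {
    one_gamete(a1, a2, first, r, L, f1a.data());
    one_gamete(b1, b2, first, r, L, f1b.data());
    for (int j = 0; j < n_f2; ++j) {
      one_gamete(f1a.data(), f1b.data(), first, r, L, g1.data());
      one_gamete(f1a.data(), f1b.data(), first, r, L, g2.data());
      double pv = mu;
      for (int l = 0; l < L; ++l) pv += beta[l] * (1 - g1[l] - g2[l]);
      out[idx] = pv;
      if (geno != nullptr) {
        int* col = geno + (R_xlen_t)idx * L;
        for (int l = 0; l < L; ++l) col[l] = 1 - g1[l] - g2[l];
      }
      ++idx;
    }
  }
}

// [[Rcpp::export]]
List cpp_cross_progeny(const IntegerVector& a1, const IntegerVector& a2,
                       const IntegerVector& b1, const IntegerVector& b2,
                       const IntegerVector& first, const NumericVector& r,
                       const NumericVector& beta, const double mu,
                       const int n_f1, const int n_f2,
                       const bool return_genotypes) {
  const int L = a1.size();
  const int tot = n_f1 * n_f2;
  NumericVector pv(tot);
  if (return_genotypes) {
    IntegerMatrix G(L, tot);
    progeny_pvs(a1.begin(), a2.begin(), b1.begin(), b2.begin(), first.begin(),
                r.begin(), beta.begin(), mu, L, n_f1, n_f2, REAL(pv),
                INTEGER(G));
    return List::create(_["pv"] = pv, _["genotypes"] = G);
  }
  progeny_pvs(a1.begin(), a2.begin(), b1.begin(), b2.begin(), first.begin(),
              r.begin(), beta.begin(), mu, L, n_f1, n_f2, REAL(pv), nullptr);
  return List::create(_["pv"] = pv);
}

// Score every unordered parent pair (i < j) of a population: simulate
// n_f1 x n_f2 F2 progeny, record the mean PV of the k best (largest if
// high, smallest otherwise) and the variance of all progeny PVs.
// Returns an n*(n-1)/2 x 4 matrix: parent i, parent j, score, variance.
// [[Rcpp::export]]
NumericMatrix cpp_rank_crosses(const IntegerMatrix& H1,
                               const IntegerMatrix& H2,
                               const IntegerVector& first,
                               const NumericVector& r,
                               const NumericVector& beta, const double mu,
                               const int n_f1, const int n_f2, const int k,
                               const bool high) {
  const int L = H1.nrow();
  const int n = H1.ncol();
  const int tot = n_f1 * n_f2;
  const R_xlen_t np = (R_xlen_t)n * (n - 1) / 2;
  NumericMatrix out(np, 4);
  std::vector<double> pv(tot);
  const int* p1 = INTEGER(H1);
  const int* p2 = INTEGER(H2);
  R_xlen_t row = 0;
  for (int i = 0; i < n - 1; ++i) {
    const int* a1 = p1 + (R_xlen_t)i * L;
    const int* a2 = p2 + (R_xlen_t)i * L;
    for (int j = i + 1; j < n; ++j) {
      progeny_pvs(a1, a2, p1 + (R_xlen_t)j * L, p2 + (R_xlen_t)j * L,
                  first.begin(), r.begin(), beta.begin(), mu, L, n_f1, n_f2,
                  pv.data(), nullptr);
      double s = 0.0;
      for (int t = 0; t < tot; ++t) s += pv[t];
      const double m = s / tot;
      double ss = 0.0;
      for (int t = 0; t < tot; ++t) {
        const double d = pv[t] - m;
        ss += d * d;
      }
      if (k < tot) {
        if (high)
          std::nth_element(pv.begin(), pv.begin() + k, pv.end(),
                           std::greater<double>());
        else
          std::nth_element(pv.begin(), pv.begin() + k, pv.end());
      }
      double sk = 0.0;
      for (int t = 0; t < k; ++t) sk += pv[t];
      out(row, 0) = i + 1;
      out(row, 1) = j + 1;
      out(row, 2) = sk / k;
      out(row, 3) = tot > 1 ? ss / (tot - 1) : 0.0;
      ++row;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
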