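#include <Rcpp.h>
using namespace Rcpp;

// Exact predicted cross value over the 8 joint origin states (c1, c2, g):
// c1/c2 = active homolog of each parental gamete, g = which progeny
// chromosome the final gamete copies at the current locus. All three switch
// independently between adjacent loci with the local recombination frequency.
// State index s = c1 + 2*c2 + 4*g (each bit in {0,1}).
static double pcv_core(const int* L1, const int* L2, int N, const double* f) {
  double v[8];
  for (int s = 0; s < 8; ++s) {
    int c1 = s & 1, c2 = (s >> 1) & 1, g = (s >> 2) & 1;
    int allele = g == 0 ? L1[0 + N * c1] : L2[0 + N * c2];
    v[s] = allele ? 0.125 : 0.0;
  }
  double w[8];
  for (int i = 1; i < N; ++i) {
    double p = f[i - 1], q = 1.0 - p;
    // mix each bit independently: v <- (q*I + p*Flip_bit) v
    for (int bit = 1; bit <= 4; bit <<= 1) {
      for (int s = 0; s < 8; ++s) w[s] = q * v[s] + p * v[s ^ bit];
      for (int s = 0; s < 8; ++s) v[s] = w[s];
    }
    for (int s = 0; s < 8; ++s) {
      int c1 = s & 1, c2 = (s >> 1) & 1, g = (s >> 2) & 1;
      int allele = g == 0 ? L1[i + N * c1] : L2[i + N * c2];
      if (!allele) v[s] = 0.0;
    }
  }
  double tot = 0.0;
  for (int s = 0; s < 8; ++s) tot += v[s];
  return tot;
}

// [[Rcpp::export]]
double pcv_cpp(IntegerMatrix L1, IntegerMatrix L2, NumericVector f) {
  int N = L1.nrow();
  if (L2.nrow() != N || L1.ncol() != 2 || L2.ncol() != 2)
    stop("genotypes must be N x 2 matrices with matching N");
  if (f.size() != N - 1) stop("f must have length N - 1");
  return pcv_core(INTEGER(L1), INTEGER(L2), N, REAL(f));
}

// PCV for many candidate pairs drawn from one population array (N x 2 x K).
// idx1/idx2 are 0-based member indices.
// [[Rcpp::export]]
NumericVector pcv_pairs_cpp(IntegerVector pop, IntegerVector idx1,
                            IntegerVector idx2, NumericVector f) {
  IntegerVector dims = pop.attr("dim");
  if (dims.size() != 3 || dims[1] != 2) stop("pop must be an N x 2 x K array");
  int N = dims[0], K = dims[2];
  if (f.size() != N - 1) stop("f must have length N - 1");
  int P = idx1.size();
  if (idx2.size() != P) stop("idx1 and idx2 must have equal length");
  const int* base = INTEGER(pop);
  NumericVector out(P);
  for (int j = 0; j < P; ++j) {
    int k1 = idx1[j], k2 = idx2[j];
    if (k1 < 0 || k1 >= K || k2 < 0 || k2 >= K) stop("member index out of range");
    out[j] = pcv_core(base + (R_xlen_t)2 * N * k1, base + (R_xlen_t)2 * N * k2,
                      N, REAL(f));
  }
  return out;
}

static void one_gamete(const int* L, int N, const double* f, int* out) {
  int h = unif_rand() < 0.5 ? 0 : 1;
  out[0] = L[0 + N * h];
  for (int i = 1; i < N; ++i) {
    if (unif_rand() < f[i - 1]) h ^= 1;
    out[i] = L[i + N * h];
  }
}

// K independent gametes from one parent; meiosis is a Markov chain over loci
// with switch probability f[i] between adjacent loci (0.5 across linkage
// groups gives independent assortment).
// [[Rcpp::export]]
IntegerMatrix gametes_cpp(IntegerMatrix L, NumericVector f, int K) {
  int N = L.nrow();
  if (L.ncol() != 2) stop("genotype must be an N x 2 matrix");
  if (f.size() != N - 1) stop("f must have length N - 1");
  if (K < 1) stop("K must be >= 1");
  IntegerMatrix out(N, K);
  for (int k = 0; k < K; ++k) one_gamete(INTEGER(L), N, REAL(f), INTEGER(out) + (R_xlen_t)N * k);
  return out;
}

// One gamete per member of a population array (used by the Monte-Carlo
// oracle: each progeny contributes a single sampled gamete).
// [[Rcpp::export]]
IntegerMatrix gametes_each_cpp(IntegerVector pop, NumericVector f) {
  IntegerVector dims = pop.attr("dim");
  if (dims.size() != 3 || dims[1] != 2) stop("pop must be an N x 2 x K array");
  int N = dims[0], K = dims[2];
  if (f.size() != N - 1) stop("f must have length N - 1");
  IntegerMatrix out(N, K);
  const int* base = INTEGER(pop);
  for (int k = 0; k < K; ++k)
    one_gamete(base + (R_xlen_t)2 * N * k, N, REAL(f), INTEGER(out) + (R_xlen_t)N * k);
  return out;
}
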