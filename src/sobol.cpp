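#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Gray-code Sobol sequence generator with Joe-Kuo direction numbers
// (new-joe-kuo-6 parameterization) for dimensions up to 21, 32-bit
// precision.  Optional seeded digital-shift scrambling: each dimension's
// integer output is XORed with a fixed 32-bit word derived from the seed
// by splitmix64, which preserves the (t,s)-net equidistribution of the
// sequence while giving seed-deterministic, seed-distinct streams.

static const int SOBOL_MAXDIM = 21;
static const int SOBOL_BITS = 32;

// rows: dimension 2..21; columns: s, a, m_1..m_s (Joe & Kuo)
static const int JK_S[SOBOL_MAXDIM - 1] = {
  1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 5, 5, 6, 6, 6, 6, 6, 6, 7, 7
};
static const int JK_A[SOBOL_MAXDIM - 1] = {
  0, 1, 1, 2, 1, 4, 2, 4, 7, 11, 13, 14, 1, 13, 16, 19, 22, 25, 1, 4
};
static const int JK_M[SOBOL_MAXDIM - 1][7] = {
  {1, 0, 0, 0, 0, 0, 0},
  {1, 3, 0, 0, 0, 0, 0},
  {1, 3, 1, 0, 0, 0, 0},
  {1, 1, 1, 0, 0, 0, 0},
  {1, 1, 3, 3, 0, 0, 0},
  {1, 3, 5, 13, 0, 0, 0},
  {1, 1, 5, 5, 17, 0, 0},
  {1, 1, 5, 5, 5, 0, 0},
  {1, 1, 7, 11, 19, 0, 0},
  {1, 1, 5, 1, 1, 0, 0},
  {1, 1, 1, 3, 11, 0, 0},
  {1, 3, 5, 5, 31, 0, 0},
  {1, 3, 3, 9, 7, 49, 0},
  {1, 1, 1, 15, 21, 21, 0},
  {1, 3, 1, 13, 27, 49, 0},
  {1, 1, 1, 15, 7, 5, 0},
  {1, 3, 1, 15, 13, 25, 0},
  {1, 1, 5, 5, 19, 61, 0},
  {1, 3, 7, 11, 23, 15, 103},
  {1, 3, 7, 13, 13, 15, 69}
};

static uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static void direction_numbers(int dim, uint32_t V[][SOBOL_BITS + 1]) {
  // dimension 1: van der Corput, all m_i = 1
  for (int j = 1; j <= SOBOL_BITS; ++j)
    V[0][j] = 1u << (SOBOL_BITS - j);
  for (int d = 2; d <= dim; ++d) {
    const int s = JK_S[d - 2];
    const int a = JK_A[d - 2];
    const int *m = JK_M[d - 2];
    for (int j = 1; j <= s && j <= SOBOL_BITS; ++j)
      V[d - 1][j] = ((uint32_t)m[j - 1]) << (SOBOL_BITS - j);
    for (int j = s + 1; j <= SOBOL_BITS; ++j) {
      V[d - 1][j] = V[d - 1][j - s] ^ (V[d - 1][j - s] >> s);
      for (int k = 1; k <= s - 1; ++k)
        if ((a >> (s - 1 - k)) & 1)
          V[d - 1][j] ^= V[d - 1][j - k];
    }
  }
}

// [[Rcpp::export(name = ".sobol_points_cpp")]]
NumericMatrix sobol_points_cpp(int dim, int n, double skip, double seed,
                               bool scramble) {
  if (dim < 1 || dim > SOBOL_MAXDIM)
    stop("Sobol dimensions must be between 1 and %d", SOBOL_MAXDIM);
  if (n < 1) stop("number of points must be >= 1");
  if (skip < 0) stop("skip must be >= 0");

  static uint32_t V[SOBOL_MAXDIM][SOBOL_BITS + 1];
  direction_numbers(dim, V);

  std::vector<uint32_t> shift(dim, 0u);
  if (scramble) {
    uint64_t st = (uint64_t)((int64_t)seed) * 0x2545F4914F6CDD1DULL + 0x9E3779B97F4A7C15ULL;
    for (int d = 0; d < dim; ++d)
      shift[d] = (uint32_t)(splitmix64(st) >> 32);
  }

  NumericMatrix out(n, dim);
  std::vector<uint32_t> X(dim, 0u);
  const double denom = 4294967296.0; // 2^32
  // point m is X after m Gray-code flips; point 0 is the origin
  uint64_t total = (uint64_t)skip + (uint64_t)n;
  for (uint64_t m = 0; m < total; ++m) {
    if (m >= (uint64_t)skip) {
      uint64_t row = m - (uint64_t)skip;
      for (int d = 0; d < dim; ++d)
        out(row, d) = (double)(X[d] ^ shift[d]) / denom;
    }
    // flip the direction number of the lowest zero bit of m
    uint64_t v = m;
    int c = 1;
    while (v & 1ULL) { v >>= 1; ++c; }
    if (c > SOBOL_BITS) stop("Sobol sequence exhausted (2^32 points)");
    for (int d = 0; d < dim; ++d) X[d] ^= V[d][c];
  }
  return out;
}
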