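#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Counter-based per-column RNG for sketch matrices. Each column of the m x d
// sketch is an independent splitmix64 stream keyed by (seed, column index),
// so any column subset can be regenerated deterministically without storing
// the matrix and independently of chunking.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t col_key(uint64_t seed, uint64_t col) {
  uint64_t s = seed ^ (0x9E3779B97f4A7C15ULL * (col + 1));
  splitmix64(s); // warm-up scramble so nearby columns decorrelate
  return s;
}

// uniform in (0, 1]
static inline double u64_unit(uint64_t x) {
  return ((x >> 11) + 1) * (1.0 / 9007199254740993.0);
}

// When transpose is true the result is the nc x m slice of A' (each sketch
// column laid out as a row), saving a separate transposition before the
// right-multiplication W = M A'.
// [[Rcpp::export(name = ".sketch_fill_cpp")]]
Rcpp::NumericMatrix sketch_fill_cpp(int m, Rcpp::NumericVector cols,
                                    double seed, std::string kind,
                                    bool transpose) {
  const int nc = cols.size();
  Rcpp::NumericMatrix out(transpose ? nc : m, transpose ? m : nc);
  const double scale = 1.0 / std::sqrt((double)m);
  const uint64_t useed = (uint64_t)(int64_t)seed;
  const bool gaussian = (kind == "gaussian");
  std::vector<double> buf(m);
  for (int j = 0; j < nc; ++j) {
    uint64_t st = col_key(useed, (uint64_t)cols[j]);
    double *col = transpose ? buf.data() : &out(0, j);
    if (gaussian) {
      // Box-Muller, pairs of uniforms
      int i = 0;
      while (i < m) {
        double u1 = u64_unit(splitmix64(st));
        double u2 = u64_unit(splitmix64(st));
        double r = std::sqrt(-2.0 * std::log(u1));
        double a = 6.283185307179586476925286766559 * u2;
        col[i++] = r * std::cos(a) * scale;
        if (i < m) col[i++] = r * std::sin(a) * scale;
      }
    } else { // rademacher: 64 signs per draw, whole words unrolled
      int i = 0;
      const int full = m - (m % 64);
      while (i < full) {
        uint64_t bits = splitmix64(st);
        for (int b = 0; b < 64; ++b, bits >>= 1)
          col[i++] = (bits & 1ULL) ? scale : -scale;
      }
      if (i < m) {
        uint64_t bits = splitmix64(st);
        for (; i < m; ++i, bits >>= 1)
          col[i] = (bits & 1ULL) ? scale : -scale;
      }
    }
    if (transpose)
      for (int i = 0; i < m; ++i) out(j, i) = buf[i];
  }
  return out;
}
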