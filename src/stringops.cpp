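#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost edit distance (insert / delete / substitute), two-row DP.
static int lev_core(const std::string& a, const std::string& b) {
  const size_t m = a.size(), n = b.size();
  if (m == 0) return (int) n;
  if (n == 0) return (int) m;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (size_t j = 0; j <= n; ++j) prev[j] = (int) j;
  for (size_t i = 1; i <= m; ++i) {
    cur[0] = (int) i;
    for (size_t j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export]]
int lev_dist_cpp(std::string a, std::string b) {
  return lev_core(a, b);
}

// [[Rcpp::export]]
IntegerVector lev_dist_vec_cpp(std::string a, CharacterVector b) {
  R_xlen_t n = b.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = lev_core(a, as<std::string>(b[i]));
  }
  return out;
}

// Longest common contiguous substring. Returns c(start_a, start_b, length),
// 1-based; ties broken by the leftmost occurrence in `a`, then in `b`
// (equal-length matches ending earlier also start earlier, so keeping the
// first strictly-longer match found in row-major order gives that tie-break).
// [[Rcpp::export]]
IntegerVector lcs_longest_cpp(std::string a, std::string b) {
  const size_t m = a.size(), n = b.size();
  int best_len = 0, best_a = 0, best_b = 0;
  if (m > 0 && n > 0) {
    std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
    for (size_t i = 1; i <= m; ++i) {
      for (size_t j = 1; j <= n; ++j) {
        if (a[i - 1] == b[j - 1]) {
          cur[j] = prev[j - 1] + 1;
          if (cur[j] > best_len) {
            best_len = cur[j];
            best_a = (int) i - best_len + 1;
            best_b = (int) j - best_len + 1;
          }
        } else {
          cur[j] = 0;
        }
      }
      std::swap(prev, cur);
    }
  }
  return IntegerVector::create(best_a, best_b, best_len);
}
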