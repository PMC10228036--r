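#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Semi-global affine-gap alignment (Gotoh): global in the read, free leading
// and trailing gaps in the reference. States: M (diagonal, aligned pair),
// D (consumes reference, gap in read), I (consumes read, gap in reference).
// Gap cost = gap_open + gap_extend * length. N in the read scores 0 against
// any reference base. Traceback tie-break prefers M, then D, then I at every
// cell, making the result deterministic.

static const int NEG = INT_MIN / 4;

inline int subscore(char r, char g, int match, int mismatch) {
  if (r == 'N') return 0;
  return (r == g) ? match : -mismatch;
}

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string read, std::string ref,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
  const int m = (int)read.size();
  const int n = (int)ref.size();
  if (m == 0 || n == 0) stop("read and reference must be non-empty");

  // (m+1) x (n+1) matrices, row-major
  std::vector<int> M((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> D((size_t)(m + 1) * (n + 1), NEG);
  std::vector<int> I((size_t)(m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  // row 0: alignment may start after skipping any reference prefix for free;
  // encode the free start as M[0][j] = 0 (no leading D state is reachable).
  for (int j = 0; j <= n; ++j) M[at(0, j)] = 0;

  for (int i = 1; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      // I: gap in reference, consumes read base i
      int best_open = std::max(M[at(i - 1, j)], D[at(i - 1, j)]);
      int iopen = (best_open == NEG) ? NEG : best_open - gap_open - gap_extend;
      int iext = (I[at(i - 1, j)] == NEG) ? NEG : I[at(i - 1, j)] - gap_extend;
      I[at(i, j)] = std::max(iopen, iext);
      if (j >= 1) {
        // M: align read i with ref j
        int prev = std::max(M[at(i - 1, j - 1)],
                            std::max(D[at(i - 1, j - 1)], I[at(i - 1, j - 1)]));
        if (prev != NEG)
          M[at(i, j)] = prev + subscore(read[i - 1], ref[j - 1], match, mismatch);
        // D: gap in read, consumes ref base j
        int dopen_src = std::max(M[at(i, j - 1)], I[at(i, j - 1)]);
        int dopen = (dopen_src == NEG) ? NEG : dopen_src - gap_open - gap_extend;
        int dext = (D[at(i, j - 1)] == NEG) ? NEG : D[at(i, j - 1)] - gap_extend;
        D[at(i, j)] = std::max(dopen, dext);
      }
    }
  }

  // free trailing reference gap: best score over the last row, any state.
  // Among co-optimal endpoints take the smallest reference column.
  int best = NEG, jend = -1;
  for (int j = 0; j <= n; ++j) {
    int s = std::max(M[at(m, j)], std::max(D[at(m, j)], I[at(m, j)]));
    if (s > best) { best = s; jend = j; }
  }

  // traceback; state preference M > D > I wherever scores tie
  std::string ops;
  int i = m, j = jend;
  char state;
  {
    int s = best;
    if (M[at(i, j)] == s) state = 'M';
    else if (D[at(i, j)] == s) state = 'D';
    else state = 'I';
  }
  while (i > 0) {
    if (state == 'M') {
      ops.push_back('M');
      int target = M[at(i, j)] - subscore(read[i - 1], ref[j - 1], match, mismatch);
      --i; --j;
      if (i == 0) break;
      if (M[at(i, j)] == target) state = 'M';
      else if (D[at(i, j)] == target) state = 'D';
      else state = 'I';
    } else if (state == 'D') {
      ops.push_back('D');
      int cur = D[at(i, j)];
      --j;
      if (M[at(i, j)] != NEG && M[at(i, j)] - gap_open - gap_extend == cur) state = 'M';
      else if (D[at(i, j)] != NEG && D[at(i, j)] - gap_extend == cur) state = 'D';
      else state = 'I';
    } else { // I
      ops.push_back('I');
      int cur = I[at(i, j)];
      --i;
      if (i == 0) break;
      if (M[at(i, j)] != NEG && M[at(i, j)] - gap_open - gap_extend == cur) state = 'M';
      else if (D[at(i, j)] != NEG && D[at(i, j)] - gap_open - gap_extend == cur) state = 'D';
      else state = 'I';
    }
  }
  int ref_start = j;

  // run-length encode the reversed op string
  std::vector<char> op_out;
  std::vector<int> len_out;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    char c = ops[(size_t)k];
    if (!op_out.empty() && op_out.back() == c) ++len_out.back();
    else { op_out.push_back(c); len_out.push_back(1); }
  }
  CharacterVector opv(op_out.size());
  IntegerVector lenv(len_out.size());
  for (size_t k = 0; k < op_out.size(); ++k) {
    opv[k] = std::string(1, op_out[k]);
    lenv[k] = len_out[k];
  }
  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["op"] = opv, _["len"] = lenv);
}
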