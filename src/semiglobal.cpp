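#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment of a query against a reference.
// End gaps in the query row (unaligned reference flanks) are free; the query
// itself must be fully consumed. A gap of length L costs open + (L-1) * extend
// (both passed as positive penalties). 'N' never matches (scored as mismatch).
//
// States: M (diagonal), X (gap in query, consumes reference),
//         Y (gap in reference, consumes query).
// Tie-breaking in the DP is deterministic (M > X > Y); indel placement is
// normalised to the 3'-most equivalent position afterwards on the R side.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string query, std::string ref,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  const int n = query.size();
  const int m = ref.size();
  // DP matrices, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: state entered from (0 = M, 1 = X, 2 = Y, 3 = start)
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 3);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 3);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  // Row 0: free leading reference gap -> treat as start states in M
  for (int j = 0; j <= m; ++j) {
    M[idx(0, j)] = 0.0;
    tbM[idx(0, j)] = 3;
  }
  // Column 0: leading gaps in the reference (query overhang) are penalised
  for (int i = 1; i <= n; ++i) {
    Y[idx(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    tbY[idx(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char rc = ref[j - 1];
      const double s = (qc == rc && qc != 'N') ? match : mismatch;
      // M: from best of M/X/Y at (i-1, j-1), prefer M > X > Y
      {
        double bm = M[idx(i - 1, j - 1)], bx = X[idx(i - 1, j - 1)],
               by = Y[idx(i - 1, j - 1)];
        double best = bm; unsigned char st = 0;
        if (bx > best) { best = bx; st = 1; }
        if (by > best) { best = by; st = 2; }
        M[idx(i, j)] = (best == NEG_INF) ? NEG_INF : best + s;
        tbM[idx(i, j)] = st;
      }
      // X: gap in query (consume reference base j)
      {
        double fm = (M[idx(i, j - 1)] == NEG_INF) ? NEG_INF : M[idx(i, j - 1)] - gap_open;
        double fx = (X[idx(i, j - 1)] == NEG_INF) ? NEG_INF : X[idx(i, j - 1)] - gap_extend;
        double fy = (Y[idx(i, j - 1)] == NEG_INF) ? NEG_INF : Y[idx(i, j - 1)] - gap_open;
        double best = fm; unsigned char st = 0;
        if (fx > best) { best = fx; st = 1; }
        if (fy > best) { best = fy; st = 2; }
        X[idx(i, j)] = best;
        tbX[idx(i, j)] = st;
      }
      // Y: gap in reference (consume query base i)
      {
        double fm = (M[idx(i - 1, j)] == NEG_INF) ? NEG_INF : M[idx(i - 1, j)] - gap_open;
        double fx = (X[idx(i - 1, j)] == NEG_INF) ? NEG_INF : X[idx(i - 1, j)] - gap_open;
        double fy = (Y[idx(i - 1, j)] == NEG_INF) ? NEG_INF : Y[idx(i - 1, j)] - gap_extend;
        double best = fm; unsigned char st = 0;
        if (fx > best) { best = fx; st = 1; }
        if (fy > best) { best = fy; st = 2; }
        Y[idx(i, j)] = best;
        tbY[idx(i, j)] = st;
      }
    }
  }

  // Final: best over last row (trailing reference gap free); prefer smaller j,
  // state order M > X > Y on ties.
  double best = NEG_INF; int bj = 0; unsigned char bs = 0;
  for (int j = 0; j <= m; ++j) {
    double vm = M[idx(n, j)], vx = X[idx(n, j)], vy = Y[idx(n, j)];
    if (vm > best) { best = vm; bj = j; bs = 0; }
    if (vx > best) { best = vx; bj = j; bs = 1; }
    if (vy > best) { best = vy; bj = j; bs = 2; }
  }

  // Traceback from (n, bj, bs) to a start cell
  std::string aq, ar;
  int i = n, j = bj; unsigned char st = bs;
  while (true) {
    if (st == 0) { // M
      unsigned char prev = tbM[idx(i, j)];
      if (i == 0) break;           // start row reached
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      --i; --j;
      if (prev == 3) break;
      st = prev;
    } else if (st == 1) { // X: gap in query
      unsigned char prev = tbX[idx(i, j)];
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      --j;
      st = prev;
    } else { // Y: gap in reference
      unsigned char prev = tbY[idx(i, j)];
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      --i;
      st = prev;
    }
  }
  const int ref_start = j + 1; // 1-based first consumed reference position
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return List::create(
    _["score"] = best,
    _["aligned_query"] = aq,
    _["aligned_ref"] = ar,
    _["ref_start"] = ref_start,
    _["ref_end"] = bj);
}
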