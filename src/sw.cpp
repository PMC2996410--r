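#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Sequences arrive as 0-based integer
// encodings over the 20-letter amino-acid alphabet; `S` is the 20x20
// substitution matrix. A gap of length L costs gap_open + L * gap_ext
// (BLAST convention: the first gapped column pays both penalties).

static const int NEG = INT_MIN / 4;

// score-only kernel on raw arrays; Hrow/Fcol are scratch buffers
static int sw_score_one(const int* a, int n, const int* b, int m,
                        const int* S20, int gap_open, int gap_ext,
                        std::vector<int>& Hrow, std::vector<int>& Fcol) {
  if (n == 0 || m == 0) return 0;
  Hrow.assign(m + 1, 0);
  Fcol.assign(m + 1, NEG);
  const int go = gap_open + gap_ext, ge = gap_ext;
  int best = 0;
  int* H = Hrow.data();
  int* F = Fcol.data();
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0;  // H[i-1][j-1]
    int Hleft = 0;  // H[i][j-1]
    int E = NEG;
    const int* Srow = S20 + 20 * a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int Hup = H[j];
      E = std::max(Hleft - go, E - ge);
      const int f = std::max(Hup - go, F[j] - ge);
      F[j] = f;
      int h = Hdiag + Srow[b[j - 1]];
      if (E > h) h = E;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hdiag = Hup;
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<int> as_ivec(SEXP x) {
  IntegerVector v(x);
  return std::vector<int>(v.begin(), v.end());
}

static std::vector<int> flatten_S(const IntegerMatrix& S) {
  std::vector<int> out(400);
  for (int i = 0; i < 20; ++i)
    for (int j = 0; j < 20; ++j) out[20 * i + j] = S(i, j);
  return out;
}

// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
IntegerMatrix sw_score_matrix_cpp(List queries, List subjects,
                                  IntegerMatrix S, int gap_open, int gap_ext) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int> > qs(nq), ss(ns);
  for (int i = 0; i < nq; ++i) qs[i] = as_ivec(queries[i]);
  for (int j = 0; j < ns; ++j) ss[j] = as_ivec(subjects[j]);
  const std::vector<int> S20 = flatten_S(S);
  IntegerMatrix out(nq, ns);
  std::vector<int> Hrow, Fcol;
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < ns; ++j)
      out(i, j) = sw_score_one(qs[i].data(), (int)qs[i].size(),
                               ss[j].data(), (int)ss[j].size(),
                               S20.data(), gap_open, gap_ext, Hrow, Fcol);
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full DP with traceback. Returns score and column counts of one optimal
// local alignment; ties in the end cell break toward the smallest (i, j),
// and the traceback prefers diagonal, then a gap in the query (E), then a
// gap in the subject (F), so the reported alignment is deterministic.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector aq, IntegerVector bq,
                  IntegerMatrix S, int gap_open, int gap_ext) {
  std::vector<int> a(aq.begin(), aq.end()), b(bq.begin(), bq.end());
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0, _["columns"] = 0, _["identical"] = 0);
  const std::vector<int> S20 = flatten_S(S);
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  const int W = m + 1;
  const int go = gap_open + gap_ext, ge = gap_ext;
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int* Srow = S20.data() + 20 * a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int idx = i * W + j;
      E[idx] = std::max(H[idx - 1] - go, E[idx - 1] - ge);
      F[idx] = std::max(H[idx - W] - go, F[idx - W] - ge);
      int h = H[idx - W - 1] + Srow[b[j - 1]];
      if (E[idx] > h) h = E[idx];
      if (F[idx] > h) h = F[idx];
      if (h < 0) h = 0;
      H[idx] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int columns = 0, identical = 0;
  if (best > 0) {
    int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      const int idx = i * W + j;
      if (state == 0) {
        if (H[idx] == 0) break;
        const int diag = H[idx - W - 1] + S20[20 * a[i - 1] + b[j - 1]];
        if (H[idx] == diag) {
          ++columns;
          if (a[i - 1] == b[j - 1]) ++identical;
          --i; --j;
        } else if (H[idx] == E[idx]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) { // gap in query: consume b[j]
        ++columns;
        if (E[idx] == E[idx - 1] - ge) { --j; }
        else { --j; state = 0; }
      } else {                 // gap in subject: consume a[i]
        ++columns;
        if (F[idx] == F[idx - W] - ge) { --i; }
        else { --i; state = 0; }
      }
    }
  }
  return List::create(_["score"] = best, _["columns"] = columns,
                      _["identical"] = identical);
}
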