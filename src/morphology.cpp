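// 3D binary morphology and connected-component labelling (6-connectivity),
// used by the classical lung segmentation and body-mask steps.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static void get_dim3(const LogicalVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("expected a 3D array");
  for (int i = 0; i < 3; ++i) d[i] = dm[i];
}

// [[Rcpp::export]]
IntegerVector cppLabel3D(LogicalVector mask) {
  int d[3]; get_dim3(mask, d);
  int A = d[0], B = d[1], C = d[2];
  R_xlen_t n = (R_xlen_t)A * B * C;
  IntegerVector lab(n);
  lab.attr("dim") = mask.attr("dim");
  const int* m = LOGICAL(mask);
  int* L = INTEGER(lab);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (m[s] != 1 || L[s] != 0) continue;
    ++cur;
    L[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % A);
      int j = (int)((v / A) % B);
      int k = (int)(v / ((R_xlen_t)A * B));
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int t = 0; t < 6; ++t) {
        int i2 = i + di[t], j2 = j + dj[t], k2 = k + dk[t];
        if (i2 < 0 || i2 >= A || j2 < 0 || j2 >= B || k2 < 0 || k2 >= C)
          continue;
        R_xlen_t w = i2 + (R_xlen_t)A * (j2 + (R_xlen_t)B * k2);
        if (m[w] == 1 && L[w] == 0) { L[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

static LogicalVector morph3d(LogicalVector mask, bool dilate) {
  int d[3]; get_dim3(mask, d);
  int A = d[0], B = d[1], C = d[2];
  LogicalVector out((R_xlen_t)A * B * C);
  out.attr("dim") = mask.attr("dim");
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  for (int k = 0; k < C; ++k)
    for (int j = 0; j < B; ++j)
      for (int i = 0; i < A; ++i) {
        R_xlen_t v = i + (R_xlen_t)A * (j + (R_xlen_t)B * k);
        bool any = m[v] == 1, all = m[v] == 1;
        const int di[6] = { -1, 1, 0, 0, 0, 0 };
        const int dj[6] = { 0, 0, -1, 1, 0, 0 };
        const int dk[6] = { 0, 0, 0, 0, -1, 1 };
        for (int t = 0; t < 6; ++t) {
          int i2 = i + di[t], j2 = j + dj[t], k2 = k + dk[t];
          bool inb = i2 >= 0 && i2 < A && j2 >= 0 && j2 < B && k2 >= 0 &&
                     k2 < C;
          // outside the grid counts as background
          bool val = inb &&
            m[i2 + (R_xlen_t)A * (j2 + (R_xlen_t)B * k2)] == 1;
          any = any || val;
          all = all && val;
        }
        o[v] = dilate ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cppDilate3D(LogicalVector mask) { return morph3d(mask, true); }

// [[Rcpp::export]]
LogicalVector cppErode3D(LogicalVector mask) { return morph3d(mask, false); }
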