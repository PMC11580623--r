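#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local affine-gap alignment (Smith-Waterman-Gotoh) with traceback.
// A gap of length L costs gap_open + L * gap_ext, so the penalties are
// directly comparable with Biostrings::pairwiseAlignment(type = "local").
// Sequences are plain ACGT strings; N never matches anything.

// [[Rcpp::export(name = ".sw_affine")]]
List sw_affine(std::string query, std::string subject,
               double match = 1.0, double mismatch = -2.0,
               double gap_open = 5.0, double gap_ext = 2.0) {
  const int n = query.size(), m = subject.size();
  const double NEG = -1e30;
  // rows i over query (1..n), cols j over subject (1..m)
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG); // gap consuming query
  std::vector<double> F((n + 1) * (m + 1), NEG); // gap consuming subject
  // traceback: 0 stop, 1 diag, 2 up (E), 3 left (F)
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);
  std::vector<unsigned char> TE((n + 1) * (m + 1), 0); // E opened here?
  std::vector<unsigned char> TF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int k = idx(i, j);
      const double eo = H[idx(i - 1, j)] - gap_open - gap_ext;
      const double ee = E[idx(i - 1, j)] - gap_ext;
      E[k] = (eo >= ee) ? eo : ee;
      TE[k] = (eo >= ee) ? 1 : 0;
      const double fo = H[idx(i, j - 1)] - gap_open - gap_ext;
      const double fe = F[idx(i, j - 1)] - gap_ext;
      F[k] = (fo >= fe) ? fo : fe;
      TF[k] = (fo >= fe) ? 1 : 0;
      const char sc = subject[j - 1];
      const double sub = (qc == sc && qc != 'N') ? match : mismatch;
      const double diag = H[idx(i - 1, j - 1)] + sub;
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[k] > h) { h = E[k]; tb = 2; }
      if (F[k] > h) { h = F[k]; tb = 3; }
      H[k] = h; TB[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string qa, sa;
  int i = bi, j = bj;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    const int k = idx(i, j);
    if (state == 0) {
      const unsigned char tb = TB[k];
      if (tb == 0) break;
      if (tb == 1) {
        qa.push_back(query[i - 1]); sa.push_back(subject[j - 1]);
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa.push_back(query[i - 1]); sa.push_back('-');
      const unsigned char open_here = TE[k];
      --i;
      if (open_here) state = 0;
    } else {
      qa.push_back('-'); sa.push_back(subject[j - 1]);
      const unsigned char open_here = TF[k];
      --j;
      if (open_here) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  return List::create(
    _["score"] = best,
    _["qstart"] = i + 1, _["qend"] = bi,
    _["sstart"] = j + 1, _["send"] = bj,
    _["qaligned"] = qa, _["saligned"] = sa);
}
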