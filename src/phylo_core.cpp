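#include <Rcpp.h>
#include <sstream>
#include <iomanip>
using namespace Rcpp;

// Pairwise proportion of differing sites between rows of an integer-coded
// alignment (one row per sequence, one column per site, codes arbitrary).
// [[Rcpp::export(name = ".pdist_cpp")]]
NumericMatrix pdist_cpp(IntegerMatrix aln) {
  const int n = aln.nrow(), L = aln.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int diff = 0;
      for (int s = 0; s < L; ++s)
        if (aln(i, s) != aln(j, s)) ++diff;
      d(i, j) = d(j, i) = (double) diff / (double) L;
    }
  }
  return d;
}

static std::string num(double x) {
  std::ostringstream o;
  o << std::setprecision(10) << x;
  return o.str();
}

// Saitou-Nei neighbor joining.  Q(i,j) = (m-2) d(i,j) - r_i - r_j minimised;
// ties broken by the lexicographically smallest active pair (i, j); negative
// branch lengths clamped to zero with the deficit moved to the sibling.
// Returns a Newick string for the unrooted tree (trifurcating root).
// [[Rcpp::export(name = ".nj_cpp")]]
std::string nj_cpp(NumericMatrix dm, CharacterVector labels) {
  int n = dm.nrow();
  if (n < 3) stop("neighbor joining needs at least 3 taxa");
  std::vector<std::vector<double> > d(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d[i][j] = dm(i, j);
  std::vector<std::string> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = as<std::string>(labels[i]);
  std::vector<int> act(n);
  for (int i = 0; i < n; ++i) act[i] = i;

  while ((int) act.size() > 3) {
    int m = act.size();
    std::vector<double> r(m, 0.0);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (a != b) r[a] += d[act[a]][act[b]];
    double qbest = R_PosInf;
    int bi = -1, bj = -1;
    for (int a = 0; a < m; ++a) {
      for (int b = a + 1; b < m; ++b) {
        double q = (m - 2) * d[act[a]][act[b]] - r[a] - r[b];
        if (q < qbest - 1e-12) { qbest = q; bi = a; bj = b; }
      }
    }
    int i = act[bi], j = act[bj];
    double dij = d[i][j];
    double li = 0.5 * dij + (r[bi] - r[bj]) / (2.0 * (m - 2));
    double lj = dij - li;
    if (li < 0) { lj += li; li = 0; }
    if (lj < 0) { li += lj; lj = 0; if (li < 0) li = 0; }
    std::string merged =
      "(" + lab[i] + ":" + num(li) + "," + lab[j] + ":" + num(lj) + ")";
    // new cluster occupies i's slot; j retired
    for (int a = 0; a < m; ++a) {
      int k = act[a];
      if (k == i || k == j) continue;
      double dnew = 0.5 * (d[i][k] + d[j][k] - dij);
      d[i][k] = d[k][i] = dnew;
    }
    lab[i] = merged;
    act.erase(act.begin() + bj);
  }

  int a = act[0], b = act[1], c = act[2];
  double la = 0.5 * (d[a][b] + d[a][c] - d[b][c]);
  double lb = 0.5 * (d[a][b] + d[b][c] - d[a][c]);
  double lc = 0.5 * (d[a][c] + d[b][c] - d[a][b]);
  if (la < 0) la = 0;
  if (lb < 0) lb = 0;
  if (lc < 0) lc = 0;
  return "(" + lab[a] + ":" + num(la) + "," + lab[b] + ":" + num(lb) + "," +
         lab[c] + ":" + num(lc) + ");";
}
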