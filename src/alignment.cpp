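// Affine-gap pairwise alignment kernels (Gotoh three-state DP).
//
// Gap convention: a gap run of length L costs gap_open + L * gap_extend
// (the open charge is paid once per run, plus a per-residue extension).
// Traceback ties are broken deterministically: diagonal (match/mismatch)
// over gap-in-a, over gap-in-b.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// map sequence characters to scoring-matrix row indices
static std::vector<int> encode(const std::string& s,
                               const std::vector<int>& cmap) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int k = cmap[(unsigned char) s[i]];
    if (k < 0)
      stop("character '%s' not in scoring alphabet",
           std::string(1, s[i]).c_str());
    out[i] = k;
  }
  return out;
}

static std::vector<int> char_map(const NumericMatrix& smat) {
  std::vector<int> cmap(256, -1);
  CharacterVector rn = rownames(smat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string ch = as<std::string>(rn[i]);
    cmap[(unsigned char) ch[0]] = i;
  }
  return cmap;
}

static int count_identities(const std::string& aa, const std::string& ab) {
  int id = 0;
  for (size_t i = 0; i < aa.size(); ++i)
    if (aa[i] == ab[i] && aa[i] != '-') ++id;
  return id;
}

// [[Rcpp::export]]
List gotoh_global_cpp(std::string a, std::string b, NumericMatrix smat,
                      double gap_open, double gap_ext) {
  int m = (int) a.size(), n = (int) b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int> cmap = char_map(smat);
  std::vector<int> ai = encode(a, cmap), bi = encode(b, cmap);

  size_t W = (size_t)(n + 1);
  std::vector<double> M((m + 1) * W, NEG_INF);
  std::vector<double> X((m + 1) * W, NEG_INF); // ends with a[i] over gap (gap in b)
  std::vector<double> Y((m + 1) * W, NEG_INF); // ends with gap over b[j] (gap in a)
  // traceback: predecessor state 0=M,1=Y,2=X; 3 marks origin
  std::vector<unsigned char> tM((m + 1) * W), tX((m + 1) * W), tY((m + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[i * W] = -(gap_open + gap_ext * i);
    tX[i * W] = (i == 1) ? 0 : 2;
  }
  for (int j = 1; j <= n; ++j) {
    Y[j] = -(gap_open + gap_ext * j);
    tY[j] = (j == 1) ? 0 : 1;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1),
             u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = smat(ai[i - 1], bi[j - 1]);
      // M: prefer M, then Y, then X predecessor
      double best = M[d]; unsigned char tb = 0;
      if (Y[d] > best) { best = Y[d]; tb = 1; }
      if (X[d] > best) { best = X[d]; tb = 2; }
      M[c] = best + s; tM[c] = tb;
      // X: a[i] aligned to gap; predecessor at (i-1, j)
      double open = std::max(M[u], Y[u]) - gap_open - gap_ext;
      double xext = X[u] - gap_ext;
      if (M[u] >= Y[u]) { best = M[u] - gap_open - gap_ext; tb = 0; }
      else              { best = Y[u] - gap_open - gap_ext; tb = 1; }
      if (xext > best) { best = xext; tb = 2; }
      X[c] = best; tX[c] = tb; (void) open;
      // Y: gap aligned to b[j]; predecessor at (i, j-1)
      if (M[l] >= X[l]) { best = M[l] - gap_open - gap_ext; tb = 0; }
      else              { best = X[l] - gap_open - gap_ext; tb = 2; }
      if (Y[l] - gap_ext > best) { best = Y[l] - gap_ext; tb = 1; }
      Y[c] = best; tY[c] = tb;
    }
  }

  size_t e = (size_t) m * W + n;
  double score = M[e]; int state = 0;
  if (Y[e] > score) { score = Y[e]; state = 1; }
  if (X[e] > score) { score = X[e]; state = 2; }

  std::string ra, rb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    size_t c = (size_t) i * W + j;
    if (state == 0) {
      unsigned char tb = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = tb;
    } else if (state == 2) { // gap in b, consume a
      unsigned char tb = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = tb;
    } else { // gap in a, consume b
      unsigned char tb = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = tb;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score,
                      _["identities"] = count_identities(ra, rb),
                      _["aligned_length"] = (int) ra.size());
}

// score-only local alignment (linear memory); returns best score and the
// 1-based end coordinates of the best cell in a and b
// [[Rcpp::export]]
List sw_score_cpp(std::string a, std::string b, NumericMatrix smat,
                  double gap_open, double gap_ext) {
  int m = (int) a.size(), n = (int) b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");
  std::vector<int> cmap = char_map(smat);
  std::vector<int> ai = encode(a, cmap), bi = encode(b, cmap);

  std::vector<double> Mp(n + 1, 0.0), Mc(n + 1, 0.0);
  std::vector<double> Xp(n + 1, NEG_INF), Xc(n + 1, NEG_INF);
  std::vector<double> Yp(n + 1, NEG_INF), Yc(n + 1, NEG_INF);
  double best = 0.0; int bi_end = 0, bj_end = 0;

  for (int i = 1; i <= m; ++i) {
    Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      double s = smat(ai[i - 1], bi[j - 1]);
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      double mv = std::max(0.0, diag + s);
      double xv = std::max(std::max(Mp[j], Yp[j]) - gap_open - gap_ext,
                           Xp[j] - gap_ext);
      double yv = std::max(std::max(Mc[j - 1], Xc[j - 1]) - gap_open - gap_ext,
                           Yc[j - 1] - gap_ext);
      Mc[j] = mv; Xc[j] = xv; Yc[j] = yv;
      if (mv > best) { best = mv; bi_end = i; bj_end = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return List::create(_["score"] = best, _["end_a"] = bi_end,
                      _["end_b"] = bj_end);
}
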