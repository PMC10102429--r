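#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Windowed GLCM texture maps.
//
// For every pixel whose window fits entirely inside the raster, a gray-level
// co-occurrence matrix is accumulated from the quantized window at each
// configured offset (each offset's GLCM normalized to sum 1, symmetrized by
// adding the transpose when requested), the per-offset GLCMs are averaged
// with equal weight, and the eight Haralick-style statistics of the averaged
// GLCM are emitted. Border pixels are NA.
//
// Pair counts per offset depend only on the window and offset geometry
// ((w - |drow|) * (w - |dcol|)), so per-entry weights are precomputed.
//
// Statistics (P over 0-based levels i, j):
//   mean = mu_i;  var = sigma_i^2 (row marginal)
//   hom  = sum P / (1 + (i-j)^2);  con = sum (i-j)^2 P;  dis = sum |i-j| P
//   ent  = -sum_{P>0} P log P;     sm  = sum P^2
//   cor  = cov(i,j) / (sigma_i sigma_j), 0 when a marginal variance is 0.

// [[Rcpp::export(name = ".glcm_texture_maps_cpp")]]
List glcm_texture_maps_cpp(IntegerMatrix q, int levels, int window,
                           IntegerMatrix offsets, bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  const int h = window / 2;
  const int noff = offsets.nrow();

  if (window < 2 || nr < window || nc < window)
    stop("raster smaller than the texture window");

  // per-offset geometric pair counts and weights
  std::vector<int> npairs(noff);
  int nvalid = 0;
  for (int o = 0; o < noff; ++o) {
    int adr = std::abs(offsets(o, 0)), adc = std::abs(offsets(o, 1));
    int n = std::max(0, window - adr) * std::max(0, window - adc);
    npairs[o] = n;
    if (n > 0) ++nvalid;
  }
  if (nvalid == 0) stop("no offset yields a valid pixel pair inside the window");

  NumericMatrix m_mean(nr, nc), m_var(nr, nc), m_hom(nr, nc), m_con(nr, nc),
      m_dis(nr, nc), m_ent(nr, nc), m_sm(nr, nc), m_cor(nr, nc);
  std::fill(m_mean.begin(), m_mean.end(), NA_REAL);
  std::fill(m_var.begin(), m_var.end(), NA_REAL);
  std::fill(m_hom.begin(), m_hom.end(), NA_REAL);
  std::fill(m_con.begin(), m_con.end(), NA_REAL);
  std::fill(m_dis.begin(), m_dis.end(), NA_REAL);
  std::fill(m_ent.begin(), m_ent.end(), NA_REAL);
  std::fill(m_sm.begin(), m_sm.end(), NA_REAL);
  std::fill(m_cor.begin(), m_cor.end(), NA_REAL);

  std::vector<std::pair<int, double> > entries;
  entries.reserve(2 * window * window * noff);

  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      entries.clear();
      for (int o = 0; o < noff; ++o) {
        if (npairs[o] == 0) continue;
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        const double w = symmetric
            ? 1.0 / (nvalid * 2.0 * npairs[o])
            : 1.0 / (nvalid * (double)npairs[o]);
        const int r0 = std::max(-h, -h - dr), r1 = std::min(h, h - dr);
        const int c0 = std::max(-h, -h - dc), c1 = std::min(h, h - dc);
        for (int wr = r0; wr <= r1; ++wr) {
          for (int wc = c0; wc <= c1; ++wc) {
            const int i = q(r + wr, c + wc);
            const int j = q(r + wr + dr, c + wc + dc);
            entries.push_back(std::make_pair(i * levels + j, w));
            if (symmetric) entries.push_back(std::make_pair(j * levels + i, w));
          }
        }
      }
      std::sort(entries.begin(), entries.end());

      double Si = 0, Sj = 0, Sii = 0, Sjj = 0, Sij = 0;
      double con = 0, dis = 0, hom = 0, ent = 0, sm = 0;
      size_t k = 0;
      while (k < entries.size()) {
        const int code = entries[k].first;
        double p = 0;
        while (k < entries.size() && entries[k].first == code) {
          p += entries[k].second;
          ++k;
        }
        const int i = code / levels, j = code % levels;
        const int d = i - j;
        Si += i * p;  Sj += j * p;
        Sii += (double)i * i * p;  Sjj += (double)j * j * p;
        Sij += (double)i * j * p;
        con += (double)d * d * p;
        dis += std::abs(d) * p;
        hom += p / (1.0 + d * d);
        if (p > 0) ent -= p * std::log(p);
        sm += p * p;
      }
      const double vi = std::max(0.0, Sii - Si * Si);
      const double vj = std::max(0.0, Sjj - Sj * Sj);
      double cor = 0.0;
      if (vi > 1e-12 && vj > 1e-12)
        cor = (Sij - Si * Sj) / std::sqrt(vi * vj);

      m_mean(r, c) = Si;
      m_var(r, c) = vi;
      m_hom(r, c) = hom;
      m_con(r, c) = con;
      m_dis(r, c) = dis;
      m_ent(r, c) = ent;
      m_sm(r, c) = sm;
      m_cor(r, c) = cor;
    }
  }

  return List::create(
      _["mean"] = m_mean, _["var"] = m_var, _["hom"] = m_hom, _["con"] = m_con,
      _["dis"] = m_dis, _["ent"] = m_ent, _["sm"] = m_sm, _["cor"] = m_cor);
}
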