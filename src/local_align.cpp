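#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) with traceback.
// Scoring (integer): +match for identical A/C/G/T, mismatch for differing
// bases, 0 when either base is ambiguous (non-ACGT); a gap of length k
// costs gap_open + k * gap_ext.
// Returns score, match count, alignment columns and 0-based half-open
// spans on query and subject of the best local alignment.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// traceback byte layout: bits 0-1 H direction (0 stop, 1 diag, 2 E, 3 F),
// bit 2: E extended, bit 3: F extended.

// When band_width >= 0, the dynamic program is restricted to the diagonal
// band |(i - j) - band_diag| <= band_width; cells outside behave as empty
// (H = 0), which is exact whenever the optimal local alignment stays
// within the band — seeds supply band_diag in practice.

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string q, std::string s,
              int match = 1, int mismatch = -1,
              int gap_open = 2, int gap_ext = 1,
              int band_diag = 0, int band_width = -1) {
  const int n = q.size(), m = s.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> Hprev(m + 2, 0), Hcur(m + 2, 0);
  std::vector<int> Fprev(m + 2, NEG), Fcur(m + 2, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band_width >= 0) {
      jlo = i - band_diag - band_width;
      jhi = i - band_diag + band_width;
      if (jlo < 1) jlo = 1;
      if (jhi > m) jhi = m;
      if (jlo > jhi) {
        std::swap(Hprev, Hcur);
        std::swap(Fprev, Fcur);
        continue;
      }
    }
    Hcur[jlo - 1] = 0;
    Fcur[jlo - 1] = NEG;
    int Ej = NEG; // E for current row, column j (rolls left to right)
    const char qc = q[i - 1];
    const bool qok = is_base(qc);
    unsigned char *tbrow = &tb[(size_t)i * (m + 1)];
    const int *Hp = Hprev.data();
    const int *Fp = Fprev.data();
    int *Hc = Hcur.data();
    int *Fc = Fcur.data();
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char t = 0;
      // E: gap consuming subject base j
      int e_open = Hc[j - 1] - gap_open - gap_ext;
      int e_ext = Ej - gap_ext;
      if (e_ext > e_open) { Ej = e_ext; t |= 4; } else Ej = e_open;
      // F: gap consuming query base i
      int f_open = Hp[j] - gap_open - gap_ext;
      int f_ext = Fp[j] - gap_ext;
      if (f_ext > f_open) { Fc[j] = f_ext; t |= 8; } else Fc[j] = f_open;
      // H
      const char sc = s[j - 1];
      int sub = (!qok || !is_base(sc)) ? 0 : (qc == sc ? match : mismatch);
      int diag = Hp[j - 1] + sub;
      int h = 0; unsigned char dir = 0;
      if (diag > h) { h = diag; dir = 1; }
      if (Ej > h) { h = Ej; dir = 2; }
      if (Fc[j] > h) { h = Fc[j]; dir = 3; }
      Hc[j] = h;
      tbrow[j] = t | dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (band_width >= 0 && jhi < m) {
      // next row reads one column beyond this row's band
      Hcur[jhi + 1] = 0;
      Fcur[jhi + 1] = NEG;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  long matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    const unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      const unsigned char dir = t & 3;
      if (dir == 0) break;
      if (dir == 1) {
        ++cols;
        if (is_base(q[i - 1]) && q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (dir == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++cols;
      state = (t & 4) ? 1 : 0;
      --j;
    } else {
      ++cols;
      state = (t & 8) ? 2 : 0;
      --i;
    }
  }

  return List::create(
    _["score"] = (double)best, _["matches"] = (double)matches,
    _["columns"] = (double)cols,
    _["qstart"] = i, _["qend"] = bi,
    _["sstart"] = j, _["send"] = bj);
}
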