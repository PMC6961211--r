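#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 8-connected neighbourhood offsets
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// Circular rank-filter kernel: offsets with dx^2 + dy^2 <= radius^2 + 1
// (ImageJ RankFilters convention; radius 1 -> full 3x3, radius 2 -> 21 px).
static void kernel_offsets(double radius, std::vector<int> &odx,
                           std::vector<int> &ody) {
  int r = (int)std::floor(radius) + 1;
  double r2 = radius * radius + 1.0;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      if ((double)(dx * dx + dy * dy) <= r2) {
        odx.push_back(dx);
        ody.push_back(dy);
      }
}

// [[Rcpp::export]]
int kernel_size_cpp(double radius) {
  std::vector<int> odx, ody;
  kernel_offsets(radius, odx, ody);
  return (int)odx.size();
}

// Median filter with edge replication. radius <= 0 returns the input.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  if (radius <= 0) return clone(img);
  std::vector<int> odx, ody;
  kernel_offsets(radius, odx, ody);
  int n = (int)odx.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(n);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      for (int k = 0; k < n; ++k) {
        int yy = y + ody[k];
        int xx = x + odx[k];
        if (yy < 0) yy = 0; else if (yy >= nr) yy = nr - 1;
        if (xx < 0) xx = 0; else if (xx >= nc) xx = nc - 1;
        buf[k] = img(yy, xx);
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(y, x) = buf[n / 2]; // kernel size is always odd (symmetric + centre)
    }
  }
  return out;
}

// lexicographic (y, x) comparison of linear indices (column-major, nr rows)
static inline bool yx_less(int a, int b, int nr) {
  int ya = a % nr, xa = a / nr, yb = b % nr, xb = b / nr;
  return (ya < yb) || (ya == yb && xa < xb);
}

struct Plateau {
  double v;
  int rep;                // lexicographic-min (y, x) member
  std::vector<int> pix;   // member linear indices
  bool is_max;            // no strictly higher 8-neighbour
};

// Topographic-prominence maxima, ImageJ Find Maxima semantics:
// a candidate plateau is reported iff no path to strictly higher terrain
// stays >= v - tol everywhere; equal-valued candidates connected within
// tolerance merge into a single reported peak. Returns an m x 2 matrix of
// 0-based (x, y) representatives, ordered by (y, x).
// [[Rcpp::export]]
IntegerMatrix find_maxima_cpp(NumericMatrix img, double tol) {
  int nr = img.nrow(), nc = img.ncol(), N = nr * nc;
  double mn = img[0], mx = img[0];
  for (int i = 1; i < N; ++i) {
    if (img[i] < mn) mn = img[i];
    if (img[i] > mx) mx = img[i];
  }
  if (!(mx > mn)) return IntegerMatrix(0, 2); // constant image: no maxima

  // label equal-valued 8-connected plateaus; flag those with no higher nbr
  std::vector<int> plab(N, -1);
  std::vector<Plateau> plat;
  std::vector<int> stack;
  for (int i = 0; i < N; ++i) {
    if (plab[i] >= 0) continue;
    int id = (int)plat.size();
    plat.push_back(Plateau());
    Plateau &p = plat.back();
    p.v = img[i];
    p.rep = i;
    p.is_max = true;
    plab[i] = id;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      p.pix.push_back(j);
      if (yx_less(j, p.rep, nr)) p.rep = j;
      int y = j % nr, x = j / nr;
      for (int k = 0; k < 8; ++k) {
        int yy = y + DY[k], xx = x + DX[k];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        int jj = yy + xx * nr;
        double vj = img[jj];
        if (vj > p.v) p.is_max = false;
        if (vj == p.v && plab[jj] < 0) {
          plab[jj] = id;
          stack.push_back(jj);
        }
      }
    }
  }

  // candidate plateaus, highest first (ties: representative (y, x) order)
  std::vector<int> cand;
  for (int i = 0; i < (int)plat.size(); ++i)
    if (plat[i].is_max) cand.push_back(i);
  int nrR = nr;
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (plat[a].v != plat[b].v) return plat[a].v > plat[b].v;
    return yx_less(plat[a].rep, plat[b].rep, nrR);
  });

  std::vector<int> stamp(N, -1);
  std::vector<char> absorbed(plat.size(), 0);
  std::vector<int> reps;
  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int c = cand[ci];
    if (absorbed[c]) continue;
    double v = plat[c].v, lo = v - tol;
    bool higher = false;
    int rep = plat[c].rep;
    absorbed[c] = 1;
    stack.clear();
    for (size_t k = 0; k < plat[c].pix.size(); ++k) {
      stamp[plat[c].pix[k]] = c;
      stack.push_back(plat[c].pix[k]);
    }
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      int y = j % nr, x = j / nr;
      for (int k = 0; k < 8; ++k) {
        int yy = y + DY[k], xx = x + DX[k];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        int jj = yy + xx * nr;
        if (stamp[jj] == c) continue;
        double vj = img[jj];
        if (vj > v) { higher = true; continue; }
        if (vj >= lo) {
          stamp[jj] = c;
          stack.push_back(jj);
          int pj = plab[jj];
          if (plat[pj].is_max && !absorbed[pj]) {
            absorbed[pj] = 1; // lower maxima are within tolerance of this one
            if (vj == v && yx_less(plat[pj].rep, rep, nr)) rep = plat[pj].rep;
          }
        }
      }
    }
    if (!higher) reps.push_back(rep);
  }

  std::sort(reps.begin(), reps.end(),
            [&](int a, int b) { return yx_less(a, b, nrR); });
  IntegerMatrix out((int)reps.size(), 2);
  for (int i = 0; i < (int)reps.size(); ++i) {
    out(i, 0) = reps[i] / nr; // x (column), 0-based
    out(i, 1) = reps[i] % nr; // y (row), 0-based
  }
  return out;
}

// Union of 8-connected floods: from each seed, all pixels with
// img >= img[seed] - tol reachable from it ("maxima within tolerance").
// px, py are 0-based (x, y).
// [[Rcpp::export]]
LogicalMatrix flood_tolerance_cpp(NumericMatrix img, IntegerVector px,
                                  IntegerVector py, double tol) {
  int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix mask(nr, nc);
  std::vector<int> stamp(nr * nc, -1);
  std::vector<int> stack;
  for (int s = 0; s < px.size(); ++s) {
    int x0 = px[s], y0 = py[s];
    if (x0 < 0 || x0 >= nc || y0 < 0 || y0 >= nr)
      stop("peak coordinate outside image");
    double lo = img(y0, x0) - tol;
    int i0 = y0 + x0 * nr;
    if (stamp[i0] == s) continue;
    stamp[i0] = s;
    stack.clear();
    stack.push_back(i0);
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      mask[j] = true;
      int y = j % nr, x = j / nr;
      for (int k = 0; k < 8; ++k) {
        int yy = y + DY[k], xx = x + DX[k];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        int jj = yy + xx * nr;
        if (stamp[jj] == s || mask[jj]) continue;
        if (img[jj] >= lo) {
          stamp[jj] = s;
          stack.push_back(jj);
        }
      }
    }
  }
  return mask;
}

// CRC-32 (IEEE 802.3), for the stored-ZIP writer.
// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (int i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
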