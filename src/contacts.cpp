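#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Periodic wrap of a coordinate into [0, L).
static inline double wrap0(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L; // guard against floating point landing exactly on L
  return y;
}

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// Cell-list neighbour search between two bead groups under rectangular PBC.
//
// coords: n x 3 matrix (nm); box: length-3 rectangular box (nm);
// ia, ib: 1-based row indices of the two groups; cutoff: nm (strict '<').
// Returns an M x 2 integer matrix of (position in ia, position in ib),
// 1-based, for every bead pair at minimum-image distance < cutoff.
//
// Cells are at least `cutoff` wide by construction (ncell = floor(box/cutoff),
// cell width = box/ncell >= cutoff), so scanning the 27 neighbouring cells is
// sufficient. Small boxes (fewer than 3 cells along an axis) deduplicate the
// wrapped neighbour cells to avoid double counting.
// [[Rcpp::export]]
IntegerMatrix contact_pairs_cellist(NumericMatrix coords, NumericVector box,
                                    IntegerVector ia, IntegerVector ib,
                                    double cutoff) {
  const int na = ia.size(), nb = ib.size();
  const double cut2 = cutoff * cutoff;
  std::vector<int> out_a, out_b;
  if (na == 0 || nb == 0) return IntegerMatrix(0, 2);

  int nc[3];
  double cw[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor(box[d] / cutoff));
    cw[d] = box[d] / nc[d];
  }
  const int ncells = nc[0] * nc[1] * nc[2];

  // bucket the b group into cells
  std::vector<int> head(ncells, -1), nxt(nb, -1);
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) {
    const int r = ib[j] - 1;
    bx[j] = wrap0(coords(r, 0), box[0]);
    by[j] = wrap0(coords(r, 1), box[1]);
    bz[j] = wrap0(coords(r, 2), box[2]);
    int cx = std::min((int)(bx[j] / cw[0]), nc[0] - 1);
    int cy = std::min((int)(by[j] / cw[1]), nc[1] - 1);
    int cz = std::min((int)(bz[j] / cw[2]), nc[2] - 1);
    int cell = (cz * nc[1] + cy) * nc[0] + cx;
    nxt[j] = head[cell];
    head[cell] = j;
  }

  // distinct wrapped neighbour offsets per axis
  int offs[3][3], noffs[3];
  for (int d = 0; d < 3; ++d) {
    noffs[d] = 0;
    for (int o = -1; o <= 1; ++o) {
      int w = ((o % nc[d]) + nc[d]) % nc[d];
      bool seen = false;
      for (int k = 0; k < noffs[d]; ++k)
        if (offs[d][k] == w) { seen = true; break; }
      if (!seen) offs[d][noffs[d]++] = w;
    }
  }

  for (int i = 0; i < na; ++i) {
    const int r = ia[i] - 1;
    const double ax = wrap0(coords(r, 0), box[0]);
    const double ay = wrap0(coords(r, 1), box[1]);
    const double az = wrap0(coords(r, 2), box[2]);
    const int cx = std::min((int)(ax / cw[0]), nc[0] - 1);
    const int cy = std::min((int)(ay / cw[1]), nc[1] - 1);
    const int cz = std::min((int)(az / cw[2]), nc[2] - 1);
    for (int ox = 0; ox < noffs[0]; ++ox) {
      const int gx = (cx + offs[0][ox]) % nc[0];
      for (int oy = 0; oy < noffs[1]; ++oy) {
        const int gy = (cy + offs[1][oy]) % nc[1];
        for (int oz = 0; oz < noffs[2]; ++oz) {
          const int gz = (cz + offs[2][oz]) % nc[2];
          int j = head[(gz * nc[1] + gy) * nc[0] + gx];
          for (; j != -1; j = nxt[j]) {
            const double dx = min_image(ax - bx[j], box[0]);
            const double dy = min_image(ay - by[j], box[1]);
            const double dz = min_image(az - bz[j], box[2]);
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < cut2) {
              out_a.push_back(i + 1);
              out_b.push_back(j + 1);
            }
          }
        }
      }
    }
  }

  const int m = out_a.size();
  IntegerMatrix res(m, 2);
  for (int k = 0; k < m; ++k) {
    res(k, 0) = out_a[k];
    res(k, 1) = out_b[k];
  }
  return res;
}
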