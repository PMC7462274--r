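#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a corner-sampled scalar
// field. Each grid cube is split into six tetrahedra sharing the main
// diagonal (Freudenthal decomposition); the split is identical in every cube
// so shared faces are triangulated consistently and the surface is watertight
// for a periodic field. The iso-level is 0 with solid = {field >= 0}.
//
// Only genuine phase crossings produce triangles, so the outer faces of the
// sampling box never contribute area (the "inner surface" convention).

// corner bit order: index = x + 2*y + 4*z
static const int TETS[6][4] = {
  {0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
  {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}
};

static inline void interp(const double* p1, const double* p2,
                          double v1, double v2, double* out) {
  double t = v1 / (v1 - v2); // crossing of the linear interpolant
  if (!std::isfinite(t)) t = 0.5;
  for (int c = 0; c < 3; ++c) out[c] = p1[c] + t * (p2[c] - p1[c]);
}

static inline double tri_area(const double* a, const double* b,
                              const double* c) {
  double u[3], v[3], w[3];
  for (int i = 0; i < 3; ++i) { u[i] = b[i] - a[i]; v[i] = c[i] - a[i]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// [[Rcpp::export(name = ".cpp_march_tets")]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double h,
                    bool keep_triangles) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* f = field.begin();
  double area = 0.0;
  std::vector<double> tris; // 9 doubles per triangle
  if (keep_triangles) tris.reserve(1 << 18);

  double corner[8][3], val[8];
  double pts[4][3]; // intersection points within one tetrahedron

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_pos = false, any_neg = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          val[c] = f[(i + di) + (size_t)nx * ((j + dj) + (size_t)ny * (k + dk))];
          corner[c][0] = (i + di) * h;
          corner[c][1] = (j + dj) * h;
          corner[c][2] = (k + dk) * h;
          if (val[c] >= 0) any_pos = true; else any_neg = true;
        }
        if (!any_pos || !any_neg) continue;

        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int solid[4], nsolid = 0;
          for (int c = 0; c < 4; ++c) solid[c] = (val[T[c]] >= 0) ? 1 : 0,
                                      nsolid += solid[c];
          if (nsolid == 0 || nsolid == 4) continue;

          if (nsolid == 1 || nsolid == 3) {
            // one vertex isolated: a single triangle
            int iso = -1;
            int want = (nsolid == 1) ? 1 : 0;
            for (int c = 0; c < 4; ++c) if (solid[c] == want) iso = c;
            int np = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == iso) continue;
              interp(corner[T[iso]], corner[T[c]], val[T[iso]], val[T[c]],
                     pts[np++]);
            }
            area += tri_area(pts[0], pts[1], pts[2]);
            if (keep_triangles)
              for (int p = 0; p < 3; ++p)
                for (int c = 0; c < 3; ++c) tris.push_back(pts[p][c]);
          } else {
            // 2-2 split: quad across four edges, two triangles
            int a[2], b[2], na = 0, nb = 0;
            for (int c = 0; c < 4; ++c)
              if (solid[c]) a[na++] = c; else b[nb++] = c;
            // cycle a0-b0, a0-b1, a1-b1, a1-b0
            interp(corner[T[a[0]]], corner[T[b[0]]], val[T[a[0]]], val[T[b[0]]], pts[0]);
            interp(corner[T[a[0]]], corner[T[b[1]]], val[T[a[0]]], val[T[b[1]]], pts[1]);
            interp(corner[T[a[1]]], corner[T[b[1]]], val[T[a[1]]], val[T[b[1]]], pts[2]);
            interp(corner[T[a[1]]], corner[T[b[0]]], val[T[a[1]]], val[T[b[0]]], pts[3]);
            area += tri_area(pts[0], pts[1], pts[2]);
            area += tri_area(pts[0], pts[2], pts[3]);
            if (keep_triangles) {
              const int order[6] = {0, 1, 2, 0, 2, 3};
              for (int p = 0; p < 6; ++p)
                for (int c = 0; c < 3; ++c) tris.push_back(pts[order[p]][c]);
            }
          }
        }
      }
    }
  }

  List out = List::create(_["area"] = area);
  if (keep_triangles) {
    NumericMatrix m(3, tris.size() / 3);
    std::copy(tris.begin(), tris.end(), m.begin());
    out["triangles"] = m; // 3 x (3*ntri): columns are vertices
  }
  return out;
}

// Connected-component percolation filter for the flow domain. Keeps the
// 6-connected fluid components that touch both the inlet (layer 0) and the
// outlet (last layer) along `axis` (0-based). Returns the filtered mask;
// all-FALSE when nothing percolates.
// [[Rcpp::export(name = ".cpp_percolating_mask")]]
LogicalVector cpp_percolating_mask(LogicalVector fluid, IntegerVector dims,
                                   int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  std::vector<bool> lo, hi;

  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };

  for (size_t s = 0; s < n; ++s) {
    if (!fluid[s] || label[s]) continue;
    ++next;
    lo.push_back(false); hi.push_back(false);
    label[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int i = c % nx, j = (c / nx) % ny, k = c / ((size_t)nx * ny);
      int pos[3] = {i, j, k}, ext[3] = {nx, ny, nz};
      if (pos[axis] == 0) lo[next - 1] = true;
      if (pos[axis] == ext[axis] - 1) hi[next - 1] = true;
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int d = 0; d < 6; ++d) {
        int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t q = idx(ii, jj, kk);
        if (fluid[q] && !label[q]) { label[q] = next; stack.push_back(q); }
      }
    }
  }

  LogicalVector out(n, false);
  for (size_t s = 0; s < n; ++s)
    if (label[s] && lo[label[s] - 1] && hi[label[s] - 1]) out[s] = true;
  out.attr("dim") = dims;
  return out;
}
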