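#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Voxel-based periodic homogenization with trilinear hexahedral elements.
//
// The unit cell is discretized into nx*ny*nz cubic voxels; displacements live
// on the periodic node grid of the same size. A macroscopic strain E is
// imposed through the split u = E.x + u~ with u~ periodic, leading to
// K u~ = -sum_e Ke (E.x_e). The global matrix is stored in a block-ELL
// layout (27 neighbor offsets x 3x3 blocks per node) and solved with
// block-Jacobi preconditioned conjugate gradients. Rigid translations (the
// only nullspace under periodic constraints) are projected out of the
// preconditioned residual.
//
// Voigt order used throughout: (xx, yy, zz, yz, xz, xy), engineering shear.

namespace {

// trilinear shape gradients on the reference cube [0,1]^3, scaled by 1/h
void shape_grad(double xi, double eta, double zeta, double h, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    double sx = (a & 1) ? 1.0 : -1.0;
    double sy = (a & 2) ? 1.0 : -1.0;
    double sz = (a & 4) ? 1.0 : -1.0;
    double fx = (a & 1) ? xi : (1.0 - xi);
    double fy = (a & 2) ? eta : (1.0 - eta);
    double fz = (a & 4) ? zeta : (1.0 - zeta);
    dN[a][0] = sx * fy * fz / h;
    dN[a][1] = fx * sy * fz / h;
    dN[a][2] = fx * fy * sz / h;
  }
}

void b_matrix(const double dN[8][3], double B[6][24]) {
  std::memset(B, 0, sizeof(double) * 6 * 24);
  for (int a = 0; a < 8; ++a) {
    int c = 3 * a;
    B[0][c + 0] = dN[a][0];
    B[1][c + 1] = dN[a][1];
    B[2][c + 2] = dN[a][2];
    B[3][c + 1] = dN[a][2]; B[3][c + 2] = dN[a][1]; // yz
    B[4][c + 0] = dN[a][2]; B[4][c + 2] = dN[a][0]; // xz
    B[5][c + 0] = dN[a][1]; B[5][c + 1] = dN[a][0]; // xy
  }
}

// 24x24 element stiffness for an h-cube. Cgp points to one 6x6 stiffness per
// 2x2x2 Gauss point (octant bit order x + 2y + 4z); with `per_gp` false a
// single constant stiffness is used for all points.
void ke_hex_gp(const double* Cgp, bool per_gp, double h, double* Ke) {
  std::memset(Ke, 0, sizeof(double) * 576);
  const double g1 = 0.5 - 0.5 / std::sqrt(3.0), g2 = 0.5 + 0.5 / std::sqrt(3.0);
  const double gp[2] = {g1, g2};
  const double w = h * h * h / 8.0;
  double dN[8][3], B[6][24], CB[6][24];
  for (int iz = 0; iz < 2; ++iz)
    for (int iy = 0; iy < 2; ++iy)
      for (int ix = 0; ix < 2; ++ix) {
        const double* C = per_gp ? Cgp + 36 * (ix + 2 * iy + 4 * iz) : Cgp;
        shape_grad(gp[ix], gp[iy], gp[iz], h, dN);
        b_matrix(dN, B);
        for (int r = 0; r < 6; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0;
            for (int m = 0; m < 6; ++m) s += C[r * 6 + m] * B[m][c];
            CB[r][c] = s;
          }
        for (int r = 0; r < 24; ++r)
          for (int c = 0; c < 24; ++c) {
            double s = 0;
            for (int m = 0; m < 6; ++m) s += B[m][r] * CB[m][c];
            Ke[r * 24 + c] += w * s;
          }
      }
}

void ke_hex(const double* C, double h, double* Ke) {
  ke_hex_gp(C, false, h, Ke);
}

// strain-displacement operators at the 8 Gauss points (octant bit order)
void b_gauss(double h, double B[8][6][24]) {
  const double g1 = 0.5 - 0.5 / std::sqrt(3.0), g2 = 0.5 + 0.5 / std::sqrt(3.0);
  const double gp[2] = {g1, g2};
  double dN[8][3];
  for (int iz = 0; iz < 2; ++iz)
    for (int iy = 0; iy < 2; ++iy)
      for (int ix = 0; ix < 2; ++ix) {
        shape_grad(gp[ix], gp[iy], gp[iz], h, dN);
        b_matrix(dN, B[ix + 2 * iy + 4 * iz]);
      }
}

struct Grid {
  int nx, ny, nz;
  std::vector<int> ip, im, jp, jm, kp, km;
  Grid(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_),
      ip(nx_), im(nx_), jp(ny_), jm(ny_), kp(nz_), km(nz_) {
    for (int i = 0; i < nx; ++i) { ip[i] = (i + 1) % nx; im[i] = (i + nx - 1) % nx; }
    for (int j = 0; j < ny; ++j) { jp[j] = (j + 1) % ny; jm[j] = (j + ny - 1) % ny; }
    for (int k = 0; k < nz; ++k) { kp[k] = (k + 1) % nz; km[k] = (k + nz - 1) % nz; }
  }
  inline size_t node(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

} // namespace

// mat_id: per-voxel material, 0 = void, 1 = solid, m >= 2 = composite row
// (m - 2) of comp_C (each row a 6x6 stiffness, row-major 36 values).
// macro_strain: engineering Voigt macroscopic strain.
// Returns volume-averaged stress, iteration count and relative residual.
// [[Rcpp::export(name = ".cpp_homogenize")]]
List cpp_homogenize(IntegerVector mat_id, IntegerVector dims, double h,
                    NumericVector C_solid, NumericVector C_void,
                    NumericMatrix comp_C, NumericVector macro_strain,
                    double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nel = (size_t)nx * ny * nz, nnode = nel, ndof = 3 * nnode;
  Grid g(nx, ny, nz);

  // element stiffness per material
  std::vector<double> Ke_s(576), Ke_v(576);
  ke_hex(C_solid.begin(), h, Ke_s.data());
  ke_hex(C_void.begin(), h, Ke_v.data());
  const int ncomp = comp_C.nrow();
  if (ncomp > 0 && comp_C.ncol() != 288)
    stop("composite stiffness rows must hold 8 x 36 values");
  std::vector<double> Ke_c((size_t)ncomp * 576);
  {
    std::vector<double> Crow(288);
    for (int m = 0; m < ncomp; ++m) {
      for (int q = 0; q < 288; ++q) Crow[q] = comp_C(m, q);
      ke_hex_gp(Crow.data(), true, h, Ke_c.data() + (size_t)m * 576);
    }
  }

  // affine nodal displacement for the macroscopic strain (element-local
  // corner coordinates; rigid translation per element is irrelevant)
  double eps[6];
  for (int q = 0; q < 6; ++q) eps[q] = macro_strain[q];
  double Et[3][3] = {
    {eps[0], eps[5] / 2, eps[4] / 2},
    {eps[5] / 2, eps[1], eps[3] / 2},
    {eps[4] / 2, eps[3] / 2, eps[2]}
  };
  double uaff[24];
  for (int a = 0; a < 8; ++a) {
    double x[3] = {h * (double)(a & 1), h * (double)((a >> 1) & 1),
                   h * (double)((a >> 2) & 1)};
    for (int r = 0; r < 3; ++r)
      uaff[3 * a + r] = Et[r][0] * x[0] + Et[r][1] * x[1] + Et[r][2] * x[2];
  }

  // block-ELL matrix: per node 27 neighbor offsets, 3x3 blocks
  std::vector<double> K((size_t)nnode * 27 * 9, 0.0);
  std::vector<double> b(ndof, 0.0);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t e = g.node(i, j, k);
        int m = mat_id[e];
        const double* Ke = (m == 1) ? Ke_s.data()
                          : (m == 0) ? Ke_v.data()
                          : Ke_c.data() + (size_t)(m - 2) * 576;
        int gi[2] = {i, g.ip[i]}, gj[2] = {j, g.jp[j]}, gk[2] = {k, g.kp[k]};
        size_t nd[8];
        for (int a = 0; a < 8; ++a)
          nd[a] = g.node(gi[a & 1], gj[(a >> 1) & 1], gk[(a >> 2) & 1]);
        for (int a = 0; a < 8; ++a) {
          int ax = a & 1, ay = (a >> 1) & 1, az = (a >> 2) & 1;
          double* Krow = K.data() + nd[a] * 243;
          double* brow = b.data() + 3 * nd[a];
          for (int bb = 0; bb < 8; ++bb) {
            int bx = bb & 1, by = (bb >> 1) & 1, bz = (bb >> 2) & 1;
            int off = (bx - ax + 1) + 3 * (by - ay + 1) + 9 * (bz - az + 1);
            double* blk = Krow + (size_t)off * 9;
            for (int r = 0; r < 3; ++r)
              for (int c = 0; c < 3; ++c)
                blk[3 * r + c] += Ke[(3 * a + r) * 24 + (3 * bb + c)];
          }
          // rhs: -Ke * uaff
          for (int r = 0; r < 3; ++r) {
            double s = 0;
            for (int c = 0; c < 24; ++c) s += Ke[(3 * a + r) * 24 + c] * uaff[c];
            brow[r] -= s;
          }
        }
      }

  // block-Jacobi preconditioner: inverse of the diagonal 3x3 blocks
  std::vector<double> Dinv((size_t)nnode * 9);
  for (size_t nidx = 0; nidx < nnode; ++nidx) {
    const double* dblk = K.data() + nidx * 243 + 13 * 9; // offset (0,0,0)
    double a11 = dblk[0], a12 = dblk[1], a13 = dblk[2];
    double a21 = dblk[3], a22 = dblk[4], a23 = dblk[5];
    double a31 = dblk[6], a32 = dblk[7], a33 = dblk[8];
    double det = a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31)
               + a13 * (a21 * a32 - a22 * a31);
    if (std::abs(det) < 1e-300) det = (det >= 0 ? 1e-300 : -1e-300);
    double* o = Dinv.data() + nidx * 9;
    o[0] = (a22 * a33 - a23 * a32) / det;
    o[1] = (a13 * a32 - a12 * a33) / det;
    o[2] = (a12 * a23 - a13 * a22) / det;
    o[3] = (a23 * a31 - a21 * a33) / det;
    o[4] = (a11 * a33 - a13 * a31) / det;
    o[5] = (a13 * a21 - a11 * a23) / det;
    o[6] = (a21 * a32 - a22 * a31) / det;
    o[7] = (a12 * a31 - a11 * a32) / det;
    o[8] = (a11 * a22 - a12 * a21) / det;
  }

  // neighbor node index table per node (27 offsets), built on the fly in the
  // matvec via wrap tables
  auto matvec = [&](const std::vector<double>& x, std::vector<double>& y) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        int kk[3] = {g.km[k], k, g.kp[k]};
        int jj[3] = {g.jm[j], j, g.jp[j]};
        for (int i = 0; i < nx; ++i) {
          int ii[3] = {g.im[i], i, g.ip[i]};
          size_t nidx = g.node(i, j, k);
          const double* Krow = K.data() + nidx * 243;
          double y0 = 0, y1 = 0, y2 = 0;
          int off = 0;
          for (int dz = 0; dz < 3; ++dz)
            for (int dy = 0; dy < 3; ++dy) {
              size_t base = (size_t)nx * ((size_t)jj[dy] + (size_t)ny * kk[dz]);
              for (int dx = 0; dx < 3; ++dx, ++off) {
                const double* blk = Krow + (size_t)off * 9;
                const double* xv = x.data() + 3 * (base + ii[dx]);
                y0 += blk[0] * xv[0] + blk[1] * xv[1] + blk[2] * xv[2];
                y1 += blk[3] * xv[0] + blk[4] * xv[1] + blk[5] * xv[2];
                y2 += blk[6] * xv[0] + blk[7] * xv[1] + blk[8] * xv[2];
              }
            }
          double* yv = y.data() + 3 * nidx;
          yv[0] = y0; yv[1] = y1; yv[2] = y2;
        }
      }
  };

  auto precond = [&](const std::vector<double>& r, std::vector<double>& z) {
    for (size_t nidx = 0; nidx < nnode; ++nidx) {
      const double* o = Dinv.data() + nidx * 9;
      const double* rv = r.data() + 3 * nidx;
      double* zv = z.data() + 3 * nidx;
      zv[0] = o[0] * rv[0] + o[1] * rv[1] + o[2] * rv[2];
      zv[1] = o[3] * rv[0] + o[4] * rv[1] + o[5] * rv[2];
      zv[2] = o[6] * rv[0] + o[7] * rv[1] + o[8] * rv[2];
    }
    // project out rigid translations
    double m0 = 0, m1 = 0, m2 = 0;
    for (size_t nidx = 0; nidx < nnode; ++nidx) {
      m0 += z[3 * nidx]; m1 += z[3 * nidx + 1]; m2 += z[3 * nidx + 2];
    }
    m0 /= nnode; m1 /= nnode; m2 /= nnode;
    for (size_t nidx = 0; nidx < nnode; ++nidx) {
      z[3 * nidx] -= m0; z[3 * nidx + 1] -= m1; z[3 * nidx + 2] -= m2;
    }
  };

  auto dot = [&](const std::vector<double>& a, const std::vector<double>& c) {
    double s = 0;
    for (size_t q = 0; q < a.size(); ++q) s += a[q] * c[q];
    return s;
  };

  // PCG
  std::vector<double> u(ndof, 0.0), r(b), z(ndof), p(ndof), Ap(ndof);
  double bnorm = std::sqrt(dot(b, b));
  // a homogeneous (or phase-wise affine-exact) cell has zero fluctuation:
  // the assembled rhs is pure round-off, measured against the matrix scale
  double kscale = 0.0;
  for (size_t nidx = 0; nidx < nnode; ++nidx) {
    const double* dblk = K.data() + nidx * 243 + 13 * 9;
    for (int q = 0; q < 9; ++q) kscale += dblk[q] * dblk[q];
  }
  double eps_scale = 0.0;
  for (int q = 0; q < 6; ++q) eps_scale = std::max(eps_scale, std::abs(eps[q]));
  double bfloor = 1e-10 * std::sqrt(kscale) * eps_scale * h;
  int iters = 0;
  double relres = 0.0;
  if (bnorm > bfloor) {
    precond(r, z);
    p = z;
    double rz = dot(r, z);
    for (iters = 1; iters <= maxit; ++iters) {
      matvec(p, Ap);
      double pAp = dot(p, Ap);
      if (pAp <= 0) break;
      double alpha = rz / pAp;
      for (size_t q = 0; q < ndof; ++q) { u[q] += alpha * p[q]; r[q] -= alpha * Ap[q]; }
      double rnorm = std::sqrt(dot(r, r));
      relres = rnorm / bnorm;
      if (relres < tol) break;
      precond(r, z);
      double rz_new = dot(r, z);
      double beta = rz_new / rz;
      rz = rz_new;
      for (size_t q = 0; q < ndof; ++q) p[q] = z[q] + beta * p[q];
      if (iters % 50 == 0) Rcpp::checkUserInterrupt();
    }
    if (iters > maxit) iters = maxit;
  }

  // volume-averaged stress: sigma = (1/V) sum_e sum_gp C_gp (E + B_gp u~_e)/8
  double Bg[8][6][24];
  b_gauss(h, Bg);
  double sigma[6] = {0, 0, 0, 0, 0, 0};
  std::vector<double> Crow(288);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t e = g.node(i, j, k);
        int m = mat_id[e];
        const double* Cc = (m == 1) ? C_solid.begin()
                          : (m == 0) ? C_void.begin() : nullptr;
        bool per_gp = (Cc == nullptr);
        if (per_gp) {
          for (int q = 0; q < 288; ++q) Crow[q] = comp_C(m - 2, q);
          Cc = Crow.data();
        }
        int gi[2] = {i, g.ip[i]}, gj[2] = {j, g.jp[j]}, gk[2] = {k, g.kp[k]};
        double ue[24];
        for (int a = 0; a < 8; ++a) {
          size_t nd = g.node(gi[a & 1], gj[(a >> 1) & 1], gk[(a >> 2) & 1]);
          ue[3 * a] = u[3 * nd]; ue[3 * a + 1] = u[3 * nd + 1];
          ue[3 * a + 2] = u[3 * nd + 2];
        }
        for (int gpq = 0; gpq < 8; ++gpq) {
          const double* C = per_gp ? Cc + 36 * gpq : Cc;
          double epse[6];
          for (int q = 0; q < 6; ++q) {
            double s = 0;
            for (int c = 0; c < 24; ++c) s += Bg[gpq][q][c] * ue[c];
            epse[q] = eps[q] + s;
          }
          for (int q = 0; q < 6; ++q) {
            double s = 0;
            for (int m2 = 0; m2 < 6; ++m2) s += C[q * 6 + m2] * epse[m2];
            sigma[q] += s / 8.0;
          }
        }
      }
  NumericVector sig(6);
  for (int q = 0; q < 6; ++q) sig[q] = sigma[q] / (double)nel;

  return List::create(_["sigma"] = sig, _["iterations"] = iters,
                      _["relres"] = relres);
}
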