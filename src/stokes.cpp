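#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steady incompressible Stokes flow through a voxelized void domain on a
// staggered (MAC) grid, driven by a uniform body force along z (equivalent,
// by linearity, to an applied mean pressure gradient). Boundary conditions:
// no-slip on solid voxels, no-slip walls on the four lateral domain sides,
// periodic along the flow axis. The saddle-point system
//   -mu Lap u + Grad p = f,  Div u = 0
// is solved by conjugate gradients on the pressure Schur complement
// (Uzawa-CG); each application performs three Jacobi-PCG vector-Laplacian
// solves. Tangential no-slip at solid/wall faces uses the standard halfway
// ghost reflection.

namespace {

struct Comp {
  int nx, ny, nz;             // array extents for this velocity component
  std::vector<char> act;
  std::vector<double> diagc;  // dimensionless diagonal stencil coefficient
  std::vector<int> nb;        // 6 neighbors per node, -1 => zero contribution
  size_t size() const { return (size_t)nx * ny * nz; }
  size_t id(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_stokes")]]
List cpp_stokes(LogicalVector fluid, IntegerVector dims, double h, double mu,
                double fz, double tol, int maxit_outer, int maxit_inner,
                bool keep_fields) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t ncell = (size_t)nx * ny * nz;
  auto cid = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  auto isfluid = [&](int i, int j, int k) -> bool {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return false; // lateral walls
    k = (k % nz + nz) % nz;                                  // periodic z
    return fluid[cid(i, j, k)];
  };

  // --- build the three staggered components -------------------------------
  // u: x-faces (nx+1, ny, nz); v: y-faces (nx, ny+1, nz); w: z-faces (nx, ny, nz)
  Comp U, V, W;
  U.nx = nx + 1; U.ny = ny; U.nz = nz;
  V.nx = nx; V.ny = ny + 1; V.nz = nz;
  W.nx = nx; W.ny = ny; W.nz = nz;

  // face center cell pair along the component's own axis: (prev cell, this cell)
  auto setup = [&](Comp& C, int axis) {
    C.act.assign(C.size(), 0);
    C.diagc.assign(C.size(), 0.0);
    C.nb.assign(C.size() * 6, -1);
    // pass 1: face activity (both adjacent cells fluid)
    for (int k = 0; k < C.nz; ++k)
      for (int j = 0; j < C.ny; ++j)
        for (int i = 0; i < C.nx; ++i) {
          int ca[3] = {i, j, k}, cb[3] = {i, j, k};
          ca[axis] -= 1; // cell on the negative side of the face
          C.act[C.id(i, j, k)] = isfluid(ca[0], ca[1], ca[2]) &&
                                 isfluid(cb[0], cb[1], cb[2]);
        }
    // pass 2: stencil coefficients (needs complete activity information)
    for (int k = 0; k < C.nz; ++k)
      for (int j = 0; j < C.ny; ++j)
        for (int i = 0; i < C.nx; ++i) {
          size_t s = C.id(i, j, k);
          if (!C.act[s]) continue;
          double dg = 0.0;
          for (int d = 0; d < 3; ++d)
            for (int sgn = -1; sgn <= 1; sgn += 2) {
              int ni = i + (d == 0 ? sgn : 0);
              int nj = j + (d == 1 ? sgn : 0);
              int nk = k + (d == 2 ? sgn : 0);
              bool wrapped = false;
              if (nk < 0) { nk += C.nz; wrapped = true; }
              if (nk >= C.nz) { nk -= C.nz; wrapped = true; }
              (void)wrapped;
              bool in_range = ni >= 0 && ni < C.nx && nj >= 0 && nj < C.ny;
              bool nact = in_range && C.act[C.id(ni, nj, nk)];
              int slot = 2 * d + (sgn + 1) / 2;
              if (d == axis) {
                // normal direction: neighbor face sits on the no-slip plane
                dg += 1.0;
                if (nact) C.nb[s * 6 + slot] = (int)C.id(ni, nj, nk);
              } else {
                // tangential: wall halfway between nodes -> ghost reflection
                if (nact) {
                  dg += 1.0;
                  C.nb[s * 6 + slot] = (int)C.id(ni, nj, nk);
                } else {
                  dg += 2.0;
                }
              }
            }
          C.diagc[s] = dg;
        }
  };
  setup(U, 0);
  setup(V, 1);
  setup(W, 2);

  const double ih2 = 1.0 / (h * h);

  auto applyA = [&](const Comp& C, const std::vector<double>& x,
                    std::vector<double>& y) {
    const size_t n = C.size();
    for (size_t s = 0; s < n; ++s) {
      if (!C.act[s]) { y[s] = 0.0; continue; }
      double acc = C.diagc[s] * x[s];
      const int* nb = &C.nb[s * 6];
      for (int d = 0; d < 6; ++d)
        if (nb[d] >= 0) acc -= x[nb[d]];
      y[s] = mu * ih2 * acc;
    }
  };

  // Jacobi-PCG solve of A x = b for one component; x used as warm start
  std::vector<double> cg_r, cg_z, cg_p, cg_q;
  long inner_total = 0;
  auto solveA = [&](const Comp& C, const std::vector<double>& b,
                    std::vector<double>& x, double itol) {
    const size_t n = C.size();
    cg_r.assign(n, 0.0); cg_z.assign(n, 0.0);
    cg_p.assign(n, 0.0); cg_q.assign(n, 0.0);
    applyA(C, x, cg_q);
    double bn = 0;
    for (size_t s = 0; s < n; ++s) {
      cg_r[s] = C.act[s] ? b[s] - cg_q[s] : 0.0;
      bn += C.act[s] ? b[s] * b[s] : 0.0;
    }
    bn = std::sqrt(bn);
    if (bn == 0) { for (size_t s = 0; s < n; ++s) x[s] = 0.0; return; }
    double rz = 0;
    for (size_t s = 0; s < n; ++s) {
      if (!C.act[s]) continue;
      cg_z[s] = cg_r[s] / (mu * ih2 * C.diagc[s]);
      rz += cg_r[s] * cg_z[s];
    }
    cg_p = cg_z;
    for (int it = 0; it < maxit_inner; ++it) {
      applyA(C, cg_p, cg_q);
      double pq = 0;
      for (size_t s = 0; s < n; ++s) pq += cg_p[s] * cg_q[s];
      if (pq <= 0) break;
      double alpha = rz / pq;
      double rn = 0;
      for (size_t s = 0; s < n; ++s) {
        x[s] += alpha * cg_p[s];
        cg_r[s] -= alpha * cg_q[s];
        rn += cg_r[s] * cg_r[s];
      }
      ++inner_total;
      if (std::sqrt(rn) < itol * bn) break;
      double rz_new = 0;
      for (size_t s = 0; s < n; ++s) {
        if (!C.act[s]) continue;
        cg_z[s] = cg_r[s] / (mu * ih2 * C.diagc[s]);
        rz_new += cg_r[s] * cg_z[s];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (size_t s = 0; s < n; ++s) cg_p[s] = cg_z[s] + beta * cg_p[s];
    }
  };

  // gradient/divergence between pressure (cells) and faces
  auto gradp = [&](const std::vector<double>& p, std::vector<double>& gu,
                   std::vector<double>& gv, std::vector<double>& gw) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          size_t s = U.id(i, j, k);
          gu[s] = U.act[s] ? (p[cid(i, j, k)] - p[cid(i - 1, j, k)]) / h : 0.0;
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t s = V.id(i, j, k);
          gv[s] = V.act[s] ? (p[cid(i, j, k)] - p[cid(i, j - 1, k)]) / h : 0.0;
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t s = W.id(i, j, k);
          int km = (k - 1 + nz) % nz;
          gw[s] = W.act[s] ? (p[cid(i, j, k)] - p[cid(i, j, km)]) / h : 0.0;
        }
  };

  auto divu = [&](const std::vector<double>& uu, const std::vector<double>& vv,
                  const std::vector<double>& ww, std::vector<double>& d) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t c = cid(i, j, k);
          if (!fluid[c]) { d[c] = 0.0; continue; }
          int kp = (k + 1) % nz;
          d[c] = (uu[U.id(i + 1, j, k)] - uu[U.id(i, j, k)]
                + vv[V.id(i, j + 1, k)] - vv[V.id(i, j, k)]
                + ww[W.id(i, j, kp)] - ww[W.id(i, j, k)]) / h;
        }
  };

  size_t nfluid = 0;
  for (size_t c = 0; c < ncell; ++c) nfluid += fluid[c] ? 1 : 0;
  if (nfluid == 0) stop("flow domain is empty");
  auto project = [&](std::vector<double>& p) {
    double m = 0;
    for (size_t c = 0; c < ncell; ++c) if (fluid[c]) m += p[c];
    m /= (double)nfluid;
    for (size_t c = 0; c < ncell; ++c) p[c] = fluid[c] ? p[c] - m : 0.0;
  };

  const double itol = 1e-10;

  // u0 = A^{-1} f (force only on w)
  std::vector<double> u0(U.size(), 0.0), v0(V.size(), 0.0), w0(W.size(), 0.0);
  std::vector<double> bw(W.size(), 0.0);
  for (size_t s = 0; s < W.size(); ++s) bw[s] = W.act[s] ? fz : 0.0;
  solveA(W, bw, w0, itol);
  // rhs for Schur: S' p = Gt A^{-1} f with Gt = -Div, so rhs = -Div(u0)
  std::vector<double> rhs(ncell, 0.0);
  divu(u0, v0, w0, rhs);
  for (size_t c = 0; c < ncell; ++c) rhs[c] = -rhs[c];
  project(rhs);

  // CG on S' = Gt A^{-1} G (SPD on mean-zero pressures)
  std::vector<double> p(ncell, 0.0), rp(rhs), zp(ncell), pp(ncell), Sp(ncell);
  std::vector<double> gu(U.size()), gv(V.size()), gw(W.size());
  std::vector<double> su(U.size(), 0.0), sv(V.size(), 0.0), sw(W.size(), 0.0);

  auto applyS = [&](const std::vector<double>& q, std::vector<double>& out) {
    gradp(q, gu, gv, gw);
    std::fill(su.begin(), su.end(), 0.0);
    std::fill(sv.begin(), sv.end(), 0.0);
    std::fill(sw.begin(), sw.end(), 0.0);
    solveA(U, gu, su, itol);
    solveA(V, gv, sv, itol);
    solveA(W, gw, sw, itol);
    divu(su, sv, sw, out);
    for (size_t c = 0; c < ncell; ++c) out[c] = -out[c]; // Gt = -Div
    project(out);
  };

  double rn0 = 0;
  for (size_t c = 0; c < ncell; ++c) rn0 += rp[c] * rp[c];
  rn0 = std::sqrt(rn0);
  int outer = 0;
  double relres = 0.0;
  if (rn0 > 0) {
    pp = rp;
    double rz = rn0 * rn0;
    for (outer = 1; outer <= maxit_outer; ++outer) {
      applyS(pp, Sp);
      double pq = 0;
      for (size_t c = 0; c < ncell; ++c) pq += pp[c] * Sp[c];
      if (pq <= 0) break;
      double alpha = rz / pq;
      double rn = 0;
      for (size_t c = 0; c < ncell; ++c) {
        p[c] += alpha * pp[c];
        rp[c] -= alpha * Sp[c];
        rn += rp[c] * rp[c];
      }
      relres = std::sqrt(rn) / rn0;
      if (relres < tol) break;
      double beta = rn / rz;
      rz = rn;
      for (size_t c = 0; c < ncell; ++c) pp[c] = rp[c] + beta * pp[c];
      Rcpp::checkUserInterrupt();
    }
    if (outer > maxit_outer) outer = maxit_outer;
  }

  // final velocity: u = A^{-1}(f - G p)
  gradp(p, gu, gv, gw);
  std::vector<double> bu(U.size()), bv(V.size());
  for (size_t s = 0; s < U.size(); ++s) bu[s] = U.act[s] ? -gu[s] : 0.0;
  for (size_t s = 0; s < V.size(); ++s) bv[s] = V.act[s] ? -gv[s] : 0.0;
  for (size_t s = 0; s < W.size(); ++s) bw[s] = W.act[s] ? fz - gw[s] : 0.0;
  std::fill(u0.begin(), u0.end(), 0.0);
  std::fill(v0.begin(), v0.end(), 0.0);
  std::fill(w0.begin(), w0.end(), 0.0);
  solveA(U, bu, u0, itol);
  solveA(V, bv, v0, itol);
  solveA(W, bw, w0, itol);

  // superficial velocity over the full cross-section, averaged along z
  double usum = 0;
  for (size_t s = 0; s < W.size(); ++s) usum += w0[s];
  double ubar = usum / (double)ncell;
  double kperm = mu * ubar / fz;

  List out = List::create(
    _["k"] = kperm, _["ubar"] = ubar,
    _["outer_iterations"] = outer, _["inner_iterations"] = (double)inner_total,
    _["relres"] = relres);
  if (keep_fields) {
    NumericVector wf(w0.begin(), w0.end());
    wf.attr("dim") = IntegerVector::create(nx, ny, nz);
    NumericVector pf(p.begin(), p.end());
    pf.attr("dim") = IntegerVector::create(nx, ny, nz);
    out["w"] = wf;
    out["p"] = pf;
  }
  return out;
}
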