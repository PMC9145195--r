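// Element kernels for the membrane FEM: Saint Venant-Kirchhoff energies on
// Biot or Green-Lagrange strain, follower pressure via per-cell enclosed
// volume, analytic gradients, and finite-difference element Hessians.
//
// Units: lengths in um, moduli/pressures in MPa, forces in uN (MPa*um^2),
// energies in uN*um.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Material codes
static const int MAT_ISO_BIOT = 0;
static const int MAT_ISO_GREEN = 1;
static const int MAT_ORTHO_GREEN = 2;

struct ElemPre {
  // 0-based node ids
  int n1, n2, n3;
  // inverse reference shape matrix (2x2, column-major)
  double b00, b10, b01, b11;
  double a0t;      // reference area * thickness
  int mat;
  double p1, p2, p3; // (lambda, mu, -) or (Ea, Eb, G)
};

// Energy density and gradient for one element given current node coords.
// xl: 9 doubles (x1,y1,z1,x2,...). g: 9 doubles out (accumulated? no: set).
// Returns energy (a0t * W). ok set to false on degenerate element.
static double elem_eg(const ElemPre& ep, const double* xl, double* g,
                      bool want_grad, bool* ok) {
  double d1[3], d2[3];
  for (int i = 0; i < 3; ++i) {
    d1[i] = xl[3 + i] - xl[i];
    d2[i] = xl[6 + i] - xl[i];
  }
  // F = [d1 d2] * B  (3x2)
  double F0[3], F1[3];
  for (int i = 0; i < 3; ++i) {
    F0[i] = d1[i] * ep.b00 + d2[i] * ep.b10;
    F1[i] = d1[i] * ep.b01 + d2[i] * ep.b11;
  }
  double c11 = F0[0]*F0[0] + F0[1]*F0[1] + F0[2]*F0[2];
  double c22 = F1[0]*F1[0] + F1[1]*F1[1] + F1[2]*F1[2];
  double c12 = F0[0]*F1[0] + F0[1]*F1[1] + F0[2]*F1[2];

  double W = 0.0;
  // dW/dF = F * M with M 2x2 symmetric (Green), or R*T for Biot.
  double P0[3], P1[3]; // dW/dF columns
  if (ep.mat == MAT_ISO_BIOT) {
    double detC = c11 * c22 - c12 * c12;
    if (detC <= 1e-20) { *ok = false; return 0.0; }
    double j2 = std::sqrt(detC);
    double s = std::sqrt(c11 + c22 + 2.0 * j2);
    if (s <= 1e-12) { *ok = false; return 0.0; }
    double u11 = (c11 + j2) / s, u22 = (c22 + j2) / s, u12 = c12 / s;
    double e11 = u11 - 1.0, e22 = u22 - 1.0, e12 = u12;
    double trE = e11 + e22;
    double lam = ep.p1, mu = ep.p2;
    W = 0.5 * lam * trE * trE + mu * (e11*e11 + 2.0*e12*e12 + e22*e22);
    if (want_grad) {
      double t11 = lam * trE + 2.0 * mu * e11;
      double t22 = lam * trE + 2.0 * mu * e22;
      double t12 = 2.0 * mu * e12;
      double detU = u11 * u22 - u12 * u12;
      if (std::fabs(detU) <= 1e-14) { *ok = false; return 0.0; }
      // M = U^{-1} * T (symmetric since T and U commute)
      double i11 = u22 / detU, i22 = u11 / detU, i12 = -u12 / detU;
      double m11 = i11 * t11 + i12 * t12;
      double m12 = i11 * t12 + i12 * t22;
      double m21 = i12 * t11 + i22 * t12;
      double m22 = i12 * t12 + i22 * t22;
      for (int i = 0; i < 3; ++i) {
        P0[i] = F0[i] * m11 + F1[i] * m21;
        P1[i] = F0[i] * m12 + F1[i] * m22;
      }
    }
  } else {
    double e11 = 0.5 * (c11 - 1.0), e22 = 0.5 * (c22 - 1.0), e12 = 0.5 * c12;
    double s11, s22, s12;
    if (ep.mat == MAT_ISO_GREEN) {
      double lam = ep.p1, mu = ep.p2;
      double trE = e11 + e22;
      W = 0.5 * lam * trE * trE + mu * (e11*e11 + 2.0*e12*e12 + e22*e22);
      s11 = lam * trE + 2.0 * mu * e11;
      s22 = lam * trE + 2.0 * mu * e22;
      s12 = 2.0 * mu * e12;
    } else { // MAT_ORTHO_GREEN, strain already in material frame
      double Ea = ep.p1, Eb = ep.p2, G = ep.p3;
      W = 0.5 * Ea * e11 * e11 + 0.5 * Eb * e22 * e22 + 2.0 * G * e12 * e12;
      s11 = Ea * e11;
      s22 = Eb * e22;
      s12 = 2.0 * G * e12;
    }
    if (want_grad) {
      for (int i = 0; i < 3; ++i) {
        P0[i] = F0[i] * s11 + F1[i] * s12;
        P1[i] = F0[i] * s12 + F1[i] * s22;
      }
    }
  }
  if (want_grad) {
    // dW/d[d1 d2] = P * B^T; nodal forces scaled by a0t
    for (int i = 0; i < 3; ++i) {
      double g2 = ep.a0t * (P0[i] * ep.b00 + P1[i] * ep.b01);
      double g3 = ep.a0t * (P0[i] * ep.b10 + P1[i] * ep.b11);
      g[3 + i] = g2;
      g[6 + i] = g3;
      g[i] = -(g2 + g3);
    }
  }
  return ep.a0t * W;
}

static std::vector<ElemPre> unpack(const IntegerMatrix& tri,
                                   const NumericMatrix& binv,
                                   const NumericVector& a0t,
                                   const IntegerVector& mat,
                                   const NumericMatrix& mp) {
  int m = tri.nrow();
  std::vector<ElemPre> eps((size_t)m);
  for (int e = 0; e < m; ++e) {
    ElemPre& ep = eps[e];
    ep.n1 = tri(e, 0) - 1; ep.n2 = tri(e, 1) - 1; ep.n3 = tri(e, 2) - 1;
    ep.b00 = binv(e, 0); ep.b10 = binv(e, 1);
    ep.b01 = binv(e, 2); ep.b11 = binv(e, 3);
    ep.a0t = a0t[e];
    ep.mat = mat[e];
    ep.p1 = mp(e, 0); ep.p2 = mp(e, 1); ep.p3 = mp(e, 2);
  }
  return eps;
}

static void gather(const NumericMatrix& x, const ElemPre& ep, double* xl) {
  for (int i = 0; i < 3; ++i) {
    xl[i]     = x(ep.n1, i);
    xl[3 + i] = x(ep.n2, i);
    xl[6 + i] = x(ep.n3, i);
  }
}

// [[Rcpp::export(name = ".cs_elastic")]]
List cs_elastic(const NumericMatrix& x, const IntegerMatrix& tri,
                const NumericMatrix& binv, const NumericVector& a0t,
                const IntegerVector& mat, const NumericMatrix& mp,
                bool grad = true) {
  std::vector<ElemPre> eps = unpack(tri, binv, a0t, mat, mp);
  int n = x.nrow();
  NumericMatrix g(n, 3);
  double energy = 0.0;
  double xl[9], gl[9];
  int bad = 0;
  for (size_t e = 0; e < eps.size(); ++e) {
    const ElemPre& ep = eps[e];
    gather(x, ep, xl);
    bool ok = true;
    energy += elem_eg(ep, xl, gl, grad, &ok);
    if (!ok) { bad = (int)e + 1; break; }
    if (grad) {
      for (int i = 0; i < 3; ++i) {
        g(ep.n1, i) += gl[i];
        g(ep.n2, i) += gl[3 + i];
        g(ep.n3, i) += gl[6 + i];
      }
    }
  }
  return List::create(_["energy"] = energy, _["grad"] = g, _["bad"] = bad);
}

// Per-element strain/stress recovery: returns J, energy density W,
// trace of Cauchy stress (MPa).
// [[Rcpp::export(name = ".cs_stress")]]
NumericMatrix cs_stress(const NumericMatrix& x, const IntegerMatrix& tri,
                        const NumericMatrix& binv, const NumericVector& a0t,
                        const IntegerVector& mat, const NumericMatrix& mp) {
  std::vector<ElemPre> eps = unpack(tri, binv, a0t, mat, mp);
  int m = (int)eps.size();
  NumericMatrix out(m, 3);
  colnames(out) = CharacterVector::create("J", "W", "cauchy_trace");
  double xl[9];
  for (int e = 0; e < m; ++e) {
    const ElemPre& ep = eps[e];
    gather(x, ep, xl);
    double d1[3], d2[3];
    for (int i = 0; i < 3; ++i) {
      d1[i] = xl[3 + i] - xl[i];
      d2[i] = xl[6 + i] - xl[i];
    }
    double F0[3], F1[3];
    for (int i = 0; i < 3; ++i) {
      F0[i] = d1[i] * ep.b00 + d2[i] * ep.b10;
      F1[i] = d1[i] * ep.b01 + d2[i] * ep.b11;
    }
    double c11 = F0[0]*F0[0] + F0[1]*F0[1] + F0[2]*F0[2];
    double c22 = F1[0]*F1[0] + F1[1]*F1[1] + F1[2]*F1[2];
    double c12 = F0[0]*F1[0] + F0[1]*F1[1] + F0[2]*F1[2];
    double detC = c11 * c22 - c12 * c12;
    double J = detC > 0 ? std::sqrt(detC) : 0.0;
    double W = 0.0, trsig = NA_REAL;
    if (ep.mat == MAT_ISO_BIOT) {
      double j2 = J;
      double s = std::sqrt(c11 + c22 + 2.0 * j2);
      double u11 = (c11 + j2) / s, u22 = (c22 + j2) / s, u12 = c12 / s;
      double e11 = u11 - 1.0, e22 = u22 - 1.0, e12 = u12;
      double trE = e11 + e22;
      double lam = ep.p1, mu = ep.p2;
      W = 0.5 * lam * trE * trE + mu * (e11*e11 + 2.0*e12*e12 + e22*e22);
      double t11 = lam * trE + 2.0 * mu * e11;
      double t22 = lam * trE + 2.0 * mu * e22;
      double t12 = 2.0 * mu * e12;
      if (J > 0)
        trsig = (t11 * u11 + 2.0 * t12 * u12 + t22 * u22) / J;
    } else {
      double e11 = 0.5 * (c11 - 1.0), e22 = 0.5 * (c22 - 1.0), e12 = 0.5 * c12;
      double s11, s22, s12;
      if (ep.mat == MAT_ISO_GREEN) {
        double lam = ep.p1, mu = ep.p2;
        double trE = e11 + e22;
        W = 0.5 * lam * trE * trE + mu * (e11*e11 + 2.0*e12*e12 + e22*e22);
        s11 = lam * trE + 2.0 * mu * e11;
        s22 = lam * trE + 2.0 * mu * e22;
        s12 = 2.0 * mu * e12;
      } else {
        double Ea = ep.p1, Eb = ep.p2, G = ep.p3;
        W = 0.5 * Ea * e11 * e11 + 0.5 * Eb * e22 * e22 + 2.0 * G * e12 * e12;
        s11 = Ea * e11;
        s22 = Eb * e22;
        s12 = 2.0 * G * e12;
      }
      if (J > 0)
        trsig = (s11 * c11 + 2.0 * s12 * c12 + s22 * c22) / J;
    }
    out(e, 0) = J; out(e, 1) = W; out(e, 2) = trsig;
  }
  return out;
}

// Finite-difference element Hessians of the analytic element gradient
// (forward differences, locally symmetrized). Returns 81 triplets per
// element in dof numbering dof = 3*(node-1) + axis (1-based).
// [[Rcpp::export(name = ".cs_elastic_hess")]]
List cs_elastic_hess(const NumericMatrix& x, const IntegerMatrix& tri,
                     const NumericMatrix& binv, const NumericVector& a0t,
                     const IntegerVector& mat, const NumericMatrix& mp,
                     double h = 1e-6) {
  std::vector<ElemPre> eps = unpack(tri, binv, a0t, mat, mp);
  int m = (int)eps.size();
  IntegerVector I(81 * (R_xlen_t)m), Jv(81 * (R_xlen_t)m);
  NumericVector V(81 * (R_xlen_t)m);
  double xl[9], g0[9], gp[9], H[81];
  R_xlen_t k = 0;
  for (int e = 0; e < m; ++e) {
    const ElemPre& ep = eps[e];
    gather(x, ep, xl);
    bool ok = true;
    elem_eg(ep, xl, g0, true, &ok);
    if (!ok) stop("degenerate element %d in Hessian evaluation", e + 1);
    for (int c = 0; c < 9; ++c) {
      double save = xl[c];
      xl[c] = save + h;
      elem_eg(ep, xl, gp, true, &ok);
      xl[c] = save;
      if (!ok) stop("degenerate element %d in Hessian evaluation", e + 1);
      for (int r = 0; r < 9; ++r) H[r + 9 * c] = (gp[r] - g0[r]) / h;
    }
    int dof[9];
    int nodes[3] = {ep.n1, ep.n2, ep.n3};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) dof[3 * a + i] = 3 * nodes[a] + i + 1;
    for (int c = 0; c < 9; ++c)
      for (int r = 0; r < 9; ++r) {
        I[k] = dof[r];
        Jv[k] = dof[c];
        V[k] = 0.5 * (H[r + 9 * c] + H[c + 9 * r]);
        ++k;
      }
  }
  return List::create(_["i"] = I, _["j"] = Jv, _["v"] = V);
}

// Values-only variants of the FD Hessians: the triplet (i, j) layout is
// identical on every call for a fixed mesh, so per-iteration reassembly
// only needs the values, in the same order.
// [[Rcpp::export(name = ".cs_elastic_hess_v")]]
NumericVector cs_elastic_hess_v(const NumericMatrix& x,
                                const IntegerMatrix& tri,
                                const NumericMatrix& binv,
                                const NumericVector& a0t,
                                const IntegerVector& mat,
                                const NumericMatrix& mp,
                                double h = 1e-6) {
  std::vector<ElemPre> eps = unpack(tri, binv, a0t, mat, mp);
  int m = (int)eps.size();
  int n = x.nrow();
  const double* xp = REAL(x);
  NumericVector V(81 * (R_xlen_t)m);
  double* Vp = REAL(V);
  double xl[9], g0[9], gp[9], H[81];
  R_xlen_t k = 0;
  for (int e = 0; e < m; ++e) {
    const ElemPre& ep = eps[e];
    for (int i = 0; i < 3; ++i) {
      xl[i]     = xp[ep.n1 + n * i];
      xl[3 + i] = xp[ep.n2 + n * i];
      xl[6 + i] = xp[ep.n3 + n * i];
    }
    bool ok = true;
    elem_eg(ep, xl, g0, true, &ok);
    if (!ok) stop("degenerate element %d in Hessian evaluation", e + 1);
    for (int c = 0; c < 9; ++c) {
      double save = xl[c];
      xl[c] = save + h;
      elem_eg(ep, xl, gp, true, &ok);
      xl[c] = save;
      if (!ok) stop("degenerate element %d in Hessian evaluation", e + 1);
      for (int r = 0; r < 9; ++r) H[r + 9 * c] = (gp[r] - g0[r]) / h;
    }
    for (int c = 0; c < 9; ++c)
      for (int r = 0; r < 9; ++r)
        Vp[k++] = 0.5 * (H[r + 9 * c] + H[c + 9 * r]);
  }
  return V;
}

// [[Rcpp::export(name = ".cs_pressure_hess_v")]]
NumericVector cs_pressure_hess_v(const NumericMatrix& x,
                                 const IntegerMatrix& faces,
                                 const NumericVector& faceP,
                                 double h = 1e-6) {
  int m = faces.nrow();
  int n = x.nrow();
  const double* xp = REAL(x);
  int mact = 0;
  for (int f = 0; f < m; ++f) if (faceP[f] != 0) ++mact;
  NumericVector V(81 * (R_xlen_t)mact);
  double* Vp = REAL(V);
  double xl[9], g0[9], gp[9], H[81];
  R_xlen_t k = 0;
  for (int f = 0; f < m; ++f) {
    double P = faceP[f];
    if (P == 0) continue;
    int nodes[3] = {faces(f, 0) - 1, faces(f, 1) - 1, faces(f, 2) - 1};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) xl[3 * a + i] = xp[nodes[a] + n * i];
    double s = -P / 6.0;
    auto pg = [&](const double* y, double* g) {
      const double* xa = y; const double* xb = y + 3; const double* xd = y + 6;
      g[0] = s * (xb[1]*xd[2] - xb[2]*xd[1]);
      g[1] = s * (xb[2]*xd[0] - xb[0]*xd[2]);
      g[2] = s * (xb[0]*xd[1] - xb[1]*xd[0]);
      g[3] = s * (xd[1]*xa[2] - xd[2]*xa[1]);
      g[4] = s * (xd[2]*xa[0] - xd[0]*xa[2]);
      g[5] = s * (xd[0]*xa[1] - xd[1]*xa[0]);
      g[6] = s * (xa[1]*xb[2] - xa[2]*xb[1]);
      g[7] = s * (xa[2]*xb[0] - xa[0]*xb[2]);
      g[8] = s * (xa[0]*xb[1] - xa[1]*xb[0]);
    };
    pg(xl, g0);
    for (int c = 0; c < 9; ++c) {
      double save = xl[c];
      xl[c] = save + h;
      pg(xl, gp);
      xl[c] = save;
      for (int r = 0; r < 9; ++r) H[r + 9 * c] = (gp[r] - g0[r]) / h;
    }
    for (int c = 0; c < 9; ++c)
      for (int r = 0; r < 9; ++r)
        Vp[k++] = 0.5 * (H[r + 9 * c] + H[c + 9 * r]);
  }
  return V;
}

// Enclosed volumes per cell from oriented closed face sets (divergence
// theorem, V = sum x1.(x2 x x3)/6). cellptr: 0-based offsets, length ncell+1.
// [[Rcpp::export(name = ".cs_cellvol")]]
NumericVector cs_cellvol(const NumericMatrix& x, const IntegerMatrix& faces,
                         const IntegerVector& cellptr) {
  int nc = cellptr.size() - 1;
  NumericVector vols(nc);
  for (int c = 0; c < nc; ++c) {
    double v = 0.0;
    for (int f = cellptr[c]; f < cellptr[c + 1]; ++f) {
      int a = faces(f, 0) - 1, b = faces(f, 1) - 1, d = faces(f, 2) - 1;
      double cx = x(b,1)*x(d,2) - x(b,2)*x(d,1);
      double cy = x(b,2)*x(d,0) - x(b,0)*x(d,2);
      double cz = x(b,0)*x(d,1) - x(b,1)*x(d,0);
      v += x(a,0)*cx + x(a,1)*cy + x(a,2)*cz;
    }
    vols[c] = v / 6.0;
  }
  return vols;
}

// Gradient of the pressure potential -sum_c P_c V_c(x): faceP holds the
// pressure of the owning cell for each (outward-oriented) face.
// [[Rcpp::export(name = ".cs_pressure_grad")]]
NumericMatrix cs_pressure_grad(const NumericMatrix& x,
                               const IntegerMatrix& faces,
                               const NumericVector& faceP) {
  int n = x.nrow(), m = faces.nrow();
  NumericMatrix g(n, 3);
  for (int f = 0; f < m; ++f) {
    double P = faceP[f];
    if (P == 0) continue;
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, d = faces(f, 2) - 1;
    double xa[3] = {x(a,0), x(a,1), x(a,2)};
    double xb[3] = {x(b,0), x(b,1), x(b,2)};
    double xd[3] = {x(d,0), x(d,1), x(d,2)};
    double s = -P / 6.0;
    // dV/dxa = xb x xd, dV/dxb = xd x xa, dV/dxd = xa x xb (each /6)
    g(a,0) += s * (xb[1]*xd[2] - xb[2]*xd[1]);
    g(a,1) += s * (xb[2]*xd[0] - xb[0]*xd[2]);
    g(a,2) += s * (xb[0]*xd[1] - xb[1]*xd[0]);
    g(b,0) += s * (xd[1]*xa[2] - xd[2]*xa[1]);
    g(b,1) += s * (xd[2]*xa[0] - xd[0]*xa[2]);
    g(b,2) += s * (xd[0]*xa[1] - xd[1]*xa[0]);
    g(d,0) += s * (xa[1]*xb[2] - xa[2]*xb[1]);
    g(d,1) += s * (xa[2]*xb[0] - xa[0]*xb[2]);
    g(d,2) += s * (xa[0]*xb[1] - xa[1]*xb[0]);
  }
  return g;
}

// FD Hessian of the pressure potential, per face (same convention as the
// elastic Hessian).
// [[Rcpp::export(name = ".cs_pressure_hess")]]
List cs_pressure_hess(const NumericMatrix& x, const IntegerMatrix& faces,
                      const NumericVector& faceP, double h = 1e-6) {
  int m = faces.nrow();
  int mact = 0;
  for (int f = 0; f < m; ++f) if (faceP[f] != 0) ++mact;
  IntegerVector I(81 * (R_xlen_t)mact), Jv2(81 * (R_xlen_t)mact);
  NumericVector V(81 * (R_xlen_t)mact);
  int* Ip = INTEGER(I); int* Jp = INTEGER(Jv2); double* Vp = REAL(V);
  R_xlen_t k = 0;
  double xl[9], g0[9], gp[9], H[81];
  for (int f = 0; f < m; ++f) {
    double P = faceP[f];
    if (P == 0) continue;
    int nodes[3] = {faces(f,0) - 1, faces(f,1) - 1, faces(f,2) - 1};
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) xl[3*a + i] = x(nodes[a], i);
    double s = -P / 6.0;
    auto pg = [&](const double* y, double* g) {
      const double* xa = y; const double* xb = y + 3; const double* xd = y + 6;
      g[0] = s * (xb[1]*xd[2] - xb[2]*xd[1]);
      g[1] = s * (xb[2]*xd[0] - xb[0]*xd[2]);
      g[2] = s * (xb[0]*xd[1] - xb[1]*xd[0]);
      g[3] = s * (xd[1]*xa[2] - xd[2]*xa[1]);
      g[4] = s * (xd[2]*xa[0] - xd[0]*xa[2]);
      g[5] = s * (xd[0]*xa[1] - xd[1]*xa[0]);
      g[6] = s * (xa[1]*xb[2] - xa[2]*xb[1]);
      g[7] = s * (xa[2]*xb[0] - xa[0]*xb[2]);
      g[8] = s * (xa[0]*xb[1] - xa[1]*xb[0]);
    };
    pg(xl, g0);
    for (int c = 0; c < 9; ++c) {
      double save = xl[c];
      xl[c] = save + h;
      pg(xl, gp);
      xl[c] = save;
      for (int r = 0; r < 9; ++r) H[r + 9*c] = (gp[r] - g0[r]) / h;
    }
    int dof[9];
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) dof[3*a + i] = 3 * nodes[a] + i + 1;
    for (int c = 0; c < 9; ++c)
      for (int r = 0; r < 9; ++r) {
        Ip[k] = dof[r];
        Jp[k] = dof[c];
        Vp[k] = 0.5 * (H[r + 9*c] + H[c + 9*r]);
        ++k;
      }
  }
  return List::create(_["i"] = I, _["j"] = Jv2, _["v"] = V);
}

// Accumulate triplet values into a fixed sparse slot layout:
// x[map[k]] += v[k] (map 1-based; v1 then v2 follow the map order).
// [[Rcpp::export(name = ".cs_accum")]]
NumericVector cs_accum(const IntegerVector& map, const NumericVector& v1,
                       const NumericVector& v2, int nnz) {
  NumericVector x(nnz);
  double* xp = REAL(x);
  const int* mp = INTEGER(map);
  R_xlen_t m1 = v1.size(), m2 = v2.size();
  const double* p1 = REAL(v1);
  for (R_xlen_t k = 0; k < m1; ++k) xp[mp[k] - 1] += p1[k];
  const double* p2 = REAL(v2);
  for (R_xlen_t k = 0; k < m2; ++k) xp[mp[m1 + k] - 1] += p2[k];
  return x;
}

// Uniform-weight Laplacian smoothing step restricted to free vertices.
// nbr/nbrptr: adjacency in CSR form (1-based ids, 0-based ptr).
// [[Rcpp::export(name = ".cs_smooth_step")]]
NumericMatrix cs_smooth_step(const NumericMatrix& x, const IntegerVector& nbr,
                             const IntegerVector& nbrptr,
                             const LogicalVector& free_vtx, double lambda) {
  int n = x.nrow();
  NumericMatrix out(clone(x));
  for (int v = 0; v < n; ++v) {
    if (!free_vtx[v]) continue;
    int a = nbrptr[v], b = nbrptr[v + 1];
    if (b <= a) continue;
    double mx = 0, my = 0, mz = 0;
    for (int k = a; k < b; ++k) {
      int w = nbr[k] - 1;
      mx += x(w, 0); my += x(w, 1); mz += x(w, 2);
    }
    double inv = 1.0 / (b - a);
    out(v, 0) = x(v, 0) + lambda * (mx * inv - x(v, 0));
    out(v, 1) = x(v, 1) + lambda * (my * inv - x(v, 1));
    out(v, 2) = x(v, 2) + lambda * (mz * inv - x(v, 2));
  }
  return out;
}
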