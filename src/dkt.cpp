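// Mixed finite-element kernel for the bilayer thickness-deformation energy:
// discrete Kirchhoff triangle (DKT, Batoz/Bathe/Ho 1980) interpolation for the
// curvature term, linear (CST) interpolation for the thickness-stretch term
// and the tension load, and the DKT rotation field for the tension-gradient
// term. Nodal degrees of freedom are (u, du/dx, du/dy).
//
// Energy density: kb/2 (lap u)^2 + Kt/(2 a^2) u^2 + tau (u/a + |grad u|^2 / 2)
// (the u/a tension coupling is optional).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ElemGeom {
  double x23, y23, x31, y31, x12, y12; // edge vectors
  double twoA;
  // Batoz side coefficients, sides k=4 (2-3), 5 (3-1), 6 (1-2)
  double a[3], b[3], c[3], d[3], e[3];
};

ElemGeom elem_geom(const double* x, const double* y) {
  ElemGeom g;
  g.x23 = x[1] - x[2]; g.y23 = y[1] - y[2];
  g.x31 = x[2] - x[0]; g.y31 = y[2] - y[0];
  g.x12 = x[0] - x[1]; g.y12 = y[0] - y[1];
  g.twoA = g.x31 * g.y12 - g.x12 * g.y31;
  const double xs[3] = {g.x23, g.x31, g.x12};
  const double ys[3] = {g.y23, g.y31, g.y12};
  for (int k = 0; k < 3; ++k) {
    double l2 = xs[k] * xs[k] + ys[k] * ys[k];
    g.a[k] = -xs[k] / l2;
    g.b[k] = 0.75 * xs[k] * ys[k] / l2;
    g.c[k] = (0.25 * xs[k] * xs[k] - 0.5 * ys[k] * ys[k]) / l2;
    g.d[k] = -ys[k] / l2;
    g.e[k] = (0.25 * ys[k] * ys[k] - 0.5 * xs[k] * xs[k]) / l2;
  }
  return g;
}

// quadratic shape functions N1..N6 (corner, corner, corner, mid23, mid31,
// mid12) and their (xi, eta) derivatives
void quad_N(double xi, double eta, double* N, double* Nxi, double* Neta) {
  double L = 1.0 - xi - eta;
  N[0] = L * (2 * L - 1); N[1] = xi * (2 * xi - 1); N[2] = eta * (2 * eta - 1);
  N[3] = 4 * xi * eta; N[4] = 4 * eta * L; N[5] = 4 * xi * L;
  Nxi[0] = 1 - 4 * L; Nxi[1] = 4 * xi - 1; Nxi[2] = 0;
  Nxi[3] = 4 * eta;   Nxi[4] = -4 * eta;   Nxi[5] = 4 * (L - xi);
  Neta[0] = 1 - 4 * L; Neta[1] = 0; Neta[2] = 4 * eta - 1;
  Neta[3] = 4 * xi;    Neta[4] = 4 * (L - eta); Neta[5] = -4 * xi;
}

// Hx, Hy as 9x6 coefficient matrices over N1..N6, Batoz DOF order
// (w1, tx1, ty1, w2, tx2, ty2, w3, tx3, ty3) with tx = dw/dy, ty = -dw/dx.
void H_coeffs(const ElemGeom& g, double Cx[9][6], double Cy[9][6]) {
  for (int i = 0; i < 9; ++i)
    for (int j = 0; j < 6; ++j) { Cx[i][j] = 0; Cy[i][j] = 0; }
  const double* a = g.a; const double* b = g.b; const double* c = g.c;
  const double* d = g.d; const double* e = g.e;
  // N indices: 3 = N4 (side 2-3 -> coeff index 0), 4 = N5 (side 3-1 -> 1),
  // 5 = N6 (side 1-2 -> 2)
  const int k4 = 0, k5 = 1, k6 = 2, N4 = 3, N5 = 4, N6 = 5;
  // Hx rows
  Cx[0][N6] = 1.5 * a[k6]; Cx[0][N5] = -1.5 * a[k5];
  Cx[1][N5] = b[k5]; Cx[1][N6] = b[k6];
  Cx[2][0] = 1; Cx[2][N5] = -c[k5]; Cx[2][N6] = -c[k6];
  Cx[3][N4] = 1.5 * a[k4]; Cx[3][N6] = -1.5 * a[k6];
  Cx[4][N6] = b[k6]; Cx[4][N4] = b[k4];
  Cx[5][1] = 1; Cx[5][N6] = -c[k6]; Cx[5][N4] = -c[k4];
  Cx[6][N5] = 1.5 * a[k5]; Cx[6][N4] = -1.5 * a[k4];
  Cx[7][N4] = b[k4]; Cx[7][N5] = b[k5];
  Cx[8][2] = 1; Cx[8][N4] = -c[k4]; Cx[8][N5] = -c[k5];
  // Hy rows
  Cy[0][N6] = 1.5 * d[k6]; Cy[0][N5] = -1.5 * d[k5];
  Cy[1][0] = -1; Cy[1][N5] = e[k5]; Cy[1][N6] = e[k6];
  Cy[2][N5] = -b[k5]; Cy[2][N6] = -b[k6];
  Cy[3][N4] = 1.5 * d[k4]; Cy[3][N6] = -1.5 * d[k6];
  Cy[4][1] = -1; Cy[4][N6] = e[k6]; Cy[4][N4] = e[k4];
  Cy[5][N6] = -b[k6]; Cy[5][N4] = -b[k4];
  Cy[6][N5] = 1.5 * d[k5]; Cy[6][N4] = -1.5 * d[k4];
  Cy[7][2] = -1; Cy[7][N4] = e[k4]; Cy[7][N5] = e[k5];
  Cy[8][N4] = -b[k4]; Cy[8][N5] = -b[k5];
}

// map a 9-vector in Batoz DOF order to (u, ux, uy) order:
// w = u, tx = uy, ty = -ux  =>  column(u) = col(w), column(ux) = -col(ty),
// column(uy) = col(tx)
void to_uxy(const double* hb, double* h) {
  for (int n = 0; n < 3; ++n) {
    h[3 * n + 0] = hb[3 * n + 0];
    h[3 * n + 1] = -hb[3 * n + 2];
    h[3 * n + 2] = hb[3 * n + 1];
  }
}

const double QP[3][2] = { {0.5, 0.0}, {0.5, 0.5}, {0.0, 0.5} };

// per-quadrature-point operator rows (in (u,ux,uy) DOF order):
// bsum = lap u row; gx, gy = rotation-field rows (= -grad u); m = linear u row
struct QRows { double bsum[9], gx[9], gy[9], m[9]; };

void elem_rows(const ElemGeom& g, QRows rows[3]) {
  double Cx[9][6], Cy[9][6];
  H_coeffs(g, Cx, Cy);
  for (int q = 0; q < 3; ++q) {
    double N[6], Nxi[6], Neta[6];
    quad_N(QP[q][0], QP[q][1], N, Nxi, Neta);
    double hx[9], hy[9], hxxi[9], hxeta[9], hyxi[9], hyeta[9];
    for (int i = 0; i < 9; ++i) {
      double sx = 0, sy = 0, sxx = 0, sxe = 0, syx = 0, sye = 0;
      for (int j = 0; j < 6; ++j) {
        sx += Cx[i][j] * N[j];   sy += Cy[i][j] * N[j];
        sxx += Cx[i][j] * Nxi[j]; sxe += Cx[i][j] * Neta[j];
        syx += Cy[i][j] * Nxi[j]; sye += Cy[i][j] * Neta[j];
      }
      hx[i] = sx; hy[i] = sy; hxxi[i] = sxx; hxeta[i] = sxe;
      hyxi[i] = syx; hyeta[i] = sye;
    }
    double b1[9], b2[9];
    for (int i = 0; i < 9; ++i) {
      b1[i] = (g.y31 * hxxi[i] + g.y12 * hxeta[i]) / g.twoA;
      b2[i] = (-g.x31 * hyxi[i] - g.x12 * hyeta[i]) / g.twoA;
    }
    double bsum[9], gx[9], gy[9];
    for (int i = 0; i < 9; ++i) { bsum[i] = b1[i] + b2[i]; gx[i] = hx[i]; gy[i] = hy[i]; }
    to_uxy(bsum, rows[q].bsum);
    to_uxy(gx, rows[q].gx);
    to_uxy(gy, rows[q].gy);
    double L = 1.0 - QP[q][0] - QP[q][1];
    double mrow[9] = {L, 0, 0, QP[q][0], 0, 0, QP[q][1], 0, 0};
    for (int i = 0; i < 9; ++i) rows[q].m[i] = mrow[i];
  }
}

void elem_matrices(const double* x, const double* y,
                   double kb, double kt_a2, double tau, double load_coef,
                   double K[9][9], double f[9], double* areaOut) {
  ElemGeom g = elem_geom(x, y);
  if (g.twoA <= 1e-14)
    stop("singular-element error: degenerate (non-ccw or zero-area) triangle");
  double A = 0.5 * g.twoA;
  *areaOut = A;
  QRows rows[3];
  elem_rows(g, rows);
  for (int i = 0; i < 9; ++i) { f[i] = 0; for (int j = 0; j < 9; ++j) K[i][j] = 0; }
  double wq = A / 3.0;
  for (int q = 0; q < 3; ++q) {
    const QRows& r = rows[q];
    for (int i = 0; i < 9; ++i) {
      for (int j = i; j < 9; ++j) {
        double v = kb * r.bsum[i] * r.bsum[j]
                 + tau * (r.gx[i] * r.gx[j] + r.gy[i] * r.gy[j])
                 + kt_a2 * r.m[i] * r.m[j];
        K[i][j] += wq * v;
      }
      f[i] += wq * load_coef * r.m[i]; // "internal tension" load: tau/a * int(M)
    }
  }
  for (int i = 0; i < 9; ++i)
    for (int j = 0; j < i; ++j) K[i][j] = K[j][i];
}

} // namespace

// [[Rcpp::export(name = ".dkt_element")]]
List dkt_element(NumericMatrix coords, double kappa_b, double kt_over_a2,
                 double tau, double tau_over_a, bool tau_u_coupling) {
  double x[3] = {coords(0, 0), coords(1, 0), coords(2, 0)};
  double y[3] = {coords(0, 1), coords(1, 1), coords(2, 1)};
  double K[9][9], f[9], A;
  double lc = tau_u_coupling ? tau_over_a : 0.0;
  elem_matrices(x, y, kappa_b, kt_over_a2, tau, lc, K, f, &A);
  NumericMatrix Km(9, 9); NumericVector fv(9);
  for (int i = 0; i < 9; ++i) { fv[i] = f[i]; for (int j = 0; j < 9; ++j) Km(i, j) = K[i][j]; }
  return List::create(_["K"] = Km, _["f"] = fv, _["area"] = A);
}

// [[Rcpp::export(name = ".dkt_assemble")]]
List dkt_assemble(NumericMatrix nodes, IntegerMatrix tris,
                  double kappa_b, double kt_over_a2,
                  double tau, double tau_over_a, bool tau_u_coupling) {
  int m = tris.nrow(), n = nodes.nrow();
  int nnz = 81 * m;
  IntegerVector ti(nnz), tj(nnz);
  NumericVector tv(nnz);
  NumericVector f(3 * n);
  double areatot = 0;
  int p = 0;
  double lc = tau_u_coupling ? tau_over_a : 0.0;
  for (int e = 0; e < m; ++e) {
    int nd[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    double x[3], y[3];
    for (int k = 0; k < 3; ++k) { x[k] = nodes(nd[k], 0); y[k] = nodes(nd[k], 1); }
    double K[9][9], fe[9], A;
    elem_matrices(x, y, kappa_b, kt_over_a2, tau, lc, K, fe, &A);
    areatot += A;
    int dof[9];
    for (int k = 0; k < 3; ++k)
      for (int c = 0; c < 3; ++c) dof[3 * k + c] = 3 * nd[k] + c;
    for (int i = 0; i < 9; ++i) {
      f[dof[i]] += fe[i];
      for (int j = 0; j < 9; ++j) {
        ti[p] = dof[i] + 1; tj[p] = dof[j] + 1; tv[p] = K[i][j]; ++p;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["v"] = tv,
                      _["f"] = f, _["area"] = areatot);
}

// Per-element energy split and gradient magnitudes for a solved DOF vector.
// [[Rcpp::export(name = ".dkt_energy_parts")]]
List dkt_energy_parts(NumericMatrix nodes, IntegerMatrix tris, NumericVector U,
                      double kappa_b, double kt_over_a2,
                      double tau, double tau_over_a, bool tau_u_coupling) {
  int m = tris.nrow();
  double Ecurv = 0, Estretch = 0, Egrad = 0, Eload = 0;
  NumericVector gmax(m);
  for (int e = 0; e < m; ++e) {
    int nd[3] = {tris(e, 0) - 1, tris(e, 1) - 1, tris(e, 2) - 1};
    double x[3], y[3], ue[9];
    for (int k = 0; k < 3; ++k) {
      x[k] = nodes(nd[k], 0); y[k] = nodes(nd[k], 1);
      for (int c = 0; c < 3; ++c) ue[3 * k + c] = U[3 * nd[k] + c];
    }
    ElemGeom g = elem_geom(x, y);
    double A = 0.5 * g.twoA;
    QRows rows[3];
    elem_rows(g, rows);
    double gm = 0;
    for (int q = 0; q < 3; ++q) {
      double lap = 0, gx = 0, gy = 0, uu = 0;
      for (int i = 0; i < 9; ++i) {
        lap += rows[q].bsum[i] * ue[i];
        gx += rows[q].gx[i] * ue[i];
        gy += rows[q].gy[i] * ue[i];
        uu += rows[q].m[i] * ue[i];
      }
      double wq = A / 3.0;
      Ecurv += wq * 0.5 * kappa_b * lap * lap;
      Estretch += wq * 0.5 * kt_over_a2 * uu * uu;
      Egrad += wq * 0.5 * tau * (gx * gx + gy * gy);
      if (tau_u_coupling) Eload += wq * tau_over_a * uu;
      double gn = std::sqrt(gx * gx + gy * gy);
      if (gn > gm) gm = gn;
    }
    gmax[e] = gm;
  }
  return List::create(_["curvature"] = Ecurv, _["stretch"] = Estretch,
                      _["tension_grad"] = Egrad, _["tension_u"] = Eload,
                      _["total"] = Ecurv + Estretch + Egrad + Eload,
                      _["grad_max"] = gmax);
}
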