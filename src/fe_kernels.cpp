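#include <Rcpp.h>
using namespace Rcpp;

// Constant-strain tetrahedron kernels.
// Strain vector ordering: (exx, eyy, ezz, gxy, gyz, gzx), engineering shear.

static void tet_grads(const double *x, const double *y, const double *z,
                      double grad[4][3], double *vol6) {
  // edge matrix relative to node 0
  double m[3][3] = {
    { x[1] - x[0], x[2] - x[0], x[3] - x[0] },
    { y[1] - y[0], y[2] - y[0], y[3] - y[0] },
    { z[1] - z[0], z[2] - z[0], z[3] - z[0] }
  };
  double det =
      m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
      m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
      m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  *vol6 = det;
  // inverse of m (rows are gradients of barycentric coords 1..3 wrt x,y,z)
  double inv[3][3];
  inv[0][0] =  (m[1][1] * m[2][2] - m[1][2] * m[2][1]) / det;
  inv[0][1] = -(m[0][1] * m[2][2] - m[0][2] * m[2][1]) / det;
  inv[0][2] =  (m[0][1] * m[1][2] - m[0][2] * m[1][1]) / det;
  inv[1][0] = -(m[1][0] * m[2][2] - m[1][2] * m[2][0]) / det;
  inv[1][1] =  (m[0][0] * m[2][2] - m[0][2] * m[2][0]) / det;
  inv[1][2] = -(m[0][0] * m[1][2] - m[0][2] * m[1][0]) / det;
  inv[2][0] =  (m[1][0] * m[2][1] - m[1][1] * m[2][0]) / det;
  inv[2][1] = -(m[0][0] * m[2][1] - m[0][1] * m[2][0]) / det;
  inv[2][2] =  (m[0][0] * m[1][1] - m[0][1] * m[1][0]) / det;
  for (int a = 0; a < 3; ++a) {
    grad[1 + a][0] = inv[a][0];
    grad[1 + a][1] = inv[a][1];
    grad[1 + a][2] = inv[a][2];
  }
  for (int c = 0; c < 3; ++c)
    grad[0][c] = -(grad[1][c] + grad[2][c] + grad[3][c]);
}

static void fill_B(const double grad[4][3], double B[6][12]) {
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 12; ++c) B[r][c] = 0.0;
  for (int a = 0; a < 4; ++a) {
    double bx = grad[a][0], by = grad[a][1], bz = grad[a][2];
    int c = 3 * a;
    B[0][c] = bx;
    B[1][c + 1] = by;
    B[2][c + 2] = bz;
    B[3][c] = by; B[3][c + 1] = bx;
    B[4][c + 1] = bz; B[4][c + 2] = by;
    B[5][c] = bz; B[5][c + 2] = bx;
  }
}

static void fill_D(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 6; ++c) D[r][c] = 0.0;
  for (int r = 0; r < 3; ++r) {
    for (int c = 0; c < 3; ++c) D[r][c] = lam;
    D[r][r] = lam + 2.0 * mu;
    D[r + 3][r + 3] = mu;
  }
}

// [[Rcpp::export(name = ".tet_stiffness_one")]]
NumericMatrix tet_stiffness_one(NumericMatrix coords, double E, double nu) {
  if (coords.nrow() != 4 || coords.ncol() != 3)
    stop("element coordinates must be a 4 x 3 matrix");
  double x[4], y[4], z[4];
  for (int a = 0; a < 4; ++a) {
    x[a] = coords(a, 0); y[a] = coords(a, 1); z[a] = coords(a, 2);
  }
  double grad[4][3], vol6;
  tet_grads(x, y, z, grad, &vol6);
  double vol = std::fabs(vol6) / 6.0;
  if (vol <= 1e-12)
    stop("degenerate tetrahedron: volume below tolerance (1e-12 mm^3)");
  double B[6][12], D[6][6], DB[6][12];
  fill_B(grad, B);
  fill_D(E, nu, D);
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 12; ++c) {
      double s = 0.0;
      for (int k = 0; k < 6; ++k) s += D[r][k] * B[k][c];
      DB[r][c] = s;
    }
  NumericMatrix K(12, 12);
  for (int r = 0; r < 12; ++r)
    for (int c = 0; c < 12; ++c) {
      double s = 0.0;
      for (int k = 0; k < 6; ++k) s += B[k][r] * DB[k][c];
      K(r, c) = s * vol;
    }
  return K;
}

// [[Rcpp::export(name = ".assemble_triplets")]]
List assemble_triplets(NumericMatrix nodes, IntegerMatrix elems,
                       NumericVector E, NumericVector nu) {
  const int ne = elems.nrow();
  if (E.size() != ne || nu.size() != ne)
    stop("per-element material vectors must match the element count");
  const R_xlen_t ntrip = (R_xlen_t)ne * 144;
  IntegerVector I(ntrip), J(ntrip);
  NumericVector X(ntrip);
  NumericVector vols(ne);

  double x[4], y[4], z[4], grad[4][3], B[6][12], D[6][6], DB[6][12];
  R_xlen_t t = 0;
  for (int e = 0; e < ne; ++e) {
    int n[4];
    for (int a = 0; a < 4; ++a) {
      n[a] = elems(e, a) - 1;
      x[a] = nodes(n[a], 0); y[a] = nodes(n[a], 1); z[a] = nodes(n[a], 2);
    }
    double vol6;
    tet_grads(x, y, z, grad, &vol6);
    double vol = std::fabs(vol6) / 6.0;
    if (vol <= 1e-12)
      stop("degenerate tetrahedron at element %d: volume below 1e-12 mm^3",
           e + 1);
    vols[e] = vol;
    fill_B(grad, B);
    fill_D(E[e], nu[e], D);
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 12; ++c) {
        double s = 0.0;
        for (int k = 0; k < 6; ++k) s += D[r][k] * B[k][c];
        DB[r][c] = s;
      }
    for (int r = 0; r < 12; ++r) {
      int gr = 3 * n[r / 3] + (r % 3) + 1;  // 1-based global DOF
      for (int c = 0; c < 12; ++c) {
        double s = 0.0;
        for (int k = 0; k < 6; ++k) s += B[k][r] * DB[k][c];
        I[t] = gr;
        J[t] = 3 * n[c / 3] + (c % 3) + 1;
        X[t] = s * vol;
        ++t;
      }
    }
  }
  return List::create(_["i"] = I, _["j"] = J, _["x"] = X,
                      _["volume"] = vols);
}

// [[Rcpp::export(name = ".element_strains")]]
NumericMatrix element_strains_cpp(NumericMatrix nodes, IntegerMatrix elems,
                                  NumericMatrix u) {
  const int ne = elems.nrow();
  NumericMatrix strain(ne, 6);
  double x[4], y[4], z[4], grad[4][3];
  for (int e = 0; e < ne; ++e) {
    int n[4];
    for (int a = 0; a < 4; ++a) {
      n[a] = elems(e, a) - 1;
      x[a] = nodes(n[a], 0); y[a] = nodes(n[a], 1); z[a] = nodes(n[a], 2);
    }
    double vol6;
    tet_grads(x, y, z, grad, &vol6);
    double exx = 0, eyy = 0, ezz = 0, gxy = 0, gyz = 0, gzx = 0;
    for (int a = 0; a < 4; ++a) {
      double ux = u(n[a], 0), uy = u(n[a], 1), uz = u(n[a], 2);
      double bx = grad[a][0], by = grad[a][1], bz = grad[a][2];
      exx += bx * ux;
      eyy += by * uy;
      ezz += bz * uz;
      gxy += by * ux + bx * uy;
      gyz += bz * uy + by * uz;
      gzx += bz * ux + bx * uz;
    }
    strain(e, 0) = exx; strain(e, 1) = eyy; strain(e, 2) = ezz;
    strain(e, 3) = gxy; strain(e, 4) = gyz; strain(e, 5) = gzx;
  }
  colnames(strain) = CharacterVector::create("exx", "eyy", "ezz",
                                             "gxy", "gyz", "gzx");
  return strain;
}
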