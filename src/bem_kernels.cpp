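// Galerkin boundary-element kernels for the PMCHWT transmission problem:
// assembly of the single-layer (T) and double-layer (K) operator matrices in
// an RWG (divergence-conforming edge) basis, plus far- and near-field
// evaluation of the resulting surface currents, and the direct Richards-Wolf
// imaging quadrature.
//
// Singular self/near interactions are handled by singularity extraction: the
// static kernel 1/(4 pi R) and its gradient are integrated analytically over
// the source triangle (closed-form potential integrals), the smooth
// remainder by the regular quadrature rule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
typedef std::complex<double> cplx;

static const cplx CI(0.0, 1.0);

// Dunavant 6-point degree-4 rule (barycentric coords, weights sum to 1).
static const int NQ = 6;
static const double QW[NQ] = {
  0.223381589678011, 0.223381589678011, 0.223381589678011,
  0.109951743655322, 0.109951743655322, 0.109951743655322};
static const double QA[NQ][3] = {
  {0.108103018168070, 0.445948490915965, 0.445948490915965},
  {0.445948490915965, 0.108103018168070, 0.445948490915965},
  {0.445948490915965, 0.445948490915965, 0.108103018168070},
  {0.816847572980459, 0.091576213509771, 0.091576213509771},
  {0.091576213509771, 0.816847572980459, 0.091576213509771},
  {0.091576213509771, 0.091576213509771, 0.816847572980459}};

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { V3 v = {x, y, z}; return v; }
static inline V3 operator-(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator*(double s, const V3& a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot3(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross3(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const V3& a) { return std::sqrt(dot3(a, a)); }

struct CV3 {
  cplx x, y, z;
};
static inline CV3 cv3() { CV3 v = {0.0, 0.0, 0.0}; return v; }

struct FaceGeom {
  V3 v1, v2, v3n, n, cen;
  double area, rad;
  V3 qp[NQ];
  double qw[NQ];
};

// Refined outer rule for near/singular pairs: the triangle is split into
// nu^2 congruent sub-triangles, each carrying the 6-point rule.  The inner
// integrals are edge-singular after extraction, so the plain 6-point outer
// rule is not accurate enough close to the source triangle.
static const int NSUB = 3;                 // nu: NSUB^2 sub-triangles
static void refined_outer(const FaceGeom& fg, std::vector<V3>& pts,
                          std::vector<double>& w) {
  pts.clear(); w.clear();
  const int nu = NSUB;
  double subarea = fg.area / (nu * nu);
  // barycentric lattice over (u, v) with u along v2, v along v3;
  // cell corners expressed in lattice units, Dunavant points mapped in
  for (int i = 0; i < nu; ++i) {
    for (int j = 0; j < nu - i; ++j) {
      double up[3][2] = {{(double)i, (double)j},
                         {(double)(i + 1), (double)j},
                         {(double)i, (double)(j + 1)}};
      double dn[3][2] = {{(double)(i + 1), (double)j},
                         {(double)(i + 1), (double)(j + 1)},
                         {(double)i, (double)(j + 1)}};
      for (int cell = 0; cell < 2; ++cell) {
        if (cell == 1 && j >= nu - 1 - i) continue;
        double (*cc)[2] = (cell == 0) ? up : dn;
        for (int q = 0; q < NQ; ++q) {
          double uu = (QA[q][0] * cc[0][0] + QA[q][1] * cc[1][0] +
                       QA[q][2] * cc[2][0]) / nu;
          double vv = (QA[q][0] * cc[0][1] + QA[q][1] * cc[1][1] +
                       QA[q][2] * cc[2][1]) / nu;
          V3 p = (1.0 - uu - vv) * fg.v1 + uu * fg.v2 + vv * fg.v3n;
          pts.push_back(p);
          w.push_back(QW[q] * subarea);
        }
      }
    }
  }
}

// Map the 6-point rule onto an arbitrary flat triangle (p1, p2, p3).
static void push_tri_rule(const V3& p1, const V3& p2, const V3& p3,
                          std::vector<V3>& pts, std::vector<double>& w) {
  double area = 0.5 * norm3(cross3(p2 - p1, p3 - p1));
  for (int q = 0; q < NQ; ++q) {
    pts.push_back(QA[q][0] * p1 + QA[q][1] * p2 + QA[q][2] * p3);
    w.push_back(QW[q] * area);
  }
}

// Outer rule geometrically graded toward the shared edge (A, B) of an
// edge-adjacent pair: the extracted inner integrals have a boundary layer
// there (normal-jump of the static double-layer kernel), which uniform
// refinement resolves only at first order.
static const int NGRADE = 12;
static void graded_outer_edge(const V3& A, const V3& B, const V3& C,
                              std::vector<V3>& pts, std::vector<double>& w) {
  pts.clear(); w.clear();
  double s_hi = 1.0;
  for (int j = 0; j < NGRADE; ++j) {
    double s_lo = s_hi * 0.5;
    V3 P1 = (1 - s_hi) * A + s_hi * C, P2 = (1 - s_hi) * B + s_hi * C;
    V3 P3 = (1 - s_lo) * B + s_lo * C, P4 = (1 - s_lo) * A + s_lo * C;
    push_tri_rule(P1, P2, P3, pts, w);
    push_tri_rule(P1, P3, P4, pts, w);
    s_hi = s_lo;
  }
  V3 P3 = (1 - s_hi) * B + s_hi * C, P4 = (1 - s_hi) * A + s_hi * C;
  push_tri_rule(A, B, P3, pts, w);
  push_tri_rule(A, P3, P4, pts, w);
}

// Outer rule graded toward the shared vertex A of a vertex-adjacent pair.
static void graded_outer_vertex(const V3& A, const V3& B, const V3& C,
                                std::vector<V3>& pts, std::vector<double>& w) {
  pts.clear(); w.clear();
  double s_hi = 1.0;
  for (int j = 0; j < NGRADE; ++j) {
    double s_lo = s_hi * 0.5;
    V3 B1 = A + s_lo * (B - A), C1 = A + s_lo * (C - A);
    V3 B2 = A + s_hi * (B - A), C2 = A + s_hi * (C - A);
    push_tri_rule(B1, B2, C2, pts, w);
    push_tri_rule(B1, C2, C1, pts, w);
    s_hi = s_lo;
  }
  push_tri_rule(A, A + s_hi * (B - A), A + s_hi * (C - A), pts, w);
}

// [[Rcpp::export]]
Rcpp::List graded_outer_debug(const arma::mat& V, int mode) {
  V3 A = v3(V(0,0), V(0,1), V(0,2));
  V3 B = v3(V(1,0), V(1,1), V(1,2));
  V3 C = v3(V(2,0), V(2,1), V(2,2));
  std::vector<V3> pts;
  std::vector<double> w;
  if (mode == 0) graded_outer_edge(A, B, C, pts, w);
  else graded_outer_vertex(A, B, C, pts, w);
  arma::mat P(pts.size(), 3);
  arma::vec W(w.size());
  for (size_t i = 0; i < pts.size(); ++i) {
    P(i,0) = pts[i].x; P(i,1) = pts[i].y; P(i,2) = pts[i].z;
    W(i) = w[i];
  }
  return Rcpp::List::create(Rcpp::Named("pts") = P, Rcpp::Named("w") = W);
}

static std::vector<FaceGeom> face_geometry(const mat& V, const umat& F) {
  std::vector<FaceGeom> g(F.n_rows);
  for (uword f = 0; f < F.n_rows; ++f) {
    FaceGeom& fg = g[f];
    fg.v1 = v3(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
    fg.v2 = v3(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
    fg.v3n = v3(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
    V3 cr = cross3(fg.v2 - fg.v1, fg.v3n - fg.v1);
    double nn = norm3(cr);
    fg.area = 0.5 * nn;
    fg.n = (1.0 / nn) * cr;
    fg.cen = (1.0 / 3.0) * (fg.v1 + fg.v2 + fg.v3n);
    fg.rad = std::max(std::max(norm3(fg.v1 - fg.cen), norm3(fg.v2 - fg.cen)),
                      norm3(fg.v3n - fg.cen));
    for (int q = 0; q < NQ; ++q) {
      fg.qp[q] = QA[q][0] * fg.v1 + QA[q][1] * fg.v2 + QA[q][2] * fg.v3n;
      fg.qw[q] = QW[q] * fg.area;
    }
  }
  return g;
}

// Analytic potential integrals of the static kernel over a triangle:
//   I0  = int_T 1/R dS',  Iv = int_T (r'-rho)/R dS',  gI0 = grad_x I0,
// with rho the in-plane projection of the observation point x.
static void static_integrals(const FaceGeom& fg, const V3& x,
                             double& I0, V3& Iv, V3& gI0) {
  double d = dot3(x - fg.v1, fg.n);
  V3 rho = x - d * fg.n;
  const V3* vs[4] = {&fg.v1, &fg.v2, &fg.v3n, &fg.v1};
  I0 = 0.0;
  Iv = v3(0, 0, 0);
  gI0 = v3(0, 0, 0);
  double beta_sum = 0.0;
  for (int e = 0; e < 3; ++e) {
    V3 a = *vs[e], b = *vs[e + 1];
    V3 s = (1.0 / norm3(b - a)) * (b - a);
    V3 m = cross3(s, fg.n);                  // outward in-plane edge normal
    double lm = dot3(a - rho, s), lp = dot3(b - rho, s);
    double P = dot3(a - rho, m);             // signed distance to edge line
    double R02 = P * P + d * d;
    double Rm = norm3(x - a), Rp = norm3(x - b);
    double f2 = 0.0;
    double denom_m = Rm + lm, denom_p = Rp + lp;
    if (denom_m > 1e-300 && denom_p > 1e-300)
      f2 = std::log(denom_p / denom_m);
    double beta = std::atan2(P * lp, R02 + std::fabs(d) * Rp) -
                  std::atan2(P * lm, R02 + std::fabs(d) * Rm);
    I0 += P * f2;
    beta_sum += beta;
    Iv = Iv + (0.5 * (R02 * f2 + lp * Rp - lm * Rm)) * m;
    gI0 = gI0 - f2 * m;
  }
  I0 -= std::fabs(d) * beta_sum;
  double sgn = (d > 0.0) ? 1.0 : ((d < 0.0) ? -1.0 : 0.0);
  gI0 = gI0 - (sgn * beta_sum) * fg.n;
  Iv = Iv + I0 * rho;                        // now Iv = int r'/R dS'
}

// Inner integrals over a source triangle for one observation point:
//  IG = int G dS', IGv = int G r' dS', IgG = int grad_x G dS'
static void inner_integrals(const FaceGeom& fs, const V3& x, cplx k,
                            bool extract, cplx& IG, CV3& IGv, CV3& IgG) {
  const double inv4pi = 1.0 / (4.0 * M_PI);
  IG = 0.0;
  IGv = cv3();
  IgG = cv3();
  if (extract) {
    double I0;
    V3 Iv, gI0;
    static_integrals(fs, x, I0, Iv, gI0);
    IG = I0 * inv4pi;
    IGv.x = Iv.x * inv4pi; IGv.y = Iv.y * inv4pi; IGv.z = Iv.z * inv4pi;
    IgG.x = gI0.x * inv4pi; IgG.y = gI0.y * inv4pi; IgG.z = gI0.z * inv4pi;
    for (int q = 0; q < NQ; ++q) {
      V3 dxy = x - fs.qp[q];
      double R = norm3(dxy);
      double w = fs.qw[q];
      cplx gs, dgs;
      if (R < 1e-12 * fs.rad) {
        gs = CI * k * inv4pi;
        dgs = 0.0;
      } else {
        cplx e = std::exp(CI * k * R);
        gs = (e - 1.0) / R * inv4pi;
        // grad(G - G0) = (x-y) [ (ikR - 1) e^{ikR} + 1 ] / (4 pi R^3)
        dgs = ((CI * k * R - 1.0) * e + 1.0) / (R * R * R) * inv4pi;
      }
      IG += w * gs;
      IGv.x += w * gs * fs.qp[q].x; IGv.y += w * gs * fs.qp[q].y;
      IGv.z += w * gs * fs.qp[q].z;
      IgG.x += w * dgs * dxy.x; IgG.y += w * dgs * dxy.y; IgG.z += w * dgs * dxy.z;
    }
  } else {
    for (int q = 0; q < NQ; ++q) {
      V3 dxy = x - fs.qp[q];
      double R = norm3(dxy);
      double w = fs.qw[q];
      cplx g = std::exp(CI * k * R) * (inv4pi / R);
      cplx dg = g * (CI * k - 1.0 / R) / R;
      IG += w * g;
      IGv.x += w * g * fs.qp[q].x; IGv.y += w * g * fs.qp[q].y;
      IGv.z += w * g * fs.qp[q].z;
      IgG.x += w * dg * dxy.x; IgG.y += w * dg * dxy.y; IgG.z += w * dg * dxy.z;
    }
  }
}

// Debug/validation access to the analytic static potential integrals over
// the first face of a mesh at one observation point.
// [[Rcpp::export]]
Rcpp::List static_integrals_debug(const arma::mat& V, const arma::umat& F,
                                  const arma::vec& x) {
  std::vector<FaceGeom> geo = face_geometry(V, F);
  double I0;
  V3 Iv, gI0;
  static_integrals(geo[0], v3(x(0), x(1), x(2)), I0, Iv, gI0);
  return Rcpp::List::create(
    Rcpp::Named("I0") = I0,
    Rcpp::Named("Iv") = Rcpp::NumericVector::create(Iv.x, Iv.y, Iv.z),
    Rcpp::Named("gI0") = Rcpp::NumericVector::create(gI0.x, gI0.y, gI0.z));
}

// Debug access to the inner integrals over the first face of a mesh.
// [[Rcpp::export]]
Rcpp::List inner_integrals_debug(const arma::mat& V, const arma::umat& F,
                                 const arma::vec& x,
                                 const std::complex<double>& k, bool extract) {
  std::vector<FaceGeom> geo = face_geometry(V, F);
  cplx IG;
  CV3 IGv, IgG;
  inner_integrals(geo[0], v3(x(0), x(1), x(2)), k, extract, IG, IGv, IgG);
  return Rcpp::List::create(
    Rcpp::Named("IG") = IG,
    Rcpp::Named("IGv_x") = IGv.x, Rcpp::Named("IGv_y") = IGv.y,
    Rcpp::Named("IGv_z") = IGv.z,
    Rcpp::Named("IgG_x") = IgG.x, Rcpp::Named("IgG_y") = IgG.y,
    Rcpp::Named("IgG_z") = IgG.z);
}

// ---------------------------------------------------------------------------
// Duffy-type (Sauter-Schwab) 4D quadrature for the strongly singular
// double-layer kernel on touching triangle pairs.  The Galerkin entry
//   K[m,n] = iint f_m(x) . (grad_x G(x,y) x f_n(y)) dS_x dS_y
// is finite only through a four-dimensional cancellation at the shared
// edge/vertex; splitting it into an exact inner integral and a numeric outer
// one diverges logarithmically there.  The transforms below remove the
// singularity by radial scaling so that tensor Gauss rules converge.

static const int NGL = 5;
static const double GLX[NGL] = {0.046910077030668, 0.230765344947158,
  0.5, 0.769234655052842, 0.953089922969332};
static const double GLW[NGL] = {0.118463442528095, 0.239314335249683,
  0.284444444444444, 0.239314335249683, 0.118463442528095};

struct KAccum {
  // per (local obs edge, local src edge) accumulation of the K kernel
  cplx acc[3][3];
};

static inline void k_kernel_accum(const V3& x, const V3& y, cplx k,
                                  double wtot,
                                  const V3 vm[3], const double cm[3],
                                  const bool okm[3],
                                  const V3 vn[3], const double cn[3],
                                  const bool okn[3],
                                  KAccum& out) {
  V3 dxy = x - y;
  double R = norm3(dxy);
  if (R < 1e-14) return;
  cplx G = std::exp(CI * k * R) / (4.0 * M_PI * R);
  cplx gf = G * (CI * k - 1.0 / R) / R;
  // grad_x G = gf * (x - y)
  for (int es = 0; es < 3; ++es) {
    if (!okn[es]) continue;
    V3 fn = cn[es] * (y - vn[es]);
    V3 cr = cross3(dxy, fn);                 // (x-y) x f_n
    for (int eo = 0; eo < 3; ++eo) {
      if (!okm[eo]) continue;
      V3 fm = cm[eo] * (x - vm[eo]);
      out.acc[eo][es] += wtot * gf * dot3(fm, cr);
    }
  }
}

// Edge-adjacent pair: obs triangle (A, B, CO), src triangle (A, B, CS) with
// shared edge (A, B).  Parametrization x = (1-u)[(1-s)A + sB] + u CO (and
// likewise y), Jacobians (1-u) 2A_O (1-v) 2A_S; relative coordinate
// w = s - t; the 3D corner (w, u, v) -> radial Duffy split by the largest
// coordinate.
static void ss_K_edge(const V3& A, const V3& B, const V3& CO, const V3& CS,
                      double areaO, double areaS, cplx k,
                      const V3 vm[3], const double cm[3], const bool okm[3],
                      const V3 vn[3], const double cn[3], const bool okn[3],
                      KAccum& out) {
  for (int reg = 0; reg < 3; ++reg) {
    for (int il = 0; il < NGL; ++il)
    for (int i1 = 0; i1 < NGL; ++i1)
    for (int i2 = 0; i2 < NGL; ++i2)
    for (int it = 0; it < NGL; ++it) {
      double lam = GLX[il], m1 = GLX[i1], m2 = GLX[i2], tau = GLX[it];
      double w4 = GLW[il] * GLW[i1] * GLW[i2] * GLW[it];
      double wv, u, v;
      if (reg == 0)      { wv = lam;      u = lam * m1; v = lam * m2; }
      else if (reg == 1) { u = lam;       wv = lam * m1; v = lam * m2; }
      else               { v = lam;       wv = lam * m1; u = lam * m2; }
      if (wv > 1.0 || u > 1.0 || v > 1.0) continue;
      double jac_duffy = lam * lam;        // d(w,u,v) = lam^2 dlam dm1 dm2
      double tmax = 1.0 - wv;
      if (tmax <= 0) continue;
      double t = tmax * tau;
      double jac = jac_duffy * tmax * (1.0 - u) * (1.0 - v) *
                   4.0 * areaO * areaS;
      // two symmetric terms: s = t + w and s,t swapped
      for (int sym = 0; sym < 2; ++sym) {
        double s_ = (sym == 0) ? t + wv : t;
        double t_ = (sym == 0) ? t : t + wv;
        V3 x = (1.0 - u) * ((1.0 - s_) * A + s_ * B) + u * CO;
        V3 y = (1.0 - v) * ((1.0 - t_) * A + t_ * B) + v * CS;
        k_kernel_accum(x, y, k, w4 * jac, vm, cm, okm, vn, cn, okn, out);
      }
    }
  }
}

// Vertex-adjacent pair: obs triangle (A, BO, CO), src (A, BS, CS), shared
// vertex A.  Duffy per triangle (x = A + lam[(BO-A) + a(CO-BO)], Jacobian
// lam 2A_O), then radial split sigma <> lam.
static void ss_K_vertex(const V3& A, const V3& BO, const V3& CO,
                        const V3& BS, const V3& CS,
                        double areaO, double areaS, cplx k,
                        const V3 vm[3], const double cm[3], const bool okm[3],
                        const V3 vn[3], const double cn[3], const bool okn[3],
                        KAccum& out) {
  for (int reg = 0; reg < 2; ++reg) {
    for (int il = 0; il < NGL; ++il)
    for (int im = 0; im < NGL; ++im)
    for (int ia = 0; ia < NGL; ++ia)
    for (int ib = 0; ib < NGL; ++ib) {
      double lam = GLX[il], mu = GLX[im], a = GLX[ia], b = GLX[ib];
      double w4 = GLW[il] * GLW[im] * GLW[ia] * GLW[ib];
      double lo, so;                          // obs radius, src radius
      if (reg == 0) { lo = lam; so = lam * mu; }
      else          { so = lam; lo = lam * mu; }
      // d(lo, so) = lam dlam dmu; triangle Duffy maps add lo 2A_O, so 2A_S
      double jfull = lam * lo * so * 4.0 * areaO * areaS;
      V3 x = A + lo * ((BO - A) + a * (CO - BO));
      V3 y = A + so * ((BS - A) + b * (CS - BS));
      k_kernel_accum(x, y, k, w4 * jfull, vm, cm, okm, vn, cn, okn, out);
    }
  }
}

// Assemble the Galerkin matrices
//   T[m,n] = ik iint f_m.f_n G - (i/k) iint (div f_m)(div f_n) G
//   K[m,n] = iint f_m . (grad_x G x f_n)
// for wavenumber k, testing on mesh O against sources on mesh S (each given
// by vertices, faces, the RWG incidence face_edges / face_signs / face_opp
// and edge lengths).  O and S may be the same mesh (diagonal blocks) or two
// different closed surfaces (coated particles).
// [[Rcpp::export]]
Rcpp::List bem_assemble(const arma::mat& Vo, const arma::umat& Fo,
                        const arma::imat& feo, const arma::imat& fso,
                        const arma::umat& foo, const arma::vec& elo,
                        const arma::mat& Vs, const arma::umat& Fs,
                        const arma::imat& fes, const arma::imat& fss,
                        const arma::umat& fos, const arma::vec& els,
                        const std::complex<double>& k,
                        double near_factor = 2.0) {
  std::vector<FaceGeom> geo_o = face_geometry(Vo, Fo);
  std::vector<FaceGeom> geo_s = face_geometry(Vs, Fs);
  const uword nFo = Fo.n_rows, nFs = Fs.n_rows;
  const uword nEo = elo.n_elem, nEs = els.n_elem;
  cx_mat T(nEo, nEs, fill::zeros), K(nEo, nEs, fill::zeros);

  std::vector<V3> xr;
  std::vector<double> wr;
  std::vector<cplx> IG;
  std::vector<CV3> IGv, IgG;

  for (uword fo = 0; fo < nFo; ++fo) {
    const FaceGeom& go = geo_o[fo];
    for (uword fs = 0; fs < nFs; ++fs) {
      const FaceGeom& gs = geo_s[fs];
      V3 dc = go.cen - gs.cen;
      bool extract = norm3(dc) < near_factor * (go.rad + gs.rad);
      // classify touching pairs by shared vertex positions
      int shared = 0;
      bool is_sh[3] = {false, false, false};
      if (extract) {
        const V3* vo_[3] = {&go.v1, &go.v2, &go.v3n};
        const V3* vs_[3] = {&gs.v1, &gs.v2, &gs.v3n};
        double tol = 1e-9 * (go.rad + gs.rad);
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            if (norm3(*vo_[a] - *vs_[b]) < tol) { is_sh[a] = true; ++shared; break; }
      }
      bool use_ss = extract && shared >= 1;   // K handled by 4D quadrature
      if (extract && shared == 2) {
        // edge-adjacent: grade the outer rule toward the shared edge (T part)
        const V3* vo_[3] = {&go.v1, &go.v2, &go.v3n};
        int iC = !is_sh[0] ? 0 : (!is_sh[1] ? 1 : 2);
        graded_outer_edge(*vo_[(iC + 1) % 3], *vo_[(iC + 2) % 3], *vo_[iC],
                          xr, wr);
      } else if (extract && shared == 1) {
        const V3* vo_[3] = {&go.v1, &go.v2, &go.v3n};
        int iA = is_sh[0] ? 0 : (is_sh[1] ? 1 : 2);
        graded_outer_vertex(*vo_[iA], *vo_[(iA + 1) % 3], *vo_[(iA + 2) % 3],
                            xr, wr);
      } else if (extract) {
        // self term or near non-touching pair: uniformly refined outer rule
        refined_outer(go, xr, wr);
      } else {
        xr.assign(go.qp, go.qp + NQ);
        wr.assign(go.qw, go.qw + NQ);
      }
      size_t nq = xr.size();
      IG.resize(nq); IGv.resize(nq); IgG.resize(nq);
      for (size_t q = 0; q < nq; ++q)
        inner_integrals(gs, xr[q], k, extract, IG[q], IGv[q], IgG[q]);
      for (int eo = 0; eo < 3; ++eo) {
        int m = feo(fo, eo);
        if (m < 0) continue;
        double sm = fso(fo, eo);
        V3 vm = v3(Vo(foo(fo, eo), 0), Vo(foo(fo, eo), 1), Vo(foo(fo, eo), 2));
        double cm = sm * elo(m) / (2.0 * go.area);
        double divm = sm * elo(m) / go.area;
        for (int es = 0; es < 3; ++es) {
          int n = fes(fs, es);
          if (n < 0) continue;
          double sn = fss(fs, es);
          V3 vn = v3(Vs(fos(fs, es), 0), Vs(fos(fs, es), 1), Vs(fos(fs, es), 2));
          double cn = sn * els(n) / (2.0 * gs.area);
          double divn = sn * els(n) / gs.area;
          cplx tacc = 0.0, kacc = 0.0, sacc = 0.0;
          for (size_t q = 0; q < nq; ++q) {
            const V3& x = xr[q];
            double w = wr[q];
            double fmx = cm * (x.x - vm.x), fmy = cm * (x.y - vm.y),
                   fmz = cm * (x.z - vm.z);
            cplx sx = cn * (IGv[q].x - IG[q] * vn.x);
            cplx sy = cn * (IGv[q].y - IG[q] * vn.y);
            cplx sz = cn * (IGv[q].z - IG[q] * vn.z);
            tacc += w * (fmx * sx + fmy * sy + fmz * sz);
            sacc += w * IG[q];
            double ax = x.x - vn.x, ay = x.y - vn.y, az = x.z - vn.z;
            cplx crx = IgG[q].y * az - IgG[q].z * ay;
            cplx cry = IgG[q].z * ax - IgG[q].x * az;
            cplx crz = IgG[q].x * ay - IgG[q].y * ax;
            kacc += w * cn * (fmx * crx + fmy * cry + fmz * crz);
          }
          T(m, n) += CI * k * tacc - (CI / k) * divm * divn * sacc;
          if (!use_ss) K(m, n) += kacc;
        }
      }
      if (use_ss && shared < 3) {
        // local RWG data for the 9 edge-pair combinations
        V3 vm[3], vn[3];
        double cm[3], cn[3];
        bool okm[3], okn[3];
        for (int e = 0; e < 3; ++e) {
          okm[e] = feo(fo, e) >= 0;
          okn[e] = fes(fs, e) >= 0;
          if (okm[e]) {
            vm[e] = v3(Vo(foo(fo, e), 0), Vo(foo(fo, e), 1), Vo(foo(fo, e), 2));
            cm[e] = fso(fo, e) * elo(feo(fo, e)) / (2.0 * go.area);
          }
          if (okn[e]) {
            vn[e] = v3(Vs(fos(fs, e), 0), Vs(fos(fs, e), 1), Vs(fos(fs, e), 2));
            cn[e] = fss(fs, e) * els(fes(fs, e)) / (2.0 * gs.area);
          }
        }
        KAccum ka;
        for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) ka.acc[a][b] = 0.0;
        const V3* vo_[3] = {&go.v1, &go.v2, &go.v3n};
        const V3* vs_[3] = {&gs.v1, &gs.v2, &gs.v3n};
        double tol = 1e-9 * (go.rad + gs.rad);
        if (shared == 2) {
          int iC = !is_sh[0] ? 0 : (!is_sh[1] ? 1 : 2);
          V3 A = *vo_[(iC + 1) % 3], Bv = *vo_[(iC + 2) % 3], CO = *vo_[iC];
          int iCS = -1;
          for (int b = 0; b < 3; ++b) {
            bool match = false;
            for (int a = 0; a < 3; ++a)
              if (norm3(*vo_[a] - *vs_[b]) < tol) { match = true; break; }
            if (!match) iCS = b;
          }
          ss_K_edge(A, Bv, CO, *vs_[iCS], go.area, gs.area, k,
                    vm, cm, okm, vn, cn, okn, ka);
        } else {
          int iA = is_sh[0] ? 0 : (is_sh[1] ? 1 : 2);
          V3 A = *vo_[iA];
          int iAS = -1;
          for (int b = 0; b < 3; ++b)
            if (norm3(A - *vs_[b]) < tol) iAS = b;
          ss_K_vertex(A, *vo_[(iA + 1) % 3], *vo_[(iA + 2) % 3],
                      *vs_[(iAS + 1) % 3], *vs_[(iAS + 2) % 3],
                      go.area, gs.area, k, vm, cm, okm, vn, cn, okn, ka);
        }
        for (int eo = 0; eo < 3; ++eo) {
          int m = feo(fo, eo);
          if (m < 0) continue;
          for (int es = 0; es < 3; ++es) {
            int n = fes(fs, es);
            if (n < 0) continue;
            K(m, n) += ka.acc[eo][es];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("T") = T, Rcpp::Named("K") = K);
}

// Far-field amplitude of the surface currents in the host medium:
//   F(rhat) = (ik/4pi) int e^{-ik rhat.y} [ -eta (J - rhat (rhat.J))
//                                           + rhat x M ] dS'
// rhat may be complex (analytic continuation used by the interface
// correction); all products are bilinear (no conjugation).
// [[Rcpp::export]]
arma::cx_mat bem_farfield_eval(const arma::mat& V, const arma::umat& F,
                               const arma::imat& fe, const arma::imat& fs,
                               const arma::umat& fo, const arma::vec& el,
                               const arma::cx_vec& xJ, const arma::cx_vec& xM,
                               const arma::cx_mat& dirs,
                               const std::complex<double>& k,
                               const std::complex<double>& eta) {
  std::vector<FaceGeom> geo = face_geometry(V, F);
  const uword nD = dirs.n_rows, nF = F.n_rows;
  cx_mat out(nD, 3, fill::zeros);
  for (uword f = 0; f < nF; ++f) {
    const FaceGeom& g = geo[f];
    CV3 Jq[NQ], Mq[NQ];
    for (int q = 0; q < NQ; ++q) { Jq[q] = cv3(); Mq[q] = cv3(); }
    for (int e = 0; e < 3; ++e) {
      int m = fe(f, e);
      if (m < 0) continue;
      double c = fs(f, e) * el(m) / (2.0 * g.area);
      V3 vm = v3(V(fo(f, e), 0), V(fo(f, e), 1), V(fo(f, e), 2));
      for (int q = 0; q < NQ; ++q) {
        V3 r = g.qp[q] - vm;
        Jq[q].x += xJ(m) * c * r.x; Jq[q].y += xJ(m) * c * r.y;
        Jq[q].z += xJ(m) * c * r.z;
        Mq[q].x += xM(m) * c * r.x; Mq[q].y += xM(m) * c * r.y;
        Mq[q].z += xM(m) * c * r.z;
      }
    }
    for (uword d = 0; d < nD; ++d) {
      cplx rx = dirs(d, 0), ry = dirs(d, 1), rz = dirs(d, 2);
      cplx ax = 0.0, ay = 0.0, az = 0.0;
      for (int q = 0; q < NQ; ++q) {
        cplx ph = g.qw[q] *
          std::exp(-CI * k * (rx * g.qp[q].x + ry * g.qp[q].y + rz * g.qp[q].z));
        cplx rj = rx * Jq[q].x + ry * Jq[q].y + rz * Jq[q].z;
        ax += ph * (eta * (Jq[q].x - rj * rx) + (ry * Mq[q].z - rz * Mq[q].y));
        ay += ph * (eta * (Jq[q].y - rj * ry) + (rz * Mq[q].x - rx * Mq[q].z));
        az += ph * (eta * (Jq[q].z - rj * rz) + (rx * Mq[q].y - ry * Mq[q].x));
      }
      out(d, 0) += ax; out(d, 1) += ay; out(d, 2) += az;
    }
  }
  return (CI * k / (4.0 * M_PI)) * out;
}

// Scattered electric field at exterior points from the surface currents:
//   E(x) = -eta T(J)(x) + K(M)(x)
// evaluated with the regular quadrature rule (points must stay away from the
// surface; enforced on the R side).
// [[Rcpp::export]]
arma::cx_mat bem_nearfield_eval(const arma::mat& V, const arma::umat& F,
                                const arma::imat& fe, const arma::imat& fs,
                                const arma::umat& fo, const arma::vec& el,
                                const arma::cx_vec& xJ, const arma::cx_vec& xM,
                                const arma::mat& pts,
                                const std::complex<double>& k,
                                const std::complex<double>& eta) {
  std::vector<FaceGeom> geo = face_geometry(V, F);
  const uword nP = pts.n_rows, nF = F.n_rows;
  cx_mat out(nP, 3, fill::zeros);
  for (uword f = 0; f < nF; ++f) {
    const FaceGeom& g = geo[f];
    for (int q = 0; q < NQ; ++q) {
      const V3& y = g.qp[q];
      double w = g.qw[q];
      CV3 J = cv3(), M = cv3();
      cplx divJ = 0.0;
      for (int e = 0; e < 3; ++e) {
        int m = fe(f, e);
        if (m < 0) continue;
        double c = fs(f, e) * el(m) / (2.0 * g.area);
        V3 vm = v3(V(fo(f, e), 0), V(fo(f, e), 1), V(fo(f, e), 2));
        J.x += xJ(m) * c * (y.x - vm.x); J.y += xJ(m) * c * (y.y - vm.y);
        J.z += xJ(m) * c * (y.z - vm.z);
        M.x += xM(m) * c * (y.x - vm.x); M.y += xM(m) * c * (y.y - vm.y);
        M.z += xM(m) * c * (y.z - vm.z);
        divJ += xJ(m) * 2.0 * c;
      }
      for (uword p = 0; p < nP; ++p) {
        V3 x = v3(pts(p, 0), pts(p, 1), pts(p, 2));
        V3 dxy = x - y;
        double R = norm3(dxy);
        cplx G = std::exp(CI * k * R) / (4.0 * M_PI * R);
        cplx gf = G * (CI * k - 1.0 / R) / R;
        cplx gx = gf * dxy.x, gy = gf * dxy.y, gz = gf * dxy.z;
        cplx tx = eta * (CI * k * G * J.x + (CI / k) * divJ * gx)
                  + (gy * M.z - gz * M.y);
        cplx ty = eta * (CI * k * G * J.y + (CI / k) * divJ * gy)
                  + (gz * M.x - gx * M.z);
        cplx tz = eta * (CI * k * G * J.z + (CI / k) * divJ * gz)
                  + (gx * M.y - gy * M.x);
        out(p, 0) += w * tx; out(p, 1) += w * ty; out(p, 2) += w * tz;
      }
    }
  }
  return out;
}

// Direct Richards-Wolf quadrature: out[p,] = sum_j amp[j,] *
// exp(i (qx[j] x[p] + qy[j] y[p])) for the three Cartesian components.
// [[Rcpp::export]]
arma::cx_mat imaging_sum(const arma::vec& x, const arma::vec& y,
                         const arma::vec& qx, const arma::vec& qy,
                         const arma::cx_mat& amp) {
  const uword nP = x.n_elem, nJ = qx.n_elem;
  cx_mat out(nP, 3, fill::zeros);
  for (uword p = 0; p < nP; ++p) {
    cplx a0 = 0.0, a1 = 0.0, a2 = 0.0;
    for (uword j = 0; j < nJ; ++j) {
      cplx ph = std::exp(CI * (qx(j) * x(p) + qy(j) * y(p)));
      a0 += ph * amp(j, 0); a1 += ph * amp(j, 1); a2 += ph * amp(j, 2);
    }
    out(p, 0) = a0; out(p, 1) = a1; out(p, 2) = a2;
  }
  return out;
}
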