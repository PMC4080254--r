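#include <Rcpp.h>
using namespace Rcpp;

// Parameter layout (length-23 vector, fixed order):
// a1 a2 a3 a4 a5 a6 a7  b1 b2 b3 b4 b5 b6  c1 c2 c3 c4 c5 c6 c7  k1 k2 k3
//  0  1  2  3  4  5  6   7  8  9 10 11 12  13 14 15 16 17 18 19  20 21 22

static inline void rhs_raw(const double* p, double x, double y, double z,
                           double k2s, double mu, double* f) {
  double D1 = p[2] + p[3]*x + p[4]*y + p[5]*z + p[6]*x*z;
  double D2 = p[8] + p[9]*x + p[10]*y + p[11]*z + p[12]*y*z;
  double D3 = p[14] + p[15]*x + p[16]*y + p[17]*z + p[18]*x*z + p[19]*y*z;
  f[0] = (p[0]*x + p[1]*y)/D1 - p[20]*x + mu*k2s*y;
  f[1] = p[7]*y/D2 - p[21]*y - k2s*y;
  f[2] = p[13]*z/D3 - p[22]*z;
}

static inline void jac_raw(const double* p, double x, double y, double z,
                           double J[3][3]) {
  double N1 = p[0]*x + p[1]*y;
  double D1 = p[2] + p[3]*x + p[4]*y + p[5]*z + p[6]*x*z;
  double D2 = p[8] + p[9]*x + p[10]*y + p[11]*z + p[12]*y*z;
  double D3 = p[14] + p[15]*x + p[16]*y + p[17]*z + p[18]*x*z + p[19]*y*z;
  J[0][0] = (p[0]*D1 - N1*(p[3] + p[6]*z))/(D1*D1) - p[20];
  J[0][1] = (p[1]*D1 - N1*p[4])/(D1*D1);
  J[0][2] = -N1*(p[5] + p[6]*x)/(D1*D1);
  J[1][0] = -p[7]*y*p[9]/(D2*D2);
  J[1][1] = (p[7]*D2 - p[7]*y*(p[10] + p[12]*z))/(D2*D2) - p[21];
  J[1][2] = -p[7]*y*(p[11] + p[12]*y)/(D2*D2);
  J[2][0] = -p[13]*z*(p[15] + p[18]*z)/(D3*D3);
  J[2][1] = -p[13]*z*(p[16] + p[19]*z)/(D3*D3);
  J[2][2] = (p[13]*D3 - p[13]*z*(p[17] + p[18]*x + p[19]*y))/(D3*D3) - p[22];
}

// 3x3 linear solve, Gaussian elimination with partial pivoting
static bool solve3(double A[3][3], const double* b, double* out) {
  double M[3][4];
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) M[i][j] = A[i][j];
    M[i][3] = b[i];
  }
  for (int c = 0; c < 3; c++) {
    int piv = c;
    double best = std::fabs(M[c][c]);
    for (int r = c + 1; r < 3; r++)
      if (std::fabs(M[r][c]) > best) { best = std::fabs(M[r][c]); piv = r; }
    if (best < 1e-300) return false;
    if (piv != c) for (int j = 0; j < 4; j++) std::swap(M[c][j], M[piv][j]);
    for (int r = c + 1; r < 3; r++) {
      double f = M[r][c]/M[c][c];
      for (int j = c; j < 4; j++) M[r][j] -= f*M[c][j];
    }
  }
  for (int i = 2; i >= 0; i--) {
    double s = M[i][3];
    for (int j = i + 1; j < 3; j++) s -= M[i][j]*out[j];
    out[i] = s/M[i][i];
  }
  return true;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector state, NumericVector p, double k2s, double mu) {
  double f[3];
  rhs_raw(REAL(p), state[0], state[1], state[2], k2s, mu, f);
  return NumericVector::create(f[0], f[1], f[2]);
}

// [[Rcpp::export(name = ".jac_cpp")]]
NumericMatrix jac_cpp(NumericVector state, NumericVector p) {
  double J[3][3];
  jac_raw(REAL(p), state[0], state[1], state[2], J);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) out(i, j) = J[i][j];
  return out;
}

// Damped Newton iteration on the k2* = 0 right-hand side, clipped to the
// non-negative octant. Returns the final iterate and its max-norm residual.
// [[Rcpp::export(name = ".newton_cpp")]]
List newton_cpp(NumericVector init, NumericVector p, int maxit = 100,
                double tol = 1e-12) {
  double s[3] = {init[0], init[1], init[2]};
  double f[3];
  const double* pp = REAL(p);
  rhs_raw(pp, s[0], s[1], s[2], 0, 0, f);
  double res = std::max(std::fabs(f[0]), std::max(std::fabs(f[1]), std::fabs(f[2])));
  for (int it = 0; it < maxit && res > tol; it++) {
    double J[3][3], d[3];
    jac_raw(pp, s[0], s[1], s[2], J);
    if (!solve3(J, f, d)) break;
    double lam = 1.0;
    bool ok = false;
    for (int h = 0; h < 30; h++) {
      double s2[3] = {s[0] - lam*d[0], s[1] - lam*d[1], s[2] - lam*d[2]};
      for (int i = 0; i < 3; i++) if (s2[i] < 0) s2[i] = 0;
      double f2[3];
      rhs_raw(pp, s2[0], s2[1], s2[2], 0, 0, f2);
      double r2 = std::max(std::fabs(f2[0]), std::max(std::fabs(f2[1]), std::fabs(f2[2])));
      if (R_finite(r2) && r2 < res) {
        for (int i = 0; i < 3; i++) { s[i] = s2[i]; f[i] = f2[i]; }
        res = r2;
        ok = true;
        break;
      }
      lam *= 0.5;
    }
    if (!ok) break;
  }
  return List::create(_["root"] = NumericVector::create(s[0], s[1], s[2]),
                      _["residual"] = res);
}

// Poisson tau-leap over [0, t_end]: seven independent channels per step
// (three productions, three degradations with the extra GATA-2 channel
// folded in as its own draw, and the mu*k2*(t)*Y transfer into X).
// Negative excursions are clamped at zero and counted.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".tau_leap_cpp")]]
NumericMatrix tau_leap_cpp(NumericVector p, double mu, double k2star,
                           double t_on, double t_off, double tau,
                           double t_end, double save_every,
                           NumericVector init) {
  double a1 = p[0], a2 = p[1], a3 = p[2], a4 = p[3], a5 = p[4], a6 = p[5], a7 = p[6];
  double b1 = p[7], b2 = p[8], b3 = p[9], b4 = p[10], b5 = p[11], b6 = p[12];
  double c1 = p[13], c2 = p[14], c3 = p[15], c4 = p[16], c5 = p[17], c6 = p[18], c7 = p[19];
  double k1 = p[20], k2 = p[21], k3 = p[22];
  double X = init[0], Y = init[1], Z = init[2];
  int nsteps = (int) std::ceil(t_end/tau - 1e-9);
  int stride = (int) std::max(1.0, std::floor(save_every/tau + 0.5));
  int nsave = nsteps/stride + 1;
  NumericMatrix out(nsave, 4);
  out(0, 0) = 0; out(0, 1) = X; out(0, 2) = Y; out(0, 3) = Z;
  int isave = 1;
  double clamped = 0;
  double t = 0;
  RNGScope scope;
  for (int s = 0; s < nsteps; s++) {
    double ks = (t >= t_on && t <= t_off) ? k2star : 0.0;
    double D1 = a3 + a4*X + a5*Y + a6*Z + a7*X*Z;
    double D2 = b2 + b3*X + b4*Y + b5*Z + b6*Y*Z;
    double D3 = c2 + c3*X + c4*Y + c5*Z + c6*X*Z + c7*Y*Z;
    double dX = R::rpois((a1*X + a2*Y)/D1*tau) - R::rpois(k1*X*tau)
                + R::rpois(mu*ks*Y*tau);
    double dY = R::rpois(b1*Y/D2*tau) - R::rpois(k2*Y*tau) - R::rpois(ks*Y*tau);
    double dZ = R::rpois(c1*Z/D3*tau) - R::rpois(k3*Z*tau);
    X += dX; Y += dY; Z += dZ;
    if (X < 0) { X = 0; clamped++; }
    if (Y < 0) { Y = 0; clamped++; }
    if (Z < 0) { Z = 0; clamped++; }
    t = (s + 1)*tau;
    if ((s + 1) % stride == 0 && isave < nsave) {
      out(isave, 0) = t; out(isave, 1) = X; out(isave, 2) = Y; out(isave, 3) = Z;
      isave++;
    }
  }
  out.attr("clamped") = clamped;
  out.attr("steps") = (double) nsteps;
  return out;
}
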