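// Discrete elastic-rod engine for a two-flagellin flagellar filament.
//
// State: beads r_0..r_N (bead 0 clamped at the origin = motor plane),
// one orthonormal material frame per segment stored as a unit quaternion,
// plus the spin angle of an anchored base frame ("tripod") whose rotation
// is restricted to the lab z axis (the motor axis).
//
// Elastic energy per junction j (between frame j-1 and frame j, with the
// base frame preceding segment 0):
//   E_j = (h/2) [ A ((O1-O01)^2 + (O2-O02)^2) + C (O3-O03)^2 ],
// where O = log(R_{j-1}^T R_j)/h is the rotational strain and O0 the rest
// strain of the segment's active polymorphic state.
// Each segment additionally carries a stretch/shear coupling tying the bond
// vector to the frame:  E_i = (K/2h)(xi3-h)^2 + (G/2h)(xi1^2+xi2^2),
// xi = R_i^T (r_{i+1}-r_i).  The K term is the harmonic spring keeping bond
// lengths within 0.1% of rest; the G term is the discretization's
// shear-alignment penalty (keeps e3 along the bond to ~1e-3 rad).
//
// Overdamped dynamics: translational drag is local anisotropic (resistive
// force theory) with per-segment coefficients; frames spin against the
// rotational coefficient gamma_r per length about e3 and a slaved pivot drag
// transversally.  Integration: embedded Cash-Karp RK4(5).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// ---------- small linear algebra / quaternion helpers (w,x,y,z) ----------

inline void qmul(const double* a, const double* b, double* out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

inline void qconjmul(const double* a, const double* b, double* out) {
  // conj(a) * b
  out[0] =  a[0]*b[0] + a[1]*b[1] + a[2]*b[2] + a[3]*b[3];
  out[1] =  a[0]*b[1] - a[1]*b[0] - a[2]*b[3] + a[3]*b[2];
  out[2] =  a[0]*b[2] + a[1]*b[3] - a[2]*b[0] - a[3]*b[1];
  out[3] =  a[0]*b[3] - a[1]*b[2] + a[2]*b[1] - a[3]*b[0];
}

inline void qrotmat(const double* q, double* R) {
  // column-major 3x3: R[col*3+row]; columns are e1, e2, e3
  const double w=q[0], x=q[1], y=q[2], z=q[3];
  R[0] = 1 - 2*(y*y + z*z); R[1] = 2*(x*y + w*z);     R[2] = 2*(x*z - w*y);
  R[3] = 2*(x*y - w*z);     R[4] = 1 - 2*(x*x + z*z); R[5] = 2*(y*z + w*x);
  R[6] = 2*(x*z + w*y);     R[7] = 2*(y*z - w*x);     R[8] = 1 - 2*(x*x + y*y);
}

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}

// 2*asin(s)/s as a function of u = s^2 (s = |vector part| of a unit
// quaternion, s = sin(theta/2)); accurate to ~1e-12 for s <= 0.5.
inline double two_asinc(double u) {
  if (u > 0.30) { // fall back for large bond angles (> ~66 deg)
    double s = std::sqrt(u);
    return 2.0 * std::asin(std::min(1.0, s)) / s;
  }
  // asin(s)/s = sum a_n u^n
  static const double a[15] = {
    1.0, 1.0/6.0, 3.0/40.0, 15.0/336.0, 105.0/3456.0,
    0.0223721590909091, 0.0173527644230769, 0.0139648437500000,
    0.0115518008961397, 0.00976160952919408, 0.00839033927440976,
    0.00731252587359885, 0.00644721031188964, 0.00574137911185666,
    0.00515154017414583 };
  double p = a[14];
  for (int k = 13; k >= 0; --k) p = p*u + a[k];
  return 2.0*p;
}

// c(theta) = 1/theta^2 - (1+cos theta)/(2 theta sin theta); series in
// t2 = theta^2 for small angles, stable half-angle closed form otherwise
inline double jac_c(double t2) {
  if (t2 > 1.2) {
    const double th = std::sqrt(t2);
    return 1.0/t2 - std::cos(0.5*th)/(2.0*th*std::sin(0.5*th));
  }
  return 1.0/12.0 + t2*(1.0/720.0 + t2*(1.0/30240.0 +
         t2*(1.0/1209600.0 + t2*(1.0/47900160.0 +
         t2*(1.0/1897473600.0 + t2*(1.0/74724249600.0))))));
}

// rotation-vector (log map) of unit quaternion q; returns phi[3]
inline void qlog(const double* q, double* phi) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  if (w < 0) { w = -w; x = -x; y = -y; z = -z; }
  double u = x*x + y*y + z*z;
  double f = two_asinc(u);
  phi[0] = f*x; phi[1] = f*y; phi[2] = f*z;
}

// unit quaternion from rotation vector
inline void qexp(const double* phi, double* q) {
  double th = std::sqrt(phi[0]*phi[0] + phi[1]*phi[1] + phi[2]*phi[2]);
  double c = std::cos(0.5*th);
  double s = (th < 1e-12) ? (0.5 - th*th/48.0) : std::sin(0.5*th)/th;
  q[0] = c; q[1] = s*phi[0]; q[2] = s*phi[1]; q[3] = s*phi[2];
}

inline void qnormalize(double* q) {
  double n = std::sqrt(q[0]*q[0]+q[1]*q[1]+q[2]*q[2]+q[3]*q[3]);
  q[0]/=n; q[1]/=n; q[2]/=n; q[3]/=n;
}

// solve symmetric positive-definite 3x3 G v = f (G given by 6 comps
// gxx,gyy,gzz,gxy,gxz,gyz)
inline void solve_sym3(const double* g, const double* f, double* v) {
  const double a=g[0], b=g[1], c=g[2], d=g[3], e=g[4], h=g[5];
  const double A11 =  b*c - h*h, A12 = e*h - d*c, A13 = d*h - e*b;
  const double A22 =  a*c - e*e, A23 = d*e - a*h;
  const double A33 =  a*b - d*d;
  const double det = a*A11 + d*A12 + e*A13;
  const double id = 1.0/det;
  v[0] = id*(A11*f[0] + A12*f[1] + A13*f[2]);
  v[1] = id*(A12*f[0] + A22*f[1] + A23*f[2]);
  v[2] = id*(A13*f[0] + A23*f[1] + A33*f[2]);
}

// ------------------------------- engine ----------------------------------

struct Model {
  int n;                 // number of segments
  double h;              // rest segment length (um)
  double A, C, K, G;     // elastic moduli (pN um^2, pN um^2, pN, pN)
  // base (hook) junction: swing-twist decomposition of conj(q_b) * q_0.
  // E = (C/2h)(tw - baseTwist0)^2 + (baseKb/2)(u_z - baseUz0)^2,
  // tw = 2 atan2(z, w) the twist about the segment axis, u_z = 1-2(x^2+y^2)
  // the cosine of the hook tilt.  Torsion is transmitted with full C while
  // bending compliance represents the flexible hook.
  double baseKb;         // tilt stiffness on cos(beta) (pN um)
  double baseTwist0;     // rest twist (rad)
  double baseUz0;        // rest cos(tilt)
  // soft steric barrier representing the cell pole: tilts beyond ~120 deg
  // are penalized, which also keeps the swing-twist decomposition away
  // from its 180-degree singularity
  double baseUzWall = -0.5;
  double baseKWall = 100.0;
  double M;              // motor torque (pN um)
  int motorLocal;        // 1: torque about the first segment's axis (the
                         // hook transmits rotation whatever the tilt);
                         // 0: torque about the fixed lab z axis
  std::vector<double> gPar, gPerp, gRot;   // per segment (pN s / um^2, gRot pN s)
  std::vector<double> rest;                // 3 * 2 * n rest strains
  std::vector<int> nStates;                // per segment
  std::vector<int> active;                 // per segment (0-based)
  double qb0[4];          // base frame at zero spin
  double gBaseSpin;       // spin drag of base frame (pN s um)
  double gFramePivot;     // factor: gPerp*h^3/6 per segment computed on the fly
};

struct Deriv {
  // workspaces sized for n
  std::vector<double> Rm;      // 9*n rotation matrices
  std::vector<double> qn;      // 4*n normalized quats
  std::vector<double> F;       // 3*(n+1) bead forces
  std::vector<double> Tq;      // 3*n frame torques (body)
  std::vector<double> Gm;      // 6*(n+1) mobility sym comps
  std::vector<double> bond;    // 3*n bond vectors
  std::vector<double> blen;    // n bond lengths
  double baseTorqueZ;          // world z elastic torque on base frame
  double baseTorqueW[3];       // full world elastic torque on base frame
  double axialForce;           // z force transmitted through segment 0 spring
  void resize(int n) {
    Rm.resize(9*n); qn.resize(4*n); F.assign(3*(n+1), 0.0);
    Tq.assign(3*n, 0.0); Gm.assign(6*(n+1), 0.0);
    bond.resize(3*n); blen.resize(n);
  }
};

// layout of state vector y: [pos 3*(n+1) | quat 4*n | baseAngle]
inline int ylen(int n) { return 3*(n+1) + 4*n + 1; }

void eval_deriv(const Model& m, const double* y, double* dy, Deriv& w) {
  const int n = m.n;
  const double* pos = y;
  const double* qs  = y + 3*(n+1);
  const double psi  = y[ylen(n)-1];

  // base frame quaternion: Rz(psi) * qb0
  double qz[4] = { std::cos(0.5*psi), 0.0, 0.0, std::sin(0.5*psi) };
  double qb[4];
  qmul(qz, m.qb0, qb);

  // normalized local quats + rotation matrices
  for (int i = 0; i < n; ++i) {
    double* q = &w.qn[4*i];
    q[0]=qs[4*i]; q[1]=qs[4*i+1]; q[2]=qs[4*i+2]; q[3]=qs[4*i+3];
    double n2 = q[0]*q[0]+q[1]*q[1]+q[2]*q[2]+q[3]*q[3];
    double inv = 1.5 - 0.5*n2;          // one Newton step of rsqrt near 1
    if (std::fabs(n2 - 1.0) > 1e-4) inv = 1.0/std::sqrt(n2);
    q[0]*=inv; q[1]*=inv; q[2]*=inv; q[3]*=inv;
    qrotmat(q, &w.Rm[9*i]);
  }

  std::fill(w.F.begin(), w.F.end(), 0.0);
  std::fill(w.Tq.begin(), w.Tq.end(), 0.0);
  std::fill(w.Gm.begin(), w.Gm.end(), 0.0);
  w.baseTorqueZ = 0.0;
  w.baseTorqueW[0] = w.baseTorqueW[1] = w.baseTorqueW[2] = 0.0;

  // ---- stretch/shear springs + translational drag assembly ----
  for (int i = 0; i < n; ++i) {
    const double* R = &w.Rm[9*i];
    double* d = &w.bond[3*i];
    d[0] = pos[3*(i+1)]   - pos[3*i];
    d[1] = pos[3*(i+1)+1] - pos[3*i+1];
    d[2] = pos[3*(i+1)+2] - pos[3*i+2];
    const double len2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    const double len  = std::sqrt(len2);
    w.blen[i] = len;
    // xi = R^T d
    double xi[3] = { R[0]*d[0]+R[1]*d[1]+R[2]*d[2],
                     R[3]*d[0]+R[4]*d[1]+R[5]*d[2],
                     R[6]*d[0]+R[7]*d[1]+R[8]*d[2] };
    double g[3] = { m.G*xi[0]/m.h, m.G*xi[1]/m.h, m.K*(xi[2]-m.h)/m.h };
    // world-frame spring force R g: + on bead i, - on bead i+1
    double fw[3] = { R[0]*g[0]+R[3]*g[1]+R[6]*g[2],
                     R[1]*g[0]+R[4]*g[1]+R[7]*g[2],
                     R[2]*g[0]+R[5]*g[1]+R[8]*g[2] };
    w.F[3*i]   += fw[0]; w.F[3*i+1]   += fw[1]; w.F[3*i+2]   += fw[2];
    w.F[3*(i+1)]   -= fw[0]; w.F[3*(i+1)+1] -= fw[1]; w.F[3*(i+1)+2] -= fw[2];
    if (i == 0) w.axialForce = -fw[2];
    // body torque on frame i: xi x g
    double tq[3]; cross3(xi, g, tq);
    w.Tq[3*i] += tq[0]; w.Tq[3*i+1] += tq[1]; w.Tq[3*i+2] += tq[2];

    // drag assembly: half segment to each adjacent bead
    const double ut[3] = { d[0]/len, d[1]/len, d[2]/len };
    const double wPerp = 0.5*m.h*m.gPerp[i];
    const double wDiff = 0.5*m.h*(m.gPar[i] - m.gPerp[i]);
    const double gxx = wPerp + wDiff*ut[0]*ut[0];
    const double gyy = wPerp + wDiff*ut[1]*ut[1];
    const double gzz = wPerp + wDiff*ut[2]*ut[2];
    const double gxy = wDiff*ut[0]*ut[1];
    const double gxz = wDiff*ut[0]*ut[2];
    const double gyz = wDiff*ut[1]*ut[2];
    for (int b = i; b <= i+1; ++b) {
      double* G6 = &w.Gm[6*b];
      G6[0]+=gxx; G6[1]+=gyy; G6[2]+=gzz; G6[3]+=gxy; G6[4]+=gxz; G6[5]+=gyz;
    }
  }

  // ---- interior junction bend/twist torques ----
  for (int j = 1; j < n; ++j) {
    double P[4];
    qconjmul(&w.qn[4*(j-1)], &w.qn[4*j], P);
    double wq=P[0], x=P[1], yq=P[2], z=P[3];
    if (wq < 0) { wq=-wq; x=-x; yq=-yq; z=-z; }
    const double u = x*x + yq*yq + z*z;
    const double f = two_asinc(u);
    const double phi[3] = { f*x, f*yq, f*z };
    const double* o = &m.rest[3*(2*j + m.active[j])];
    const double Mv[3] = { m.A*(phi[0]/m.h - o[0]),
                           m.A*(phi[1]/m.h - o[1]),
                           m.C*(phi[2]/m.h - o[2]) };
    const double t2 = f*f*u;
    const double c  = jac_c(t2);
    double pm[3], ppm[3];
    cross3(phi, Mv, pm);
    cross3(phi, pm, ppm);
    // torque on frame j (its body frame): -(M - 0.5 phi x M + c phi x phi x M)
    w.Tq[3*j]   -= Mv[0] - 0.5*pm[0] + c*ppm[0];
    w.Tq[3*j+1] -= Mv[1] - 0.5*pm[1] + c*ppm[1];
    w.Tq[3*j+2] -= Mv[2] - 0.5*pm[2] + c*ppm[2];
    // torque on previous frame (its body frame): +(M + 0.5 phi x M + c ...)
    w.Tq[3*(j-1)]   += Mv[0] + 0.5*pm[0] + c*ppm[0];
    w.Tq[3*(j-1)+1] += Mv[1] + 0.5*pm[1] + c*ppm[1];
    w.Tq[3*(j-1)+2] += Mv[2] + 0.5*pm[2] + c*ppm[2];
  }

  // ---- base (hook) junction: swing-twist coupling ----
  {
    double P[4];
    qconjmul(qb, &w.qn[0], P);
    if (P[0] < 0) { P[0]=-P[0]; P[1]=-P[1]; P[2]=-P[2]; P[3]=-P[3]; }
    const double wq=P[0], x=P[1], yq=P[2], z=P[3];
    const double wz2 = std::max(1e-10, wq*wq + z*z);
    const double tw = 2.0*std::atan2(z, wq);
    const double uz = 1.0 - 2.0*(x*x + yq*yq);
    const double gT = (m.C/m.h) * (tw - m.baseTwist0);   // dE/d(tw)
    double gB = m.baseKb * (uz - m.baseUz0);              // dE/d(uz)
    if (uz < m.baseUzWall) gB += m.baseKWall * (uz - m.baseUzWall);
    // gradients w.r.t. body rotation delta of segment frame 0
    const double dtw0[3] = { (z*x - wq*yq)/wz2, (wq*x + z*yq)/wz2, 1.0 };
    const double dm0[3]  = { x*wq + yq*z, -x*z + yq*wq, 0.0 };   // d(x^2+y^2)
    for (int k = 0; k < 3; ++k)
      w.Tq[k] -= gT*dtw0[k] + gB*(-2.0*dm0[k]);
    // gradients w.r.t. body rotation eps of the base frame
    const double dtwB[3] = { -(wq*yq + z*x)/wz2, (wq*x - z*yq)/wz2, -1.0 };
    const double dmB[3]  = { -x*wq + yq*z, -x*z - yq*wq, 0.0 };
    double tb[3];
    for (int k = 0; k < 3; ++k)
      tb[k] = -(gT*dtwB[k] + gB*(-2.0*dmB[k]));
    double Rb[9]; qrotmat(qb, Rb);
    for (int r = 0; r < 3; ++r)
      w.baseTorqueW[r] = Rb[r]*tb[0] + Rb[3+r]*tb[1] + Rb[6+r]*tb[2];
    w.baseTorqueZ += w.baseTorqueW[2];
  }

  // ---- translational velocities ----
  dy[0] = dy[1] = dy[2] = 0.0;            // bead 0 clamped
  for (int b = 1; b <= n; ++b)
    solve_sym3(&w.Gm[6*b], &w.F[3*b], &dy[3*b]);

  // motor drive about the proximal segment's axis must enter before the
  // frame-spin derivatives are formed
  if (m.motorLocal) w.Tq[2] += m.M;

  // ---- frame spins ----
  double* dq = dy + 3*(n+1);
  for (int i = 0; i < n; ++i) {
    const double gSpin  = m.gRot[i]*m.h;
    const double gPivot = m.gPerp[i]*m.h*m.h*m.h/6.0;
    const double om[4] = { 0.0,
                           w.Tq[3*i]/gPivot,
                           w.Tq[3*i+1]/gPivot,
                           w.Tq[3*i+2]/gSpin };
    double qd[4];
    qmul(&w.qn[4*i], om, qd);
    dq[4*i]   = 0.5*qd[0];
    dq[4*i+1] = 0.5*qd[1];
    dq[4*i+2] = 0.5*qd[2];
    dq[4*i+3] = 0.5*qd[3];
  }

  // ---- base spin ----
  // with the local (tripod) drive the base frame is a passive twist
  // anchor that follows the rotation; with the lab-axis drive the motor
  // torque acts on the base frame directly
  dy[ylen(n)-1] = (m.motorLocal ? w.baseTorqueZ : m.M + w.baseTorqueZ)
                  / m.gBaseSpin;
}

// elastic energy split: (bend/twist, stretch+shear) for current state vector
void eval_energy(const Model& m, const double* y, double* ebt, double* es,
                 Deriv& w) {
  const int n = m.n;
  const double* pos = y;
  const double* qs  = y + 3*(n+1);
  const double psi  = y[ylen(n)-1];
  double qz[4] = { std::cos(0.5*psi), 0.0, 0.0, std::sin(0.5*psi) };
  double qb[4]; qmul(qz, m.qb0, qb);
  for (int i = 0; i < n; ++i) {
    double* q = &w.qn[4*i];
    for (int k = 0; k < 4; ++k) q[k] = qs[4*i+k];
    qnormalize(q);
    qrotmat(q, &w.Rm[9*i]);
  }
  double Ebt = 0.0, Es = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* R = &w.Rm[9*i];
    const double d[3] = { pos[3*(i+1)]-pos[3*i], pos[3*(i+1)+1]-pos[3*i+1],
                          pos[3*(i+1)+2]-pos[3*i+2] };
    const double xi[3] = { R[0]*d[0]+R[1]*d[1]+R[2]*d[2],
                           R[3]*d[0]+R[4]*d[1]+R[5]*d[2],
                           R[6]*d[0]+R[7]*d[1]+R[8]*d[2] };
    Es += 0.5*m.K*(xi[2]-m.h)*(xi[2]-m.h)/m.h
        + 0.5*m.G*(xi[0]*xi[0]+xi[1]*xi[1])/m.h;
  }
  for (int j = 1; j < n; ++j) {
    double P[4]; qconjmul(&w.qn[4*(j-1)], &w.qn[4*j], P);
    double phi[3]; qlog(P, phi);
    const double* o = &m.rest[3*(2*j + m.active[j])];
    const double d1 = phi[0]/m.h - o[0];
    const double d2 = phi[1]/m.h - o[1];
    const double d3 = phi[2]/m.h - o[2];
    Ebt += 0.5*m.h*(m.A*(d1*d1 + d2*d2) + m.C*d3*d3);
  }
  {
    double P[4]; qconjmul(qb, &w.qn[0], P);
    if (P[0] < 0) { P[0]=-P[0]; P[1]=-P[1]; P[2]=-P[2]; P[3]=-P[3]; }
    const double tw = 2.0*std::atan2(P[3], P[0]);
    const double uz = 1.0 - 2.0*(P[1]*P[1] + P[2]*P[2]);
    Ebt += 0.5*(m.C/m.h)*(tw - m.baseTwist0)*(tw - m.baseTwist0)
         + 0.5*m.baseKb*(uz - m.baseUz0)*(uz - m.baseUz0);
    if (uz < m.baseUzWall)
      Ebt += 0.5*m.baseKWall*(uz - m.baseUzWall)*(uz - m.baseUzWall);
  }
  *ebt = Ebt; *es = Es;
}

// junction strain vectors for the current state (3 x n, column j = segment j)
void eval_strains(const Model& m, const double* y, double* out, Deriv& w) {
  const int n = m.n;
  const double* qs = y + 3*(n+1);
  const double psi = y[ylen(n)-1];
  double qz[4] = { std::cos(0.5*psi), 0.0, 0.0, std::sin(0.5*psi) };
  double qb[4]; qmul(qz, m.qb0, qb);
  for (int i = 0; i < n; ++i) {
    double* q = &w.qn[4*i];
    for (int k = 0; k < 4; ++k) q[k] = qs[4*i+k];
    qnormalize(q);
  }
  for (int j = 0; j < n; ++j) {
    const double* qprev = (j == 0) ? qb : &w.qn[4*(j-1)];
    double P[4]; qconjmul(qprev, &w.qn[4*j], P);
    double phi[3]; qlog(P, phi);
    out[3*j] = phi[0]/m.h; out[3*j+1] = phi[1]/m.h; out[3*j+2] = phi[2]/m.h;
  }
}

// polymorphic relabeling: per segment pick argmin local energy density,
// ties (within a tiny relative margin) keep the current index
int select_states(const Model& m, const double* strains, std::vector<int>& active) {
  int nSwitch = 0;
  for (int j = 1; j < m.n; ++j) {   // segment 0's junction is the hook
    if (m.nStates[j] < 2) { continue; }
    const double* Om = &strains[3*j];
    double best = 0.0, cur = 0.0;
    int bestK = active[j];
    for (int k = 0; k < m.nStates[j]; ++k) {
      const double* o = &m.rest[3*(2*j + k)];
      const double d1 = Om[0]-o[0], d2 = Om[1]-o[1], d3 = Om[2]-o[2];
      const double e = 0.5*(m.A*(d1*d1 + d2*d2) + m.C*d3*d3);
      if (k == active[j]) cur = e;
      if (k == bestK) best = e;
      if (e < best) { best = e; bestK = k; }
    }
    if (bestK != active[j] && best < cur - 1e-12*(cur + 1e-9)) {
      active[j] = bestK; ++nSwitch;
    }
  }
  return nSwitch;
}

Model model_from_list(const List& cfg) {
  Model m;
  m.n = as<int>(cfg["n"]);
  m.h = as<double>(cfg["h"]);
  m.A = as<double>(cfg["A"]);
  m.C = as<double>(cfg["C"]);
  m.K = as<double>(cfg["K"]);
  m.G = as<double>(cfg["G"]);
  m.baseKb = as<double>(cfg["baseKb"]);
  m.baseTwist0 = as<double>(cfg["baseTwist0"]);
  m.baseUz0 = as<double>(cfg["baseUz0"]);
  m.M = as<double>(cfg["M"]);
  m.motorLocal = cfg.containsElementNamed("motorLocal") ?
    as<int>(cfg["motorLocal"]) : 0;
  NumericVector gp = cfg["gammaPar"], gq = cfg["gammaPerp"], gr = cfg["gammaRot"];
  m.gPar.assign(gp.begin(), gp.end());
  m.gPerp.assign(gq.begin(), gq.end());
  m.gRot.assign(gr.begin(), gr.end());
  NumericVector rest = cfg["restStrains"];   // 3 x 2 x n
  m.rest.assign(rest.begin(), rest.end());
  IntegerVector ns = cfg["nStates"], ac = cfg["activeIndex"];
  m.nStates.assign(ns.begin(), ns.end());
  m.active.assign(ac.begin(), ac.end());
  NumericVector qb0 = cfg["baseQuat"];
  for (int k = 0; k < 4; ++k) m.qb0[k] = qb0[k];
  m.gBaseSpin = as<double>(cfg["gammaBaseSpin"]);
  return m;
}

void pack_state(const List& st, int n, std::vector<double>& y) {
  NumericMatrix pos = st["positions"];   // (n+1) x 3
  NumericMatrix qs  = st["quats"];       // n x 4
  const double baseAngle = as<double>(st["baseAngle"]);
  y.assign(ylen(n), 0.0);
  for (int b = 0; b <= n; ++b)
    for (int k = 0; k < 3; ++k) y[3*b+k] = pos(b, k);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 4; ++k) y[3*(n+1)+4*i+k] = qs(i, k);
  y[ylen(n)-1] = baseAngle;
}

} // namespace

// ------------------------------ exports ----------------------------------

// [[Rcpp::export(name = ".cpp_elastic_eval")]]
List cpp_elastic_eval(List cfg, List state) {
  Model m = model_from_list(cfg);
  // suppress drag/motor contributions; deriv gives elastic forces before mobility
  std::vector<double> y; pack_state(state, m.n, y);
  Deriv w; w.resize(m.n);
  std::vector<double> dy(ylen(m.n), 0.0);
  eval_deriv(m, y.data(), dy.data(), w);
  double ebt, es;
  eval_energy(m, y.data(), &ebt, &es, w);
  NumericMatrix F(m.n + 1, 3), Tq(m.n, 3);
  for (int b = 0; b <= m.n; ++b)
    for (int k = 0; k < 3; ++k) F(b, k) = w.F[3*b+k];
  for (int i = 0; i < m.n; ++i)
    for (int k = 0; k < 3; ++k) Tq(i, k) = w.Tq[3*i+k];
  std::vector<double> strains(3*m.n);
  eval_strains(m, y.data(), strains.data(), w);
  NumericMatrix S(3, m.n);
  std::copy(strains.begin(), strains.end(), S.begin());
  return List::create(_["forces"] = F, _["torques"] = Tq,
                      _["baseTorqueZ"] = w.baseTorqueZ,
                      _["baseTorque"] = NumericVector::create(
                        w.baseTorqueW[0], w.baseTorqueW[1], w.baseTorqueW[2]),
                      _["energyBendTwist"] = ebt, _["energyStretch"] = es,
                      _["strains"] = S, _["axialForce"] = w.axialForce);
}

// [[Rcpp::export(name = ".cpp_select_states")]]
IntegerVector cpp_select_states(List cfg, List state) {
  Model m = model_from_list(cfg);
  std::vector<double> y; pack_state(state, m.n, y);
  Deriv w; w.resize(m.n);
  std::vector<double> strains(3*m.n);
  eval_strains(m, y.data(), strains.data(), w);
  std::vector<int> act = m.active;
  select_states(m, strains.data(), act);
  return IntegerVector(act.begin(), act.end());
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List cfg, List state, List integ) {
  Model m = model_from_list(cfg);
  const int n = m.n;
  const int ny = ylen(n);

  const double T        = as<double>(integ["duration"]);
  const double rtol     = as<double>(integ["relTol"]);
  const double atol     = as<double>(integ["absTol"]);
  const double dtInit   = as<double>(integ["dtInit"]);
  const double minStep  = as<double>(integ["minStep"]);
  const double maxStep  = as<double>(integ["maxStep"]);
  const double snapDt   = as<double>(integ["snapshotInterval"]);
  const double forceDt  = as<double>(integ["forceInterval"]);
  const bool   poly     = as<bool>(integ["polymorphic"]);
  const bool   earlyExit= as<bool>(integ["earlyExit"]);
  const double exitZ    = as<double>(integ["exitZ"]);
  const double exitHold = as<double>(integ["exitHold"]);
  const double strainAbort = as<double>(integ["strainAbort"]);
  const double maxSteps = integ.containsElementNamed("maxSteps") ?
    as<double>(integ["maxSteps"]) : 5e7;

  std::vector<double> y; pack_state(state, n, y);
  Deriv w; w.resize(n);

  // Cash-Karp tableau
  static const double a21=1.0/5;
  static const double a31=3.0/40, a32=9.0/40;
  static const double a41=3.0/10, a42=-9.0/10, a43=6.0/5;
  static const double a51=-11.0/54, a52=5.0/2, a53=-70.0/27, a54=35.0/27;
  static const double a61=1631.0/55296, a62=175.0/512, a63=575.0/13824,
                      a64=44275.0/110592, a65=253.0/4096;
  static const double b1=37.0/378, b3=250.0/621, b4=125.0/594, b6=512.0/1771;
  static const double d1=b1-2825.0/27648, d3=b3-18575.0/48384,
                      d4=b4-13525.0/55296, d5=-277.0/14336, d6=b6-1.0/4;

  std::vector<double> k1(ny), k2(ny), k3(ny), k4(ny), k5(ny), k6(ny),
                      yt(ny), ynew(ny), strains(3*n);

  double t = 0.0, dt = dtInit;
  long nAccept = 0, nReject = 0, nSwitch = 0;
  double maxStrainSnap = 0.0;

  // outputs
  std::vector<double> snapT, snapPos, snapQ, snapAngle, snapSteps;
  std::vector<int> snapState;
  std::vector<double> fT, fV, fAngle;
  double nextSnap = 0.0, nextForce = 0.0;
  double belowSince = -1.0;     // for early exit
  int status = 0;               // 0 ok, 1 early-exit screw, 2 stiffness, 3 strain
  std::string message = "completed";

  auto record_snapshot = [&](double tc) {
    snapT.push_back(tc);
    snapSteps.push_back((double)(nAccept + nReject));
    for (int b = 0; b <= n; ++b)
      for (int k = 0; k < 3; ++k) snapPos.push_back(y[3*b+k]);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 4; ++k) snapQ.push_back(y[3*(n+1)+4*i+k]);
    for (int i = 0; i < n; ++i) snapState.push_back(m.active[i]);
    snapAngle.push_back(y[ny-1]);
    // bond-length invariant at recorded times
    double mx = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = y[3*(i+1)]-y[3*i], dyb = y[3*(i+1)+1]-y[3*i+1],
             dz = y[3*(i+1)+2]-y[3*i+2];
      double rel = std::fabs(std::sqrt(dx*dx+dyb*dyb+dz*dz) - m.h)/m.h;
      if (rel > mx) mx = rel;
    }
    if (mx > maxStrainSnap) maxStrainSnap = mx;
  };

  auto record_force = [&](double tc) {
    eval_deriv(m, y.data(), k1.data(), w);  // cheap relative to sampling rate
    fT.push_back(tc); fV.push_back(w.axialForce); fAngle.push_back(y[ny-1]);
  };

  record_snapshot(0.0); nextSnap = snapDt;
  record_force(0.0);    nextForce = forceDt;

  eval_deriv(m, y.data(), k1.data(), w);

  while (t < T) {
    if (dt > maxStep) dt = maxStep;
    if (t + dt > T) dt = T - t;

    for (int i = 0; i < ny; ++i) yt[i] = y[i] + dt*a21*k1[i];
    eval_deriv(m, yt.data(), k2.data(), w);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + dt*(a31*k1[i]+a32*k2[i]);
    eval_deriv(m, yt.data(), k3.data(), w);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + dt*(a41*k1[i]+a42*k2[i]+a43*k3[i]);
    eval_deriv(m, yt.data(), k4.data(), w);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + dt*(a51*k1[i]+a52*k2[i]+a53*k3[i]+a54*k4[i]);
    eval_deriv(m, yt.data(), k5.data(), w);
    for (int i = 0; i < ny; ++i) yt[i] = y[i] + dt*(a61*k1[i]+a62*k2[i]+a63*k3[i]+a64*k4[i]+a65*k5[i]);
    eval_deriv(m, yt.data(), k6.data(), w);

    double err2 = 0.0;
    for (int i = 0; i < ny; ++i) {
      ynew[i] = y[i] + dt*(b1*k1[i] + b3*k3[i] + b4*k4[i] + b6*k6[i]);
      const double e = dt*(d1*k1[i] + d3*k3[i] + d4*k4[i] + d5*k5[i] + d6*k6[i]);
      const double sc = atol + rtol*std::fabs(y[i]);
      const double r = e/sc;
      err2 += r*r;
    }
    const double errNorm = std::sqrt(err2/ny);

    if (errNorm <= 1.0) {
      t += dt;
      std::swap(y, ynew);
      ++nAccept;
      // renormalize quaternions (frame re-orthonormalization)
      for (int i = 0; i < n; ++i) qnormalize(&y[3*(n+1)+4*i]);
      // polymorphic relabeling after each accepted step
      if (poly) {
        eval_strains(m, y.data(), strains.data(), w);
        nSwitch += select_states(m, strains.data(), m.active);
      }
      if (t >= nextForce - 1e-15) { record_force(t); nextForce += forceDt; }
      if (t >= nextSnap - 1e-15) {
        record_snapshot(t); nextSnap += snapDt;
        if (maxStrainSnap > strainAbort) {
          status = 3;
          message = "bond-length variation exceeded limit";
          break;
        }
      }
      if (earlyExit) {
        const double ztip = y[3*n+2];
        if (ztip < exitZ) {
          if (belowSince < 0) belowSince = t;
          else if (t - belowSince > exitHold) {
            status = 1; message = "early exit: persistent screw"; break;
          }
        } else belowSince = -1.0;
      }
      eval_deriv(m, y.data(), k1.data(), w);
      // gentle growth: the dynamics are stability-limited, so aggressive
      // growth only buys rejected steps
      const double fac = std::min(1.3, std::max(0.2, 0.9*std::pow(errNorm + 1e-30, -0.2)));
      dt *= fac;
    } else {
      ++nReject;
      dt *= std::max(0.1, 0.9*std::pow(errNorm, -0.25));
      if (dt < minStep) {
        status = 2; message = "step size underflow (stiffness)"; break;
      }
    }
    if (nAccept + nReject > maxSteps) {
      status = 4; message = "step budget exhausted"; break;
    }
  }

  if (snapT.back() < t - 1e-15) record_snapshot(t);

  const int ns = (int)snapT.size();
  NumericVector times(snapT.begin(), snapT.end());
  NumericVector pos(snapPos.begin(), snapPos.end());
  pos.attr("dim") = IntegerVector::create(3, n+1, ns);
  NumericVector qsnap(snapQ.begin(), snapQ.end());
  qsnap.attr("dim") = IntegerVector::create(4, n, ns);
  IntegerVector st(snapState.begin(), snapState.end());
  st.attr("dim") = IntegerVector::create(n, ns);

  return List::create(
    _["times"] = times, _["positions"] = pos, _["quats"] = qsnap,
    _["stateIndex"] = st,
    _["baseAngle"] = NumericVector(snapAngle.begin(), snapAngle.end()),
    _["snapSteps"] = NumericVector(snapSteps.begin(), snapSteps.end()),
    _["forceTimes"] = NumericVector(fT.begin(), fT.end()),
    _["axialForce"] = NumericVector(fV.begin(), fV.end()),
    _["forceBaseAngle"] = NumericVector(fAngle.begin(), fAngle.end()),
    _["maxBondStrain"] = maxStrainSnap,
    _["nAccept"] = (double)nAccept, _["nReject"] = (double)nReject,
    _["nPolymorphicSwitches"] = (double)nSwitch,
    _["finalTime"] = t, _["status"] = status, _["message"] = message);
}
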