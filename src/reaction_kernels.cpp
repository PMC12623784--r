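// Node-local backward-Euler reaction updates, batched over mesh nodes.
// Hard-coded right-hand sides and Jacobians of the model families; the R
// implementations of the same networks are the reference (tests compare
// both). Cytosolic concentrations are frozen during the node-local solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;

// Dense Gaussian elimination with partial pivoting, column-major A (n x n),
// solves in place into b. One shared routine for every model family so
// that structurally identical subsystems produce bitwise identical
// results (the negative-feedback model with the feedback off must
// reproduce positive-feedback trajectories exactly).
static bool lu_solve_small(int n, double* A, double* b) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(A[k + k * n]);
    for (int i = k + 1; i < n; ++i) {
      const double v = std::fabs(A[i + k * n]);
      if (v > amax) { amax = v; piv = i; }
    }
    if (amax == 0.0) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k + j * n], A[piv + j * n]);
      std::swap(b[k], b[piv]);
    }
    const double d = A[k + k * n];
    for (int i = k + 1; i < n; ++i) {
      const double m = A[i + k * n] / d;
      if (m != 0.0) {
        for (int j = k + 1; j < n; ++j) A[i + j * n] -= m * A[k + j * n];
        b[i] -= m * b[k];
      }
      A[i + k * n] = 0.0;
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < n; ++j) s -= A[i + j * n] * b[j];
    b[i] = s / A[i + i * n];
  }
  return true;
}

// Newton iteration on F(c) = c - c0 - dt f(c) = 0 for one node.
// fj fills f and J given the local concentration vector.
template <int N, typename FJ>
static bool newton_node(double* c0, double dt, FJ fj, double tol, int maxit,
                        double* out) {
  double c[N], f[N], r[N], J[N * N], A[N * N];
  for (int i = 0; i < N; ++i) c[i] = c0[i];
  for (int it = 0; it < maxit; ++it) {
    fj(c, f, J);
    double rmax = 0.0;
    for (int i = 0; i < N; ++i) {
      r[i] = c[i] - c0[i] - dt * f[i];
      const double a = std::fabs(r[i]);
      if (a > rmax) rmax = a;
    }
    if (rmax < tol) {
      for (int i = 0; i < N; ++i) out[i] = c[i];
      return true;
    }
    for (int j = 0; j < N * N; ++j) A[j] = -dt * J[j];
    for (int i = 0; i < N; ++i) A[i + i * N] += 1.0;
    for (int i = 0; i < N; ++i) r[i] = -r[i];
    if (!lu_solve_small(N, A, r)) return false;
    bool finite = true;
    for (int i = 0; i < N; ++i) {
      c[i] += r[i];
      if (!std::isfinite(c[i])) finite = false;
    }
    if (!finite) return false;
  }
  return false;
}

struct PfParams {
  double k1a, k1b, k2a, k2b, k3, k4a, k4b, k5a, k5b, k7, I, Bc;
};

// order: T, D, B42, Bm
struct PfFJ {
  const PfParams& p;
  void operator()(const double* c, double* f, double* Jm) const {
    const double T = c[0], D = c[1], B42 = c[2], Bm = c[3];
    const double act = (p.k2a * Bm + p.k3 * B42) * D;
    f[0] = act - (p.k2b + p.k4a * Bm + p.k7 * p.Bc) * T + p.k4b * B42;
    f[1] = p.k2b * T - act - p.k5b * D + p.k5a * p.I;
    f[2] = (p.k4a * Bm + p.k7 * p.Bc) * T - p.k4b * B42;
    f[3] = p.k1a * p.Bc - p.k1b * Bm + p.k4b * B42 - p.k4a * Bm * T;
    mat J(Jm, 4, 4, false, true);
    J.zeros();
    J(0, 0) = -(p.k2b + p.k4a * Bm + p.k7 * p.Bc);
    J(0, 1) = p.k2a * Bm + p.k3 * B42;
    J(0, 2) = p.k3 * D + p.k4b;
    J(0, 3) = p.k2a * D - p.k4a * T;
    J(1, 0) = p.k2b;
    J(1, 1) = -(p.k2a * Bm + p.k3 * B42) - p.k5b;
    J(1, 2) = -p.k3 * D;
    J(1, 3) = -p.k2a * D;
    J(2, 0) = p.k4a * Bm + p.k7 * p.Bc;
    J(2, 2) = -p.k4b;
    J(2, 3) = p.k4a * T;
    J(3, 0) = -p.k4a * Bm;
    J(3, 2) = p.k4b;
    J(3, 3) = -p.k1b - p.k4a * T;
  }
};

// order: T, D, B42, Bm, B42s, Bms ; cyto I, Bc, Bcs
struct NfParams {
  double k1a, k1b, k2a, k2b, k3, k4a, k4b, k5a, k5b, k7, I, Bc, Bcs;
};

struct NfFJ {
  const NfParams& p;
  void operator()(const double* c, double* f, double* Jm) const {
    const double T = c[0], D = c[1], B42 = c[2], Bm = c[3], B42s = c[4],
                 Bms = c[5];
    const double act = (p.k2a * Bm + p.k3 * B42) * D;
    f[0] = act - (p.k2b + p.k4a * (Bm + Bms) + p.k7 * (p.Bc + p.Bcs)) * T +
           p.k4b * (B42 + B42s);
    f[1] = p.k2b * T - act - p.k5b * D + p.k5a * p.I;
    f[2] = (p.k4a * Bm + p.k7 * p.Bc) * T - p.k4b * B42;
    f[3] = p.k1a * p.Bc - p.k1b * Bm + p.k4b * B42 - p.k4a * Bm * T;
    f[4] = (p.k4a * Bms + p.k7 * p.Bcs) * T - p.k4b * B42s;
    f[5] = p.k1a * p.Bcs - p.k1b * Bms + p.k4b * B42s - p.k4a * Bms * T;
    mat J(Jm, 6, 6, false, true);
    J.zeros();
    J(0, 0) = -(p.k2b + p.k4a * (Bm + Bms) + p.k7 * (p.Bc + p.Bcs));
    J(0, 1) = p.k2a * Bm + p.k3 * B42;
    J(0, 2) = p.k3 * D + p.k4b;
    J(0, 3) = p.k2a * D - p.k4a * T;
    J(0, 4) = p.k4b;
    J(0, 5) = -p.k4a * T;
    J(1, 0) = p.k2b;
    J(1, 1) = -(p.k2a * Bm + p.k3 * B42) - p.k5b;
    J(1, 2) = -p.k3 * D;
    J(1, 3) = -p.k2a * D;
    J(2, 0) = p.k4a * Bm + p.k7 * p.Bc;
    J(2, 2) = -p.k4b;
    J(2, 3) = p.k4a * T;
    J(3, 0) = -p.k4a * Bm;
    J(3, 2) = p.k4b;
    J(3, 3) = -p.k1b - p.k4a * T;
    J(4, 0) = p.k4a * Bms + p.k7 * p.Bcs;
    J(4, 4) = -p.k4b;
    J(4, 5) = p.k4a * T;
    J(5, 0) = -p.k4a * Bms;
    J(5, 4) = p.k4b;
    J(5, 5) = -p.k1b - p.k4a * T;
  }
};

// order: T, D, B42, Bm, A, AS, S, P, X, G ; cyto I, Bc, Gc, Ac, Sc
struct SepParams {
  double k1a, k1b, k2a, k2b, k3, k4a, k4b, k5a, k5b, k7, k12a, k12b, k13,
      k15, k16, k17, k18, k19, k20, k21, k22, k23, k24, k25, I, Bc, Gc, Ac,
      Sc;
};

struct SepFJ {
  const SepParams& p;
  void operator()(const double* c, double* f, double* Jm) const {
    const double T = c[0], D = c[1], B42 = c[2], Bm = c[3], A = c[4],
                 AS = c[5], S = c[6], P = c[7], X = c[8], G = c[9];
    const double act = (p.k2a * Bm + p.k3 * B42) * D;
    const double poly = (2 * p.k16 * S - p.k17 * P) * S;
    f[0] = act - (p.k2b + p.k4a * Bm + p.k7 * p.Bc) * T - p.k13 * G * T +
           p.k4b * B42;
    f[1] = p.k2b * T + p.k13 * G * T - act - p.k5b * D + p.k5a * p.I;
    f[2] = (p.k4a * Bm + p.k7 * p.Bc) * T - p.k4b * B42;
    f[3] = p.k1a * p.Bc - p.k1b * Bm + p.k4b * B42 - p.k4a * Bm * T;
    f[4] = p.k15 * AS - p.k19 * A * S - p.k20 * A * p.Sc - p.k22 * A +
           p.k23 * p.Ac * B42;
    f[5] = p.k19 * A * S + p.k20 * A * p.Sc - p.k15 * AS;
    f[6] = p.k15 * AS - poly - p.k21 * S - p.k19 * A * S + p.k18 * P +
           p.k25 * p.Sc * X;
    f[7] = poly - p.k18 * P;
    f[8] = -p.k24 * X;
    f[9] = p.k12a * p.Gc * P - p.k12b * G;
    mat J(Jm, 10, 10, false, true);
    J.zeros();
    J(0, 0) = -(p.k2b + p.k4a * Bm + p.k7 * p.Bc) - p.k13 * G;
    J(0, 1) = p.k2a * Bm + p.k3 * B42;
    J(0, 2) = p.k3 * D + p.k4b;
    J(0, 3) = p.k2a * D - p.k4a * T;
    J(0, 9) = -p.k13 * T;
    J(1, 0) = p.k2b + p.k13 * G;
    J(1, 1) = -(p.k2a * Bm + p.k3 * B42) - p.k5b;
    J(1, 2) = -p.k3 * D;
    J(1, 3) = -p.k2a * D;
    J(1, 9) = p.k13 * T;
    J(2, 0) = p.k4a * Bm + p.k7 * p.Bc;
    J(2, 2) = -p.k4b;
    J(2, 3) = p.k4a * T;
    J(3, 0) = -p.k4a * Bm;
    J(3, 2) = p.k4b;
    J(3, 3) = -p.k1b - p.k4a * T;
    J(4, 2) = p.k23 * p.Ac;
    J(4, 4) = -p.k19 * S - p.k20 * p.Sc - p.k22;
    J(4, 5) = p.k15;
    J(4, 6) = -p.k19 * A;
    J(5, 4) = p.k19 * S + p.k20 * p.Sc;
    J(5, 5) = -p.k15;
    J(5, 6) = p.k19 * A;
    J(6, 4) = -p.k19 * S;
    J(6, 5) = p.k15;
    J(6, 6) = -4 * p.k16 * S + p.k17 * P - p.k21 - p.k19 * A;
    J(6, 7) = p.k17 * S + p.k18;
    J(6, 8) = p.k25 * p.Sc;
    J(7, 6) = 4 * p.k16 * S - p.k17 * P;
    J(7, 7) = -p.k17 * S - p.k18;
    J(8, 8) = -p.k24;
    J(9, 7) = p.k12a * p.Gc;
    J(9, 9) = -p.k12b;
  }
};

static double pget(const Rcpp::List& pl, const char* nm) {
  return Rcpp::as<double>(pl[nm]);
}

//' Batched node-local backward-Euler reaction update.
//'
//' @param F0 N x n matrix of membrane concentrations.
//' @param model_id 1 positive feedback, 2 negative feedback, 3 septin.
//' @param pl parameter list; cyto named concentrations appended.
//' @param cyto named cytosolic concentrations.
//' @param dt step size.
//' @param tol absolute Newton residual tolerance.
//' @param maxit maximum Newton iterations.
//' @return updated matrix, or R_NilValue on failure.
//' @keywords internal
// [[Rcpp::export(name = ".reaction_be_cpp")]]
SEXP reaction_be_cpp(const Rcpp::NumericMatrix& F0, int model_id,
                     const Rcpp::List& pl, const Rcpp::NumericVector& cyto,
                     double dt, double tol, int maxit) {
  const int N = F0.nrow(), n = F0.ncol();
  Rcpp::NumericMatrix out(N, n);
  std::vector<double> c0(n), cn(n);
  bool ok = true;
  if (model_id == 1) {
    PfParams p{pget(pl, "k1a"), pget(pl, "k1b"), pget(pl, "k2a"),
               pget(pl, "k2b"), pget(pl, "k3"),  pget(pl, "k4a"),
               pget(pl, "k4b"), pget(pl, "k5a"), pget(pl, "k5b"),
               pget(pl, "k7"),  cyto[0],         cyto[1]};
    PfFJ fj{p};
    for (int i = 0; i < N && ok; ++i) {
      for (int j = 0; j < n; ++j) c0[j] = F0(i, j);
      ok = newton_node<4>(c0.data(), dt, fj, tol, maxit, cn.data());
      for (int j = 0; j < n; ++j) out(i, j) = cn[j];
    }
  } else if (model_id == 2) {
    NfParams p{pget(pl, "k1a"), pget(pl, "k1b"), pget(pl, "k2a"),
               pget(pl, "k2b"), pget(pl, "k3"),  pget(pl, "k4a"),
               pget(pl, "k4b"), pget(pl, "k5a"), pget(pl, "k5b"),
               pget(pl, "k7"),  cyto[0],         cyto[1],        cyto[2]};
    NfFJ fj{p};
    for (int i = 0; i < N && ok; ++i) {
      for (int j = 0; j < n; ++j) c0[j] = F0(i, j);
      ok = newton_node<6>(c0.data(), dt, fj, tol, maxit, cn.data());
      for (int j = 0; j < n; ++j) out(i, j) = cn[j];
    }
  } else if (model_id == 3) {
    SepParams p{pget(pl, "k1a"),  pget(pl, "k1b"),  pget(pl, "k2a"),
                pget(pl, "k2b"),  pget(pl, "k3"),   pget(pl, "k4a"),
                pget(pl, "k4b"),  pget(pl, "k5a"),  pget(pl, "k5b"),
                pget(pl, "k7"),   pget(pl, "k12a"), pget(pl, "k12b"),
                pget(pl, "k13"),  pget(pl, "k15"),  pget(pl, "k16"),
                pget(pl, "k17"),  pget(pl, "k18"),  pget(pl, "k19"),
                pget(pl, "k20"),  pget(pl, "k21"),  pget(pl, "k22"),
                pget(pl, "k23"),  pget(pl, "k24"),  pget(pl, "k25"),
                cyto[0],          cyto[1],          cyto[2],
                cyto[3],          cyto[4]};
    SepFJ fj{p};
    for (int i = 0; i < N && ok; ++i) {
      for (int j = 0; j < n; ++j) c0[j] = F0(i, j);
      ok = newton_node<10>(c0.data(), dt, fj, tol, maxit, cn.data());
      for (int j = 0; j < n; ++j) out(i, j) = cn[j];
    }
  } else {
    Rcpp::stop("unknown model_id");
  }
  if (!ok) return R_NilValue;
  return out;
}
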