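#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout for a batch of R runs over N nodes with 3 variables each:
//   S[(node*3 + comp)*R + r]
// so the run index is contiguous and the edge loop vectorises across runs.

namespace {

void vector_field(int model, const double *pars, int N, int R,
                  const double *S, double *D) {
  if (model == 0) { // Lorenz: (alpha(y-x), gamma x - y - xz, xy - beta z)
    const double a = pars[0], g = pars[1], b = pars[2];
    for (int n = 0; n < N; ++n) {
      const double *x = S + (size_t)(n * 3 + 0) * R;
      const double *y = S + (size_t)(n * 3 + 1) * R;
      const double *z = S + (size_t)(n * 3 + 2) * R;
      double *dx = D + (size_t)(n * 3 + 0) * R;
      double *dy = D + (size_t)(n * 3 + 1) * R;
      double *dz = D + (size_t)(n * 3 + 2) * R;
      for (int r = 0; r < R; ++r) {
        dx[r] = a * (y[r] - x[r]);
        dy[r] = g * x[r] - y[r] - x[r] * z[r];
        dz[r] = x[r] * y[r] - b * z[r];
      }
    }
  } else if (model == 1) { // Rossler: (-y-z, x+ay, b+z(x-c))
    const double a = pars[0], b = pars[1], c = pars[2];
    for (int n = 0; n < N; ++n) {
      const double *x = S + (size_t)(n * 3 + 0) * R;
      const double *y = S + (size_t)(n * 3 + 1) * R;
      const double *z = S + (size_t)(n * 3 + 2) * R;
      double *dx = D + (size_t)(n * 3 + 0) * R;
      double *dy = D + (size_t)(n * 3 + 1) * R;
      double *dz = D + (size_t)(n * 3 + 2) * R;
      for (int r = 0; r < R; ++r) {
        dx[r] = -y[r] - z[r];
        dy[r] = x[r] + a * y[r];
        dz[r] = b + z[r] * (x[r] - c);
      }
    }
  } else { // linear decay test system: ds/dt = -s
    const size_t L = (size_t)N * 3 * R;
    for (size_t i = 0; i < L; ++i) D[i] = -S[i];
  }
}

// Diffusive coupling in difference form: node i gains
//   eps * w_ij * Gamma * (s_j - s_i)
// for every undirected edge {i,j}. Difference form vanishes exactly (in
// floating point) on the synchronization manifold s_i == s_j.
void add_coupling(int E, const int *ei, const int *ej, const double *ew,
                  double eps, const double *G, bool gid, int R,
                  const double *S, double *D) {
  if (eps == 0.0 || E == 0) return;
  if (gid) { // inner coupling Gamma = I fast path
    for (int e = 0; e < E; ++e) {
      const int i = ei[e], j = ej[e];
      const double w = eps * ew[e];
      for (int c = 0; c < 3; ++c) {
        const double *__restrict Si = S + (size_t)(i * 3 + c) * R;
        const double *__restrict Sj = S + (size_t)(j * 3 + c) * R;
        double *__restrict Di = D + (size_t)(i * 3 + c) * R;
        double *__restrict Dj = D + (size_t)(j * 3 + c) * R;
        for (int r = 0; r < R; ++r) {
          const double d = w * (Sj[r] - Si[r]);
          Di[r] += d;
          Dj[r] -= d;
        }
      }
    }
  } else {
    for (int e = 0; e < E; ++e) {
      const int i = ei[e], j = ej[e];
      const double w = eps * ew[e];
      for (int r = 0; r < R; ++r) {
        double dvec[3];
        for (int k = 0; k < 3; ++k)
          dvec[k] = S[(size_t)(j * 3 + k) * R + r] - S[(size_t)(i * 3 + k) * R + r];
        for (int c = 0; c < 3; ++c) {
          // column-major 3x3 Gamma
          const double g = G[c + 0] * dvec[0] + G[c + 3] * dvec[1] + G[c + 6] * dvec[2];
          D[(size_t)(i * 3 + c) * R + r] += w * g;
          D[(size_t)(j * 3 + c) * R + r] -= w * g;
        }
      }
    }
  }
}

struct Deriv {
  int model, N, R, E;
  const double *pars;
  const int *ei, *ej;
  const double *ew;
  double eps;
  const double *G;
  bool gid;
  void operator()(const double *S, double *D) const {
    vector_field(model, pars, N, R, S, D);
    add_coupling(E, ei, ej, ew, eps, G, gid, R, S, D);
  }
};

} // namespace

// Integrate a batch of R runs of the same coupled system.
// scheme: 0 = forward Euler, 1 = midpoint RK2, 2 = classical RK4.
// record_mode: 0 = record all nodes (requires R == 1),
//              1 = record only node r for run r (perturbative batches).
// Returns the recorded frames; frame 0 is the initial state.
// [[Rcpp::export]]
NumericVector cpp_integrate(int model, NumericVector pars,
                            IntegerVector edge_i, IntegerVector edge_j,
                            NumericVector edge_w, double epsilon,
                            NumericVector gamma_inner, bool gamma_identity,
                            NumericVector init, int N, int R,
                            double h, int steps, int scheme,
                            int record_every, int record_mode,
                            double divergence_bound) {
  if (N < 1 || R < 1) stop("N and R must be positive");
  if (record_mode == 0 && R != 1) stop("record_mode 0 requires a single run");
  if ((int)init.size() != N * 3 * R) stop("initial state has wrong length");
  const size_t L = (size_t)N * 3 * R;
  std::vector<double> S(init.begin(), init.end());
  std::vector<double> k1(L), k2(L), k3(L), k4(L), tmp(L);

  Deriv f{model, N, R, (int)edge_i.size(), REAL(pars),
          INTEGER(edge_i), INTEGER(edge_j), REAL(edge_w),
          epsilon, REAL(gamma_inner), gamma_identity};

  const int nrec = steps / record_every + 1;
  const int per_frame = (record_mode == 0) ? N * 3 : R * 3;
  NumericVector out((size_t)nrec * per_frame);
  double *O = REAL(out);

  auto record = [&](int frame) {
    double *dst = O + (size_t)frame * per_frame;
    if (record_mode == 0) {
      for (int n = 0; n < N; ++n)
        for (int c = 0; c < 3; ++c) dst[n * 3 + c] = S[(size_t)(n * 3 + c)];
    } else {
      for (int r = 0; r < R; ++r)
        for (int c = 0; c < 3; ++c) dst[r * 3 + c] = S[(size_t)(r * 3 + c) * R + r];
    }
  };
  record(0);

  int frame = 1;
  for (int s = 1; s <= steps; ++s) {
    f(S.data(), k1.data());
    if (scheme == 0) {
      for (size_t i = 0; i < L; ++i) S[i] += h * k1[i];
    } else if (scheme == 1) {
      for (size_t i = 0; i < L; ++i) tmp[i] = S[i] + 0.5 * h * k1[i];
      f(tmp.data(), k2.data());
      for (size_t i = 0; i < L; ++i) S[i] += h * k2[i];
    } else {
      for (size_t i = 0; i < L; ++i) tmp[i] = S[i] + 0.5 * h * k1[i];
      f(tmp.data(), k2.data());
      for (size_t i = 0; i < L; ++i) tmp[i] = S[i] + 0.5 * h * k2[i];
      f(tmp.data(), k3.data());
      for (size_t i = 0; i < L; ++i) tmp[i] = S[i] + h * k3[i];
      f(tmp.data(), k4.data());
      const double h6 = h / 6.0;
      for (size_t i = 0; i < L; ++i)
        S[i] += h6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
    }
    double mx = 0.0;
    bool bad = false;
    for (size_t i = 0; i < L; ++i) {
      const double a = std::fabs(S[i]);
      if (a > mx) mx = a;
      if (std::isnan(S[i])) { bad = true; break; }
    }
    if (bad || mx > divergence_bound)
      stop("trajectory diverged at step %d (|state| exceeded %g)", s,
           divergence_bound);
    if (s % record_every == 0) record(frame++);
  }
  out.attr("nrec") = nrec;
  return out;
}
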