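#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Passive compartment chain integrators.
//
// System: C_i dV_i/dt = g_leak_i (Em - V_i) + sum_j (V_j - V_i)/Rc_ij
//                       + g_syn(t) (Esyn - V_i)   [synaptic compartment only]
//
// scheme "local": classical per-compartment exponential Euler. Each
// compartment relaxes toward its instantaneous steady state
//   Vinf_i = (g_leak_i*Em + sum_j V_j/Rc_ij + g_syn*Esyn) / G_i
// with factor exp(-G_i*dt/C_i), neighbors held at start-of-step values.
// g_syn is evaluated at the step start.
//
// scheme "matrix": exponential Euler on the full coupled system. With
// conductances frozen at the step midpoint the system is linear and the
// step is propagated exactly through the eigendecomposition of the
// symmetrized matrix B = C^{-1/2} K C^{-1/2}. Only the freezing of the
// (slow, tau_syn-scale) synaptic conductance contributes error, so this
// scheme stays accurate when compartment time constants drop far below
// the step, where the decoupled update develops a systematic bias.

// Jacobi eigendecomposition of a small symmetric matrix (n <= 8 in
// practice; spine chains have n <= 3). A is overwritten; V gets the
// eigenvectors (columns), d the eigenvalues.
static void jacobi_eigen(std::vector<double>& A, int n,
                         std::vector<double>& V, std::vector<double>& d) {
  for (int i = 0; i < n * n; ++i) V[i] = 0.0;
  for (int i = 0; i < n; ++i) V[i * n + i] = 1.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < n; ++p)
      for (int q = p + 1; q < n; ++q) off += A[p * n + q] * A[p * n + q];
    if (off < 1e-30) break;
    for (int p = 0; p < n; ++p) {
      for (int q = p + 1; q < n; ++q) {
        double apq = A[p * n + q];
        if (std::fabs(apq) < 1e-300) continue;
        double theta = (A[q * n + q] - A[p * n + p]) / (2.0 * apq);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < n; ++k) {
          double akp = A[k * n + p], akq = A[k * n + q];
          A[k * n + p] = c * akp - s * akq;
          A[k * n + q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; ++k) {
          double apk = A[p * n + k], aqk = A[q * n + k];
          A[p * n + k] = c * apk - s * aqk;
          A[q * n + k] = s * apk + c * aqk;
        }
        for (int k = 0; k < n; ++k) {
          double vkp = V[k * n + p], vkq = V[k * n + q];
          V[k * n + p] = c * vkp - s * vkq;
          V[k * n + q] = s * vkp + c * vkq;
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) d[i] = A[i * n + i];
}

// solve K x = rhs for small symmetric negative-definite K (Gaussian
// elimination with partial pivoting; K copied)
static void solve_small(std::vector<double> K, std::vector<double> rhs,
                        std::vector<double>& x, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(K[r * n + col]) > std::fabs(K[piv * n + col])) piv = r;
    if (piv != col) {
      for (int c2 = 0; c2 < n; ++c2) std::swap(K[col * n + c2], K[piv * n + c2]);
      std::swap(rhs[col], rhs[piv]);
    }
    for (int r = col + 1; r < n; ++r) {
      double f = K[r * n + col] / K[col * n + col];
      for (int c2 = col; c2 < n; ++c2) K[r * n + c2] -= f * K[col * n + c2];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int c2 = r + 1; c2 < n; ++c2) s -= K[r * n + c2] * x[c2];
    x[r] = s / K[r * n + r];
  }
}

// [[Rcpp::export(name = ".exp_euler_run")]]
List exp_euler_run(NumericVector C, NumericVector g_leak,
                   double Em, double Esyn,
                   IntegerVector couple_i, IntegerVector couple_j,
                   NumericVector couple_R,
                   int syn_comp, NumericVector gsyn,
                   double dt_s, bool record, std::string scheme) {
  const int n = C.size();
  const int nc = couple_R.size();
  const int nsteps = gsyn.size();

  std::vector<double> V(n, Em), Vnew(n);
  NumericMatrix trace;
  if (record) {
    trace = NumericMatrix(nsteps + 1, n);
    for (int i = 0; i < n; ++i) trace(0, i) = Em;
  }
  double peak = Em;

  if (scheme == "local") {
    std::vector<double> Gstat(n), num_stat(n), decay(n);
    for (int i = 0; i < n; ++i) Gstat[i] = g_leak[i];
    for (int k = 0; k < nc; ++k) {
      double gc = 1.0 / couple_R[k];
      Gstat[couple_i[k]] += gc;
      Gstat[couple_j[k]] += gc;
    }
    for (int i = 0; i < n; ++i) {
      num_stat[i] = g_leak[i] * Em;
      decay[i] = std::exp(-Gstat[i] * dt_s / C[i]);
    }
    for (int s = 0; s < nsteps; ++s) {
      double gs = gsyn[s];
      for (int i = 0; i < n; ++i) {
        double num = num_stat[i], G = Gstat[i];
        if (i == syn_comp) { num += gs * Esyn; G += gs; }
        for (int k = 0; k < nc; ++k) {
          if (couple_i[k] == i) num += V[couple_j[k]] / couple_R[k];
          else if (couple_j[k] == i) num += V[couple_i[k]] / couple_R[k];
        }
        double Vinf = num / G;
        double dec = (i == syn_comp && gs != 0.0)
          ? std::exp(-G * dt_s / C[i]) : decay[i];
        Vnew[i] = Vinf + (V[i] - Vinf) * dec;
      }
      for (int i = 0; i < n; ++i) V[i] = Vnew[i];
      if (V[syn_comp] > peak) peak = V[syn_comp];
      if (record) for (int i = 0; i < n; ++i) trace(s + 1, i) = V[i];
    }
  } else {  // matrix scheme
    // K without the synaptic term; rebuilt with it each step
    std::vector<double> K0(n * n, 0.0);
    for (int i = 0; i < n; ++i) K0[i * n + i] = -g_leak[i];
    for (int k = 0; k < nc; ++k) {
      double gc = 1.0 / couple_R[k];
      int a = couple_i[k], b = couple_j[k];
      K0[a * n + a] -= gc; K0[b * n + b] -= gc;
      K0[a * n + b] += gc; K0[b * n + a] += gc;
    }
    std::vector<double> sC(n), isC(n);
    for (int i = 0; i < n; ++i) { sC[i] = std::sqrt(C[i]); isC[i] = 1.0 / sC[i]; }
    std::vector<double> K(n * n), B(n * n), Q(n * n), lam(n),
      b(n), vstar(n), y(n), z(n), expl(n);
    double gs_prev = -1.0;
    for (int s = 0; s < nsteps; ++s) {
      double gs = gsyn[s];
      if (gs != gs_prev) {
        for (int i = 0; i < n * n; ++i) K[i] = K0[i];
        K[syn_comp * n + syn_comp] -= gs;
        for (int i = 0; i < n; ++i) b[i] = g_leak[i] * Em;
        b[syn_comp] += gs * Esyn;
        for (int i = 0; i < n; ++i) b[i] = -b[i];
        solve_small(K, b, vstar, n);               // K vstar = -b
        for (int i = 0; i < n * n; ++i) B[i] = K[i];
        for (int r = 0; r < n; ++r)
          for (int c2 = 0; c2 < n; ++c2) B[r * n + c2] *= isC[r] * isC[c2];
        jacobi_eigen(B, n, Q, lam);
        for (int i = 0; i < n; ++i) expl[i] = std::exp(lam[i] * dt_s);
        gs_prev = gs;
      }
      // y = Q^T C^{1/2} (V - vstar); y *= exp(lam dt); V = vstar + C^{-1/2} Q y
      for (int i = 0; i < n; ++i) z[i] = sC[i] * (V[i] - vstar[i]);
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < n; ++k) acc += Q[k * n + i] * z[k];
        y[i] = acc * expl[i];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < n; ++k) acc += Q[i * n + k] * y[k];
        V[i] = vstar[i] + isC[i] * acc;
      }
      if (V[syn_comp] > peak) peak = V[syn_comp];
      if (record) for (int i = 0; i < n; ++i) trace(s + 1, i) = V[i];
    }
  }

  NumericVector vfinal(n);
  for (int i = 0; i < n; ++i) vfinal[i] = V[i];
  List out = List::create(_["peak_vm"] = peak, _["v_final"] = vfinal);
  if (record) out["trace"] = trace;
  return out;
}
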