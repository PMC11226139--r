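// Operator-split Bidomain / monodomain time integration on an assembled Q1
// finite-element problem.  Sparse matrices arrive as the slots of a symmetric
// Matrix::dgCMatrix (column-compressed == row-compressed for symmetric
// matrices).  Linear systems are solved by Jacobi-preconditioned conjugate
// gradients; the singular elliptic (extracellular) system is kept consistent
// by projecting onto the zero-mean gauge with mass-lumped weights.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

NumericVector cells_step_cpp(NumericMatrix states, NumericVector gate_params,
                             NumericVector rho, NumericVector iks_factor,
                             int cell_type, double tau, NumericVector istim);

struct Csr {
  const int *p;
  const int *i;
  const double *x;
  int n;
  bool empty;
};

static Csr csr_from(const S4 &mat) {
  Csr m;
  IntegerVector dim = mat.slot("Dim");
  m.n = dim[0];
  IntegerVector p = mat.slot("p");
  IntegerVector i = mat.slot("i");
  NumericVector x = mat.slot("x");
  m.p = INTEGER(p);
  m.i = INTEGER(i);
  m.x = REAL(x);
  m.empty = (x.size() == 0);
  return m;
}

static void spmv(const Csr &A, const double *v, double *y) {
  for (int c = 0; c < A.n; ++c) y[c] = 0.0;
  for (int c = 0; c < A.n; ++c) {
    double vc = v[c];
    for (int k = A.p[c]; k < A.p[c + 1]; ++k) y[A.i[k]] += A.x[k] * vc;
  }
}

static void diag_of(const Csr &A, std::vector<double> &d) {
  d.assign(A.n, 0.0);
  for (int c = 0; c < A.n; ++c)
    for (int k = A.p[c]; k < A.p[c + 1]; ++k)
      if (A.i[k] == c) d[c] = A.x[k];
}

// weighted zero-mean projection (gauge fixing for the extracellular system)
static void project_zero_mean(double *v, const std::vector<double> &w,
                              double wsum, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += w[i] * v[i];
  m /= wsum;
  for (int i = 0; i < n; ++i) v[i] -= m;
}

// Euclidean zero-mean projection (consistency: keeps the residual in the
// range of the singular symmetric operator, which is constants-orthogonal)
static void project_zero_sum(double *v, int n) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) m += v[i];
  m /= n;
  for (int i = 0; i < n; ++i) v[i] -= m;
}

// Jacobi-PCG; returns iterations used, -1 on failure to converge.
static const double PCG_ATOL = 1e-12; // absolute residual floor (mV scale)

static int pcg(const Csr &A, const std::vector<double> &dinv, double *x,
               const double *b, double rtol, int maxit,
               const std::vector<double> *proj_w, double proj_wsum,
               std::vector<double> &r, std::vector<double> &z,
               std::vector<double> &pd, std::vector<double> &Ap) {
  int n = A.n;
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm <= PCG_ATOL) {
    for (int i = 0; i < n; ++i) x[i] = 0.0;
    return 0;
  }
  spmv(A, x, Ap.data());
  for (int i = 0; i < n; ++i) r[i] = b[i] - Ap[i];
  if (proj_w) project_zero_sum(r.data(), n);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = dinv[i] * r[i];
    rz += r[i] * z[i];
  }
  pd = z;
  for (int it = 0; it < maxit; ++it) {
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
    if (std::sqrt(rnorm) <= std::max(rtol * bnorm, PCG_ATOL)) {
      if (proj_w) project_zero_mean(x, *proj_w, proj_wsum, n);
      return it;
    }
    spmv(A, pd.data(), Ap.data());
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += pd[i] * Ap[i];
    double alpha = rz / pAp;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * pd[i];
      r[i] -= alpha * Ap[i];
    }
    if (proj_w) project_zero_sum(r.data(), n);
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = dinv[i] * r[i];
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) pd[i] = z[i] + beta * pd[i];
  }
  return -1;
}

// [[Rcpp::export(name = ".pcg_cpp")]]
List pcg_cpp(S4 A, NumericVector b, NumericVector x0, double rtol, int maxit,
             bool zero_mean, NumericVector weights) {
  Csr Am = csr_from(A);
  int n = Am.n;
  std::vector<double> dinv(n);
  diag_of(Am, dinv);
  for (int i = 0; i < n; ++i) dinv[i] = dinv[i] != 0 ? 1.0 / dinv[i] : 1.0;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), z(n), pd(n), Ap(n);
  std::vector<double> w;
  double wsum = 0.0;
  const std::vector<double> *pw = nullptr;
  if (zero_mean) {
    w.assign(weights.begin(), weights.end());
    for (double v : w) wsum += v;
    pw = &w;
    project_zero_mean(x.data(), w, wsum, n);
  }
  int it = pcg(Am, dinv, x.data(), REAL(b), rtol, maxit, pw, wsum, r, z, pd, Ap);
  if (it < 0) {
    spmv(Am, x.data(), Ap.data());
    double res = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = REAL(b)[i] - Ap[i];
      res += d * d;
    }
    stop("conjugate gradients failed to converge (residual %g after %d iterations)",
         std::sqrt(res), maxit);
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it);
}

// Fused operator-splitting loop over a tissue mesh.
//   A_par = M/tau + Ktilde  (parabolic system matrix; Ktilde = K(D)/c_m)
//   M     = consistent mass matrix
//   Ki    = K(D_i)/c_m  (bidomain only; also the parabolic diffusion operator)
//   Kie   = K(D_i + D_e)/c_m (bidomain elliptic operator)
// stimuli: concatenated node-index sets (stim_ptr CSR layout, 0-based),
// each with onset, duration, amplitude (pA/pF equivalent).
// [[Rcpp::export(name = ".tissue_run_cpp")]]
List tissue_run_cpp(NumericMatrix states0, NumericVector gate_params,
                    NumericVector rho, NumericVector iks_factor,
                    IntegerVector cell_type_per_node, S4 A_par, S4 M_mat,
                    Nullable<S4> Ki_mat, Nullable<S4> Kie_mat, bool bidomain,
                    double tau, double t_end, IntegerVector stim_ptr,
                    IntegerVector stim_nodes, NumericVector stim_t0,
                    NumericVector stim_dur, NumericVector stim_amp,
                    IntegerVector probe_nodes, double record_dt,
                    NumericVector ue0, double rtol_par, double rtol_ell,
                    int maxit, double event_thresh, double event_slope,
                    double snap_dt) {
  int n = states0.ncol();
  NumericMatrix states = clone(states0);
  Csr Apar = csr_from(A_par), M = csr_from(M_mat);
  Csr Ki, Kie;
  if (bidomain) {
    if (Ki_mat.isNull() || Kie_mat.isNull())
      stop("bidomain mode requires Ki and Kie matrices");
    Ki = csr_from(S4(Ki_mat));
    Kie = csr_from(S4(Kie_mat));
  }
  std::vector<double> dinv_par(n), dinv_ell, mlump(n, 0.0);
  diag_of(Apar, dinv_par);
  for (int i = 0; i < n; ++i) dinv_par[i] = 1.0 / dinv_par[i];
  // mass-lumped weights for the zero-mean gauge
  for (int c = 0; c < n; ++c)
    for (int k = M.p[c]; k < M.p[c + 1]; ++k) mlump[M.i[k]] += M.x[k];
  double msum = 0.0;
  for (double v : mlump) msum += v;
  if (bidomain) {
    dinv_ell.resize(n);
    diag_of(Kie, dinv_ell);
    for (int i = 0; i < n; ++i)
      dinv_ell[i] = dinv_ell[i] != 0 ? 1.0 / dinv_ell[i] : 1.0;
  }

  int nstep = (int)std::round(t_end / tau);
  int every = std::max(1, (int)std::round(record_dt / tau));
  int nrec = nstep / every + 1;
  int np = probe_nodes.size();
  NumericMatrix traces(nrec, np);
  NumericVector tvec(nrec);
  int snap_every = snap_dt > 0 ? std::max(1, (int)std::round(snap_dt / tau)) : 0;
  int nsnap = snap_every > 0 ? nstep / snap_every + 1 : 0;
  NumericMatrix snaps(nsnap > 0 ? n : 0, nsnap);
  NumericVector snap_times(nsnap);

  std::vector<double> v(n), vnew(n), ue(n), istim(n), rhs(n), tmp(n), work(n);
  std::vector<double> r(n), z(n), pd(n), Ap(n);
  for (int i = 0; i < n; ++i) v[i] = states(0, i);
  if (ue0.size() == n)
    for (int i = 0; i < n; ++i) ue[i] = ue0[i];
  vnew = v;

  std::vector<char> above(n, 0);
  for (int i = 0; i < n; ++i)
    above[i] = states(0, i) > event_thresh;
  std::vector<double> ev_t;
  std::vector<int> ev_node;
  NumericVector istim_r(n);
  long par_iters = 0, ell_iters = 0;
  int isnap = 0, ir = 0;
  for (int q = 0; q < np; ++q) traces(0, q) = v[probe_nodes[q]];
  tvec[0] = 0.0;
  ir = 1;
  if (snap_every > 0) {
    for (int i = 0; i < n; ++i) snaps(i, 0) = v[i];
    snap_times[0] = 0.0;
    isnap = 1;
  }

  // group nodes by cell type so the per-node ODE stage can be called per type
  bool uniform_type = true;
  for (int i = 1; i < n; ++i)
    if (cell_type_per_node[i] != cell_type_per_node[0]) uniform_type = false;
  if (!uniform_type)
    stop("per-node cell types must be uniform (layers differ via iks_factor)");
  int cell_type = cell_type_per_node[0];

  for (int nstp = 0; nstp < nstep; ++nstp) {
    double t = nstp * tau;
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int k = 0; k < stim_t0.size(); ++k) {
      if (t >= stim_t0[k] && t < stim_t0[k] + stim_dur[k]) {
        for (int q = stim_ptr[k]; q < stim_ptr[k + 1]; ++q)
          istim[stim_nodes[q]] += stim_amp[k];
      }
    }
    for (int i = 0; i < n; ++i) istim_r[i] = istim[i];
    // ODE stage (V frozen)
    NumericVector iion =
        cells_step_cpp(states, gate_params, rho, iks_factor, cell_type, tau,
                       istim_r);
    // elliptic stage (bidomain): Kie ue = -Ki v^n
    if (bidomain) {
      spmv(Ki, v.data(), tmp.data());
      for (int i = 0; i < n; ++i) tmp[i] = -tmp[i];
      int it = pcg(Kie, dinv_ell, ue.data(), tmp.data(), rtol_ell, maxit,
                   &mlump, msum, r, z, pd, Ap);
      if (it < 0) stop("elliptic CG failed to converge at t = %f ms", t);
      ell_iters += it;
    }
    // parabolic stage: (M/tau + K) v^{n+1} = M (v/tau - iion + istim) [- Ki ue]
    for (int i = 0; i < n; ++i) work[i] = v[i] / tau - iion[i] + istim[i];
    spmv(M, work.data(), rhs.data());
    if (bidomain) {
      spmv(Ki, ue.data(), tmp.data());
      for (int i = 0; i < n; ++i) rhs[i] -= tmp[i];
    }
    int it = pcg(Apar, dinv_par, vnew.data(), rhs.data(), rtol_par, maxit,
                 nullptr, 0.0, r, z, pd, Ap);
    if (it < 0) stop("parabolic CG failed to converge at t = %f ms", t);
    par_iters += it;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(vnew[i]))
        stop("non-finite membrane potential at t = %f ms, node %d", t, i + 1);
      if (!above[i] && vnew[i] > event_thresh &&
          (vnew[i] - v[i]) / tau > event_slope) {
        above[i] = 1;
        ev_t.push_back(t + tau);
        ev_node.push_back(i + 1);
      } else if (above[i] && vnew[i] < event_thresh - 10.0) {
        above[i] = 0;
      }
      v[i] = vnew[i];
      states(0, i) = vnew[i];
    }
    if ((nstp + 1) % every == 0 && ir < nrec) {
      for (int q = 0; q < np; ++q) traces(ir, q) = v[probe_nodes[q]];
      tvec[ir] = (nstp + 1) * tau;
      ++ir;
    }
    if (snap_every > 0 && (nstp + 1) % snap_every == 0 && isnap < nsnap) {
      for (int i = 0; i < n; ++i) snaps(i, isnap) = v[i];
      snap_times[isnap] = (nstp + 1) * tau;
      ++isnap;
    }
  }
  return List::create(
      _["time"] = tvec, _["traces"] = traces, _["final_states"] = states,
      _["ue"] = NumericVector(ue.begin(), ue.end()),
      _["events"] = DataFrame::create(_["node"] = wrap(ev_node),
                                      _["time"] = wrap(ev_t)),
      _["snapshots"] = snaps, _["snapshot_times"] = snap_times,
      _["cg_iterations"] = NumericVector::create(
          _["parabolic"] = (double)par_iters, _["elliptic"] = (double)ell_iters));
}
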