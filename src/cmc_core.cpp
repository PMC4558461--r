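// Compiled core for the canonical-microcircuit (CMC) neural mass model:
// linearised spectral forward model (transfer functions, windowed cross-
// spectral densities and their gradients) and a fixed-step delay-ODE
// integrator. Parameter vectors use the package-wide layout:
//   [0:3]   T1..T4   synaptic rate constants (Hz)
//   [4:13]  g1..g10  intrinsic connection strengths (Hz)
//   [14]    gamma    sigmoid slope
//   [15]    d        conduction delay (ms)
//   [16]    c_dp     deep-pyramidal observation weight
//   [17:20] a1 a2 b1 b2  input / measurement-noise power laws
//   [21:28] d_spec1..8   spectral innovations of the input
// Populations: 1 spiny stellate (granular), 2 superficial pyramidal,
// 3 inhibitory interneurons, 4 deep pyramidal.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const int N_PAR = 29;
// wiring rows: {target, source, sign, g-index, delayed}; all 0-based
static const int WIRE[10][5] = {
  {0, 0, -1, 0, 0},  // g1  ss->ss (gain control)
  {0, 1, -1, 1, 1},  // g2  sp->ss
  {0, 2, -1, 2, 1},  // g3  ii->ss (inhibitory)
  {1, 0, +1, 7, 1},  // g8  ss->sp (excitatory)
  {1, 1, -1, 6, 0},  // g7  sp->sp
  {2, 0, +1, 4, 1},  // g5  ss->ii (excitatory)
  {2, 2, -1, 3, 0},  // g4  ii->ii (inhibitory)
  {2, 3, +1, 5, 1},  // g6  dp->ii (excitatory)
  {3, 2, -1, 8, 1},  // g9  ii->dp (inhibitory)
  {3, 3, -1, 9, 0}   // g10 dp->dp
};

static inline double sig_centred(double v, double gamma) {
  return 1.0 / (1.0 + std::exp(-gamma * v)) - 0.5;
}

// Jacobians of the 8-state system at the origin: instantaneous (J0) and
// delayed (Jd) parts. State order (v1..v4, i1..i4).
static void cmc_jacobians(const rowvec& th, mat& J0, mat& Jd) {
  J0.zeros(8, 8); Jd.zeros(8, 8);
  const double s1 = th(14) / 4.0;  // sigmoid slope at the origin
  for (int k = 0; k < 4; ++k) {
    J0(k, 4 + k) = 1.0;                    // vdot = i
    J0(4 + k, k) -= th(k) * th(k);         // -T^2 v
    J0(4 + k, 4 + k) = -2.0 * th(k);       // -2T i
  }
  for (int r = 0; r < 10; ++r) {
    const int tg = WIRE[r][0], src = WIRE[r][1], sgn = WIRE[r][2],
              gi = WIRE[r][3], del = WIRE[r][4];
    const double val = sgn * th(tg) * th(4 + gi) * s1;
    if (del) Jd(4 + tg, src) += val; else J0(4 + tg, src) += val;
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_cmc_jacobians(const arma::rowvec& theta) {
  mat J0, Jd;
  cmc_jacobians(theta, J0, Jd);
  return Rcpp::List::create(Rcpp::Named("J0") = J0, Rcpp::Named("Jd") = Jd);
}

// per-population depolarisation transfer functions H_pop(f) (4 x F complex)
static cx_mat transfer_pop(const rowvec& th, const vec& freq) {
  mat J0, Jd;
  cmc_jacobians(th, J0, Jd);
  const double d_s = th(15) / 1000.0;
  vec B = zeros<vec>(8); B(4) = th(0);  // input drives the granular currents
  cx_mat H(4, freq.n_elem);
  cx_mat I8 = cx_mat(eye(8, 8), zeros(8, 8));
  cx_mat J0c = cx_mat(J0, zeros(8, 8)), Jdc = cx_mat(Jd, zeros(8, 8));
  for (uword j = 0; j < freq.n_elem; ++j) {
    const double w = 2.0 * datum::pi * freq(j);
    cx_double ed = std::exp(cx_double(0.0, -w * d_s));
    cx_mat A = cx_double(0.0, w) * I8 - J0c - Jdc * ed;
    cx_vec h;
    bool ok = solve(h, A, cx_vec(B, zeros<vec>(8)), solve_opts::no_approx);
    if (!ok) Rcpp::stop("resolvent not invertible at frequency %f Hz", freq(j));
    H.col(j) = h.subvec(0, 3);
  }
  return H;
}

static double max_re_eig(const rowvec& th) {
  mat J0, Jd;
  cmc_jacobians(th, J0, Jd);
  cx_vec ev = eig_gen(J0 + Jd);
  return max(real(ev));
}

// [[Rcpp::export]]
Rcpp::List cpp_transfer(const arma::rowvec& theta, const arma::vec& freq) {
  cx_mat H = transfer_pop(theta, freq);
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("max_re") = max_re_eig(theta));
}

// endogenous input spectral density on the grid; psi is F x 8 (cosine set)
static vec input_spectrum(const rowvec& th, const vec& freq, const mat& psi) {
  vec shape = psi * th.subvec(21, 28).t();
  return th(17) * exp(-th(18) * log(freq) + shape);
}

static vec observed_spectrum(const cx_mat& H, const rowvec& th, const vec& freq,
                             const mat& psi, double obs_gain) {
  cx_vec Hobs = H.row(1).t() + th(16) * H.row(3).t();
  vec gu = input_spectrum(th, freq, psi);
  return obs_gain * obs_gain * square(abs(Hobs)) % gu +
         th(19) * exp(-th(20) * log(freq));
}

// windowed predicted spectra; Theta is W x 29
// [[Rcpp::export]]
Rcpp::List cpp_csd(const arma::mat& Theta, const arma::vec& freq,
                   const arma::mat& psi, double obs_gain, double penalty_log) {
  const uword W = Theta.n_rows, F = freq.n_elem;
  mat S(W, F);
  vec maxre(W);
  for (uword w = 0; w < W; ++w) {
    rowvec th = Theta.row(w);
    maxre(w) = max_re_eig(th);
    if (maxre(w) >= 0) { S.row(w).fill(std::exp(penalty_log)); continue; }
    cx_mat H = transfer_pop(th, freq);
    S.row(w) = observed_spectrum(H, th, freq, psi, obs_gain).t();
  }
  return Rcpp::List::create(Rcpp::Named("S") = S, Rcpp::Named("max_re") = maxre);
}

// windowed spectra plus d log S / d lambda_p by central finite differences on
// the log-scalings (theta_p -> theta_p * exp(+-step)); dynamics parameters
// (indices 0..15) need a fresh resolvent sweep, the observation/input/noise
// parameters (16..28) reuse the stored pyramidal transfers.
// [[Rcpp::export]]
Rcpp::List cpp_csd_grad(const arma::mat& Theta, const arma::vec& freq,
                        const arma::mat& psi, double obs_gain,
                        double penalty_log, double step) {
  const uword W = Theta.n_rows, F = freq.n_elem;
  mat S(W, F);
  cube G(F, N_PAR, W, fill::zeros);
  vec maxre(W);
  const double up = std::exp(step), dn = std::exp(-step);
  for (uword w = 0; w < W; ++w) {
    rowvec th = Theta.row(w);
    maxre(w) = max_re_eig(th);
    if (maxre(w) >= 0) { S.row(w).fill(std::exp(penalty_log)); continue; }
    cx_mat H = transfer_pop(th, freq);
    vec S0 = observed_spectrum(H, th, freq, psi, obs_gain);
    S.row(w) = S0.t();
    for (int p = 0; p < N_PAR; ++p) {
      vec Sp, Sm;
      if (p <= 15) {
        rowvec thp = th; thp(p) *= up;
        rowvec thm = th; thm(p) *= dn;
        Sp = observed_spectrum(transfer_pop(thp, freq), thp, freq, psi, obs_gain);
        Sm = observed_spectrum(transfer_pop(thm, freq), thm, freq, psi, obs_gain);
      } else {
        rowvec thp = th; thp(p) *= up;
        rowvec thm = th; thm(p) *= dn;
        Sp = observed_spectrum(H, thp, freq, psi, obs_gain);
        Sm = observed_spectrum(H, thm, freq, psi, obs_gain);
      }
      G.slice(w).col(p) = (log(Sp) - log(Sm)) / (2.0 * step);
    }
  }
  return Rcpp::List::create(Rcpp::Named("S") = S, Rcpp::Named("G") = G,
                            Rcpp::Named("max_re") = maxre);
}

// nonlinear (or linearised) delay-ODE integration, fixed-step RK4 with a
// linearly interpolated delay buffer. Theta rows give per-window parameters;
// within the first ramp_samps of each window (after the first) parameters are
// blended linearly from the previous window. u is the exogenous input at the
// integration rate. Returns the four mean depolarisations per sample.
// [[Rcpp::export]]
arma::mat cpp_simulate(const arma::mat& Theta, const arma::vec& u, double fs,
                       int window_samps, int ramp_samps, bool linear) {
  const uword n = u.n_elem;
  const uword W = Theta.n_rows;
  const double dt = 1.0 / fs;
  mat V(n, 4, fill::zeros);
  vec x = zeros<vec>(8);  // v1..v4, i1..i4

  auto theta_at = [&](uword j) -> rowvec {
    uword w = std::min<uword>(j / window_samps, W - 1);
    if (w == 0 || ramp_samps <= 0) return Theta.row(w);
    uword off = j - w * (uword)window_samps;
    if (off >= (uword)ramp_samps) return Theta.row(w);
    double al = (double)(off + 1) / (double)ramp_samps;
    return (1.0 - al) * Theta.row(w - 1) + al * Theta.row(w);
  };

  // delayed depolarisation: quadratic (3-point Lagrange) interpolation on
  // the stored solution, clamped at the current working state for sub-step
  // look-back; falls back to linear at the buffer edges
  // V.row(j) (the state at the current step's start) is already stored, so
  // only strictly-future samples fall back to the working stage state
  auto v_at = [&](long k, const vec& xcur, uword j) -> vec {
    if (k < 0) return zeros<vec>(4);
    if ((uword)k > j) return vec(xcur.subvec(0, 3));
    return vec(V.row((uword)k).t());
  };
  auto v_delayed = [&](double pos, const vec& xcur, uword j) -> vec {
    if (pos <= 0.0) return zeros<vec>(4);
    long lo = (long)std::floor(pos);
    double t = pos - lo;  // in [0, 1)
    vec vm1 = v_at(lo - 1, xcur, j), v0 = v_at(lo, xcur, j),
        v1 = v_at(lo + 1, xcur, j);
    if (lo < 1) return (1.0 - t) * v0 + t * v1;
    // quadratic through (-1, 0, +1)
    return 0.5 * t * (t - 1.0) * vm1 + (1.0 - t * t) * v0 +
           0.5 * t * (t + 1.0) * v1;
  };

  auto u_at = [&](double pos) -> double {
    if (pos <= 0.0) return u(0);
    if (pos >= (double)(n - 1)) return u(n - 1);
    uword lo = (uword)std::floor(pos);
    double fr = pos - lo;
    return (1.0 - fr) * u(lo) + fr * u(lo + 1);
  };

  auto deriv = [&](const vec& xs, const vec& vdel, double uin,
                   const rowvec& th) -> vec {
    vec dx(8);
    const double gamma = th(14);
    vec fr_inst(4), fr_del(4);
    for (int k = 0; k < 4; ++k) {
      if (linear) {
        fr_inst(k) = gamma / 4.0 * xs(k);
        fr_del(k)  = gamma / 4.0 * vdel(k);
      } else {
        fr_inst(k) = sig_centred(xs(k), gamma);
        fr_del(k)  = sig_centred(vdel(k), gamma);
      }
    }
    vec drive = zeros<vec>(4);
    for (int r = 0; r < 10; ++r) {
      const int tg = WIRE[r][0], src = WIRE[r][1], sgn = WIRE[r][2],
                gi = WIRE[r][3], del = WIRE[r][4];
      drive(tg) += sgn * th(4 + gi) * (del ? fr_del(src) : fr_inst(src));
    }
    drive(0) += uin;
    for (int k = 0; k < 4; ++k) {
      dx(k) = xs(4 + k);
      dx(4 + k) = th(k) * drive(k) - 2.0 * th(k) * xs(4 + k) -
                  th(k) * th(k) * xs(k);
    }
    return dx;
  };

  const double cs[4] = {0.0, 0.5, 0.5, 1.0};
  for (uword j = 0; j < n; ++j) {
    V.row(j) = x.subvec(0, 3).t();
    if (j == n - 1) break;
    rowvec th = theta_at(j);
    const double dlag = th(15) / 1000.0 * fs;  // delay in samples
    vec k1, k2, k3, k4;
    vec stage = x;
    k1 = deriv(stage, v_delayed((double)j - dlag, stage, j), u_at((double)j), th);
    stage = x + 0.5 * dt * k1;
    k2 = deriv(stage, v_delayed((double)j + cs[1] - dlag, stage, j),
               u_at((double)j + cs[1]), th);
    stage = x + 0.5 * dt * k2;
    k3 = deriv(stage, v_delayed((double)j + cs[2] - dlag, stage, j),
               u_at((double)j + cs[2]), th);
    stage = x + dt * k3;
    k4 = deriv(stage, v_delayed((double)j + cs[3] - dlag, stage, j),
               u_at((double)j + cs[3]), th);
    x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!x.is_finite() || std::abs(x(0)) > 1e6 || std::abs(x(1)) > 1e6 ||
        std::abs(x(2)) > 1e6 || std::abs(x(3)) > 1e6)
      Rcpp::stop("numerical blow-up at t = %.3f s (window %d); check parameters",
                 j * dt, (int)(j / window_samps) + 1);
  }
  return V;
}
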