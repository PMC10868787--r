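// Numerical cores: network integration, backpropagation through time,
// and fixed-step flows on the (kappa, theta) torus with optional
// variational (monodromy) integration.
//
// Time is in milliseconds throughout; omega in rad/ms.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-channel instantaneous input value.
// kind 0 ("osc"):   u(theta) = amp * sin(theta + phase)
// kind 1 ("tonic"): u = amp
static inline double chan_u(int kind, double amp, double phase, double theta) {
  return kind == 0 ? amp * std::sin(theta + phase) : amp;
}

// Same channel after leaky filtering with time constant tau:
// v(theta) = amp/sqrt((omega*tau)^2+1) * sin(theta + phase - atan(omega*tau))
// for oscillatory channels (steady-state solution), amp for tonic ones.
static inline double chan_v(int kind, double amp, double phase, double theta,
                            double fgain, double flag_) {
  return kind == 0 ? amp * fgain * std::sin(theta + phase - flag_) : amp;
}

// ---------------------------------------------------------------------------
// Full network simulation (Euler-Maruyama), single trial.
// inputs: C x T matrix of input time courses (reference + stimuli).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_rnn_sim(const arma::mat& m, const arma::mat& n,
                       const arma::mat& J, bool fullrank,
                       const arma::mat& I_in, const arma::vec& w,
                       double readout_scale, int readout_mode,
                       const arma::mat& inputs, const arma::vec& x0,
                       double h, double tau, double sigma_noise,
                       int seed, bool return_x) {
  const uword N = I_in.n_rows, T = inputs.n_cols;
  const double a = h / tau;
  const double sn = std::sqrt(h / tau) * std::sqrt(2.0) * sigma_noise;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  mat X;
  if (return_x) X.set_size(N, T);
  vec x = x0, r(T);
  for (uword k = 0; k < T; ++k) {
    if (return_x) X.col(k) = x;
    const vec act = (readout_mode == 1) ? vec(tanh(x)) : x;
    r(k) = (readout_scale / double(N)) * dot(w, act);
    if (k + 1 == T) break;
    const vec phi = tanh(x);
    vec drive = fullrank ? vec(J * phi) : vec(m * (n.t() * phi) / double(N));
    drive += I_in * inputs.col(k);
    vec xn = (1.0 - a) * x + a * drive;
    if (sn > 0) {
      for (uword i = 0; i < N; ++i) xn(i) += sn * gauss(rng);
    }
    x = xn;
    if (!xn.is_finite())
      Rcpp::stop("non-finite network state at step %d", (int)(k + 1));
  }
  return Rcpp::List::create(Rcpp::Named("x") = X, Rcpp::Named("r") = r,
                            Rcpp::Named("x_final") = x);
}

// ---------------------------------------------------------------------------
// Batched forward pass + backpropagation through time.
//
// State update (Euler-Maruyama):
//   x_{k+1} = (1-a) x_k + a (J tanh x_k + I u_k) + sqrt(h/tau) N(0, 2 sigma^2)
// Readout r_k = (c/N) w' x_k  (or w' tanh x_k), loss = mean over masked
// samples of (r - target)^2; rate regularizer = per-trial
// (1/N) sum_i (masked-time-mean of x_i)^2, averaged over the batch.
//
// inputs cube: C x B x T; target/mask: T x B.
// Returns loss components and gradients w.r.t. m, n (or J), I, readout scale.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_rnn_bptt(const arma::mat& m, const arma::mat& n,
                        const arma::mat& J, bool fullrank,
                        const arma::mat& I_in, const arma::vec& w,
                        double readout_scale, int readout_mode,
                        const arma::cube& inputs, const arma::mat& target,
                        const arma::mat& mask, double h, double tau,
                        double reg_coef, double sigma_noise, int seed,
                        bool compute_grads) {
  const uword N = I_in.n_rows, C = I_in.n_cols;
  const uword B = inputs.n_cols, T = inputs.n_slices;
  const uword R = fullrank ? 0 : m.n_cols;
  const double a = h / tau;
  const double sn = std::sqrt(h / tau) * std::sqrt(2.0) * sigma_noise;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);

  cube X(N, B, T, fill::zeros);  // states; x_0 = 0
  // forward (slices are used by reference; phi reused as scratch)
  mat phi(N, B);
  for (uword k = 0; k + 1 < T; ++k) {
    phi = tanh(X.slice(k));
    mat& xn = X.slice(k + 1);
    if (fullrank)
      xn = J * phi;
    else
      xn = m * (n.t() * phi) / double(N);
    xn += I_in * inputs.slice(k);  // (N x C) * (C x B)
    xn *= a;
    xn += (1.0 - a) * X.slice(k);
    if (sn > 0) xn.for_each([&](double& e) { e += sn * gauss(rng); });
    if (!xn.is_finite())
      Rcpp::stop("non-finite network state at step %d", (int)(k + 1));
  }

  // readout (rbase = readout before scaling so d/dscale is cheap)
  mat rbase(T, B);
  if (readout_mode == 1) {
    for (uword k = 0; k < T; ++k)
      rbase.row(k) = (w.t() * tanh(X.slice(k))) / double(N);
  } else {
    // one GEMV over the whole cube (slices are contiguous)
    const mat Xflat(const_cast<double*>(X.memptr()), N, B * T, false, true);
    rbase = trans(reshape(w.t() * Xflat / double(N), B, T));
  }
  const mat r = readout_scale * rbase;

  const double M_tot = accu(mask);
  if (M_tot <= 0) Rcpp::stop("empty loss mask");
  const mat err = mask % (r - target);
  const double loss = accu(err % err) / M_tot;

  // rate regularizer
  rowvec Mb = sum(mask, 0);  // masked samples per trial
  mat xbar(N, B, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    const mat xk = X.slice(k);
    for (uword b = 0; b < B; ++b)
      if (mask(k, b) > 0) xbar.col(b) += xk.col(b);
  }
  for (uword b = 0; b < B; ++b) xbar.col(b) /= std::max(Mb(b), 1.0);
  double reg = 0.0;
  for (uword b = 0; b < B; ++b) reg += dot(xbar.col(b), xbar.col(b)) / double(N);
  reg /= double(B);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("reg") = reg,
      Rcpp::Named("objective") = loss + reg_coef * reg,
      Rcpp::Named("r") = r);
  if (!compute_grads) return out;

  // backward
  const mat e = 2.0 * (mask % (r - target)) / M_tot;  // dL/dr
  mat gI(N, C, fill::zeros), gm, gn, gJ;
  if (fullrank) gJ.zeros(N, N); else { gm.zeros(N, R); gn.zeros(N, R); }
  double gscale = accu(e % rbase);

  // per-trial regularizer coefficient on x (applied on masked steps)
  vec regc(B);
  for (uword b = 0; b < B; ++b)
    regc(b) = 2.0 * reg_coef / (double(B) * double(N) * std::max(Mb(b), 1.0));

  mat dbuf(N, B);
  auto direct_grad = [&](uword k, mat& d) {
    if (readout_mode == 1) {
      d = (readout_scale / double(N)) * (w * e.row(k));
      d %= 1.0 - square(tanh(X.slice(k)));
    } else {
      d = (readout_scale / double(N)) * (w * e.row(k));
    }
    for (uword b = 0; b < B; ++b)
      if (mask(k, b) > 0) d.col(b) += regc(b) * xbar.col(b);
  };

  mat lam(N, B), back(N, B);
  direct_grad(T - 1, lam);  // lambda_{T-1}
  for (uword kk = T - 1; kk-- > 0;) {
    const uword k = kk;  // step whose state feeds lambda_{k+1}
    phi = tanh(X.slice(k));
    // parameter gradients using lambda_{k+1} (= lam)
    gI += a * (lam * inputs.slice(k).t());
    if (fullrank) {
      gJ += a * (lam * phi.t());
    } else {
      gm += (a / double(N)) * (lam * (n.t() * phi).t());
      gn += (a / double(N)) * (phi * (m.t() * lam).t());
    }
    // recurrence
    if (fullrank) back = J.t() * lam; else back = n * (m.t() * lam) / double(N);
    back %= 1.0 - square(phi);
    direct_grad(k, dbuf);
    lam *= (1.0 - a);
    lam += dbuf + a * back;
  }

  out["gI"] = gI;
  out["gscale"] = gscale;
  if (fullrank) out["gJ"] = gJ; else { out["gm"] = gm; out["gn"] = gn; }
  return out;
}

// ---------------------------------------------------------------------------
// Flow of the reduced network dynamics on (kappa1, kappa2) with theta = omega t.
//
//   tau dk_i/dt = -k_i + (1/N) n_i' tanh(x) + sum_c alpha_{i,c} u_c(theta)
//   x = m kappa + sum_c Iperp_c v_c(theta)
//
// Batched over K initial conditions (columns of kappa0). Optionally
// integrates the variational equation dM/dt = Dk(RHS) M alongside.
// ---------------------------------------------------------------------------
struct KField {
  const mat& m; const mat& n; const mat& Iperp; const mat& alpha;
  const ivec& kind; const vec& amp; const vec& phase;
  double omega, tau, fgain, flag_;
  uword N, C;
  KField(const mat& m_, const mat& n_, const mat& Ip, const mat& al,
         const ivec& kd, const vec& am, const vec& ph, double om, double tu)
      : m(m_), n(n_), Iperp(Ip), alpha(al), kind(kd), amp(am), phase(ph),
        omega(om), tau(tu) {
    fgain = 1.0 / std::sqrt(om * om * tu * tu + 1.0);
    flag_ = std::atan(om * tu);
    N = m.n_rows; C = Iperp.n_cols;
  }
  // xconst(theta) = sum_c Iperp_c v_c; uvec alpha-drive
  void theta_terms(double theta, vec& xconst, vec& adrive) const {
    vec v(C), u(C);
    for (uword c = 0; c < C; ++c) {
      v(c) = chan_v(kind(c), amp(c), phase(c), theta, fgain, flag_);
      u(c) = chan_u(kind(c), amp(c), phase(c), theta);
    }
    xconst = Iperp * v;
    adrive = alpha * u;  // length 2
  }
  // derivative for all K columns; optionally per-column Jacobians (2x2xK)
  void rhs(const mat& kap, double theta, mat& dk, cube* Jout) const {
    vec xconst, adrive;
    theta_terms(theta, xconst, adrive);
    mat x = m * kap;           // N x K
    x.each_col() += xconst;
    const mat th = tanh(x);
    dk = (n.t() * th) / double(N);
    dk.each_col() += adrive;
    dk -= kap;
    dk /= tau;
    if (Jout) {
      const mat y = 1.0 - square(th);
      for (uword j = 0; j < kap.n_cols; ++j) {
        mat mj = m;
        mj.each_col() %= y.col(j);
        (*Jout).slice(j) = ((n.t() * mj) / double(N) - eye(2, 2)) / tau;
      }
    }
  }
};

template <typename Field>
Rcpp::List flow_integrate(const Field& F, mat kap, double theta0, double h,
                          int n_steps, int method, bool monodromy,
                          int traj_stride, int rankdim) {
  const uword K = kap.n_cols;
  cube M;
  if (monodromy) {
    M.set_size(rankdim, rankdim, K);
    for (uword j = 0; j < K; ++j) M.slice(j) = eye(rankdim, rankdim);
  }
  vec winding(K, fill::zeros), phiprev(K);
  if (rankdim == 2)
    for (uword j = 0; j < K; ++j) phiprev(j) = std::atan2(kap(1, j), kap(0, j));

  std::vector<mat> traj;
  std::vector<double> traj_theta;
  if (traj_stride > 0) { traj.push_back(kap); traj_theta.push_back(theta0); }

  mat dk1, dk2, dk3, dk4;
  cube J1, J2, J3, J4;
  cube* pJ1 = nullptr; cube* pJ2 = nullptr; cube* pJ3 = nullptr; cube* pJ4 = nullptr;
  if (monodromy) {
    J1.set_size(rankdim, rankdim, K); J2.set_size(rankdim, rankdim, K);
    J3.set_size(rankdim, rankdim, K); J4.set_size(rankdim, rankdim, K);
    pJ1 = &J1; pJ2 = &J2; pJ3 = &J3; pJ4 = &J4;
  }

  for (int s = 0; s < n_steps; ++s) {
    const double th = theta0 + F.omega * (double(s) * h);
    if (method == 0) {  // Euler
      F.rhs(kap, th, dk1, pJ1);
      if (monodromy)
        for (uword j = 0; j < K; ++j)
          M.slice(j) += h * (J1.slice(j) * M.slice(j));
      kap += h * dk1;
    } else {  // RK4 (Jacobian evaluated along the RK4 state stages)
      F.rhs(kap, th, dk1, pJ1);
      F.rhs(kap + 0.5 * h * dk1, th + 0.5 * h * F.omega, dk2, pJ2);
      F.rhs(kap + 0.5 * h * dk2, th + 0.5 * h * F.omega, dk3, pJ3);
      F.rhs(kap + h * dk3, th + h * F.omega, dk4, pJ4);
      if (monodromy) {
        for (uword j = 0; j < K; ++j) {
          const mat& Mj = M.slice(j);
          const mat k1 = J1.slice(j) * Mj;
          const mat k2 = J2.slice(j) * (Mj + 0.5 * h * k1);
          const mat k3 = J3.slice(j) * (Mj + 0.5 * h * k2);
          const mat k4 = J4.slice(j) * (Mj + h * k3);
          M.slice(j) = Mj + (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
        }
      }
      kap += (h / 6.0) * (dk1 + 2.0 * dk2 + 2.0 * dk3 + dk4);
    }
    if (!kap.is_finite()) Rcpp::stop("non-finite state at step %d", s + 1);
    if (rankdim == 2) {
      for (uword j = 0; j < K; ++j) {
        const double ph = std::atan2(kap(1, j), kap(0, j));
        double d = ph - phiprev(j);
        while (d > M_PI) d -= 2.0 * M_PI;
        while (d < -M_PI) d += 2.0 * M_PI;
        winding(j) += d;
        phiprev(j) = ph;
      }
    }
    if (traj_stride > 0 && ((s + 1) % traj_stride == 0)) {
      traj.push_back(kap);
      traj_theta.push_back(theta0 + F.omega * (double(s + 1) * h));
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("kappa") = kap, Rcpp::Named("winding") = winding);
  if (monodromy) out["M"] = M;
  if (traj_stride > 0) {
    cube tr(rankdim, K, traj.size());
    vec tth(traj.size());
    for (size_t i = 0; i < traj.size(); ++i) {
      tr.slice(i) = traj[i];
      tth(i) = traj_theta[i];
    }
    out["traj"] = tr;
    out["traj_theta"] = tth;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_kappa_flow(const arma::mat& m, const arma::mat& n,
                          const arma::mat& Iperp, const arma::mat& alpha,
                          const arma::ivec& ch_kind, const arma::vec& ch_amp,
                          const arma::vec& ch_phase, double omega, double tau,
                          const arma::mat& kappa0, double theta0, double h,
                          int n_steps, int method, bool monodromy,
                          int traj_stride) {
  KField F(m, n, Iperp, alpha, ch_kind, ch_amp, ch_phase, omega, tau);
  return flow_integrate(F, kappa0, theta0, h, n_steps, method, monodromy,
                        traj_stride, 2);
}

// ---------------------------------------------------------------------------
// Mean-field flow for mixture-of-Gaussians connectivity (rank 1 or 2):
//
//  tau dk_i/dt = -k_i + sum_l w_l G_l [ sum_j k_j S_mn(j,i,l)
//                                       + sum_c v_c S_In(c,i,l) ]
//  G_l = 1/sqrt(1 + (pi/2) Delta_l^2),
//  Delta_l^2 = sum_j var_m(j,l) k_j^2 + sum_c var_I(c,l) v_c^2.
// ---------------------------------------------------------------------------
struct MField {
  int rank; const vec& wts;
  const cube& Smn;   // rank x rank x L, S(j,i) = sigma_{m(j) n(i)}
  const cube& Sin;   // C x rank x L
  const mat& var_m;  // rank x L
  const mat& var_I;  // C x L
  const ivec& kind; const vec& amp; const vec& phase;
  double omega, tau, fgain, flag_;
  uword L, C;
  MField(int r, const vec& w_, const cube& Smn_, const cube& Sin_,
         const mat& vm, const mat& vI, const ivec& kd, const vec& am,
         const vec& ph, double om, double tu)
      : rank(r), wts(w_), Smn(Smn_), Sin(Sin_), var_m(vm), var_I(vI),
        kind(kd), amp(am), phase(ph), omega(om), tau(tu) {
    fgain = 1.0 / std::sqrt(om * om * tu * tu + 1.0);
    flag_ = std::atan(om * tu);
    L = wts.n_elem; C = var_I.n_rows;
  }
  void rhs(const mat& kap, double theta, mat& dk, cube* Jout) const {
    const uword K = kap.n_cols;
    vec v(C);
    for (uword c = 0; c < C; ++c)
      v(c) = chan_v(kind(c), amp(c), phase(c), theta, fgain, flag_);
    dk.set_size(rank, K);
    dk = -kap;
    if (Jout)
      for (uword q = 0; q < K; ++q)
        (*Jout).slice(q) = -eye(rank, rank);
    for (uword l = 0; l < L; ++l) {
      // per-column gain and linear terms
      for (uword q = 0; q < K; ++q) {
        double d2 = 0.0;
        for (int j = 0; j < rank; ++j)
          d2 += var_m(j, l) * kap(j, q) * kap(j, q);
        for (uword c = 0; c < C; ++c) d2 += var_I(c, l) * v(c) * v(c);
        const double G = 1.0 / std::sqrt(1.0 + M_PI_2 * d2);
        vec lin(rank, fill::zeros);
        for (int i = 0; i < rank; ++i) {
          for (int j = 0; j < rank; ++j) lin(i) += kap(j, q) * Smn(j, i, l);
          for (uword c = 0; c < C; ++c) lin(i) += v(c) * Sin(c, i, l);
        }
        for (int i = 0; i < rank; ++i) dk(i, q) += wts(l) * G * lin(i);
        if (Jout) {
          const double dG = -(M_PI_2 / 2.0) * std::pow(1.0 + M_PI_2 * d2, -1.5);
          for (int i = 0; i < rank; ++i)
            for (int j = 0; j < rank; ++j)
              (*Jout)(i, j, q) += wts(l) * (G * Smn(j, i, l) +
                  lin(i) * dG * 2.0 * var_m(j, l) * kap(j, q));
        }
      }
    }
    dk /= tau;
    if (Jout) (*Jout) /= tau;
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_mf_flow(int rank, const arma::vec& wts, const arma::cube& Smn,
                       const arma::cube& Sin, const arma::mat& var_m,
                       const arma::mat& var_I, const arma::ivec& ch_kind,
                       const arma::vec& ch_amp, const arma::vec& ch_phase,
                       double omega, double tau, const arma::mat& kappa0,
                       double theta0, double h, int n_steps, int method,
                       bool monodromy, int traj_stride) {
  MField F(rank, wts, Smn, Sin, var_m, var_I, ch_kind, ch_amp, ch_phase,
           omega, tau);
  return flow_integrate(F, kappa0, theta0, h, n_steps, method, monodromy,
                        traj_stride, rank);
}

// ---------------------------------------------------------------------------
// Coupling-function extraction on a (theta, phi) grid (rank-2 network):
//  x(theta, phi) = m1 r cos(phi) + m2 r sin(phi) + sum_c Iperp_c v_c(theta)
//  tau dphi/dt = (1/r^2) [ (1/N) (k1 n2 - k2 n1)' tanh(x)
//                          + (k1 a2c - k2 a1c) u_c(theta) summed over c ]
// Returns dphi/dt in rad/ms; g = dphi/dt - omega is formed in R.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_coupling_grid(const arma::mat& m, const arma::mat& n,
                            const arma::mat& Iperp, const arma::mat& alpha,
                            const arma::ivec& ch_kind, const arma::vec& ch_amp,
                            const arma::vec& ch_phase, double omega,
                            double tau, double r, const arma::vec& theta_grid,
                            const arma::vec& phi_grid) {
  KField F(m, n, Iperp, alpha, ch_kind, ch_amp, ch_phase, omega, tau);
  const uword nt = theta_grid.n_elem, np = phi_grid.n_elem;
  mat out(nt, np);
  mat kap(2, np);
  for (uword p = 0; p < np; ++p) {
    kap(0, p) = r * std::cos(phi_grid(p));
    kap(1, p) = r * std::sin(phi_grid(p));
  }
  mat dk;
  for (uword t = 0; t < nt; ++t) {
    F.rhs(kap, theta_grid(t), dk, nullptr);
    for (uword p = 0; p < np; ++p)
      out(t, p) = (kap(0, p) * dk(1, p) - kap(1, p) * dk(0, p)) / (r * r);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Two-phase oscillator simulation with bilinearly interpolated coupling.
// g is sampled on a regular periodic grid theta in [0,2pi), phi in [0,2pi).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_phase_sim(const arma::mat& g, double omega, double tau_unused,
                         double theta0, const arma::vec& phi0, double h,
                         int n_steps, int traj_stride) {
  const uword nt = g.n_rows, np = g.n_cols, K = phi0.n_elem;
  const double dt_th = 2.0 * M_PI / double(nt), dt_ph = 2.0 * M_PI / double(np);
  auto wrap2pi = [](double x) -> double {
    return x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
  };
  auto interp = [&](double th, double ph) -> double {
    th = wrap2pi(th);
    ph = wrap2pi(ph);
    const double ft = th / dt_th, fp = ph / dt_ph;
    const uword i0 = (uword)std::floor(ft) % nt, i1 = (i0 + 1) % nt;
    const uword j0 = (uword)std::floor(fp) % np, j1 = (j0 + 1) % np;
    const double wt = ft - std::floor(ft), wp = fp - std::floor(fp);
    return (1 - wt) * ((1 - wp) * g(i0, j0) + wp * g(i0, j1)) +
           wt * ((1 - wp) * g(i1, j0) + wp * g(i1, j1));
  };
  vec phi = phi0;
  std::vector<vec> traj;
  if (traj_stride > 0) traj.push_back(phi);
  for (int s = 0; s < n_steps; ++s) {
    const double th = theta0 + omega * double(s) * h;
    // RK4 on phi (theta advances exactly linearly)
    vec k1(K), k2(K), k3(K), k4(K);
    for (uword j = 0; j < K; ++j) k1(j) = omega + interp(th, phi(j));
    for (uword j = 0; j < K; ++j)
      k2(j) = omega + interp(th + 0.5 * h * omega, phi(j) + 0.5 * h * k1(j));
    for (uword j = 0; j < K; ++j)
      k3(j) = omega + interp(th + 0.5 * h * omega, phi(j) + 0.5 * h * k2(j));
    for (uword j = 0; j < K; ++j)
      k4(j) = omega + interp(th + h * omega, phi(j) + h * k3(j));
    phi += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (traj_stride > 0 && ((s + 1) % traj_stride == 0)) traj.push_back(phi);
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("phi") = phi,
      Rcpp::Named("theta") = theta0 + omega * double(n_steps) * h);
  if (traj_stride > 0) {
    mat tr(K, traj.size());
    for (size_t i = 0; i < traj.size(); ++i) tr.col(i) = traj[i];
    out["traj"] = tr;
  }
  return out;
}
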