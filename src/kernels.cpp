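// Numerical kernels: frequency-domain transfer functions of the linearized
// network and Euler-Maruyama integration of the (linearized or nonlinear)
// stochastic dynamics with a conduction-delay buffer.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Transfer functions T(w) = (i*w*I - J0 - exp(-i*w*delay) * Jext)^{-1} B,
// returning the depolarization rows (first nv states) for each frequency.
// [[Rcpp::export]]
arma::cx_cube tf_solve_cpp(const arma::mat& J0, const arma::mat& Jext,
                           const arma::mat& B, const arma::vec& omega,
                           double delay, int nv) {
  const uword n = J0.n_rows, m = B.n_cols, nf = omega.n_elem;
  cx_cube out(nv, m, nf);
  cx_mat I = cx_mat(eye(n, n), zeros(n, n));
  cx_mat cJ0 = cx_mat(J0, zeros(n, n));
  cx_mat cJe = cx_mat(Jext, zeros(n, n));
  cx_mat cB = cx_mat(B, zeros(n, m));
  for (uword k = 0; k < nf; ++k) {
    std::complex<double> iw(0.0, omega(k));
    std::complex<double> ph = std::exp(std::complex<double>(0.0, -omega(k) * delay));
    cx_mat A = iw * I - cJ0 - ph * cJe;
    cx_mat X = solve(A, cB);
    out.slice(k) = X.rows(0, nv - 1);
  }
  return out;
}

// Integrate the two-source network with a Heun (improved Euler) step.
// States x = [v (8); vdot (8)]. Wint, Wext: signed, scaled 8x8 weight
// matrices (target row). drive: nsteps x 2 matrix, already multiplied by
// the drive scale. input_idx: 0-based indices of the spiny stellate
// depolarizations. Extrinsic input uses v delayed by delay_steps. If
// linear, firing is rho * v; otherwise the centered logistic sigmoid with
// the given slope. Returns the v trajectory (nsteps x 8). Throws on
// numerical blow-up.

struct CmcField {
  const mat &Wint, &Wext;
  const vec &kappa;
  vec k2;
  double rho, slope;
  bool linear;
  CmcField(const mat& Wi, const mat& We, const vec& k, double r, double s,
           bool lin) : Wint(Wi), Wext(We), kappa(k), k2(square(k)),
                       rho(r), slope(s), linear(lin) {}
  vec fire(const vec& v) const {
    if (linear) return rho * v;
    return 1.0 / (1.0 + exp(-slope * v)) - 0.5;
  }
  // dv, dvd for given v, vd, delayed v, and per-population drive
  void operator()(const vec& v, const vec& vd, const vec& vdel,
                  const vec& dr, vec& dv, vec& dvd) const {
    vec u = Wint * fire(v) + Wext * fire(vdel) + dr;
    dv = vd;
    dvd = kappa % u - 2.0 * kappa % vd - k2 % v;
  }
};

// [[Rcpp::export]]
arma::mat sim_cmc_cpp(const arma::mat& Wint, const arma::mat& Wext,
                      const arma::vec& kappa, double rho, double slope,
                      const arma::mat& drive, const arma::uvec& input_idx,
                      double dt, int delay_steps, bool linear) {
  const uword np = kappa.n_elem, nsteps = drive.n_rows;
  const int d = delay_steps;
  vec v(np, fill::zeros), vd(np, fill::zeros);
  CmcField f(Wint, Wext, kappa, rho, slope, linear);
  mat buf(np, std::max(d, 1), fill::zeros); // slot (t mod d) holds v(t)
  mat out(nsteps, np);
  vec dr1(np, fill::zeros), dr2(np, fill::zeros);
  vec dv1(np), dvd1(np), dv2(np), dvd2(np);
  for (uword t = 0; t < nsteps; ++t) {
    uword t2 = std::min(t + 1, nsteps - 1);
    dr1.zeros(); dr2.zeros();
    for (uword s = 0; s < input_idx.n_elem; ++s) {
      dr1(input_idx(s)) = drive(t, s);
      dr2(input_idx(s)) = drive(t2, s);
    }
    vec vdel1 = (d > 0) ? vec(buf.col(t % d)) : v;
    f(v, vd, vdel1, dr1, dv1, dvd1);
    vec vp = v + dt * dv1, vdp = vd + dt * dvd1;
    vec vdel2 = (d > 1) ? vec(buf.col((t + 1) % d)) : vp;
    f(vp, vdp, vdel2, dr2, dv2, dvd2);
    if (d > 0) buf.col(t % d) = v;
    v += 0.5 * dt * (dv1 + dv2);
    vd += 0.5 * dt * (dvd1 + dvd2);
    out.row(t) = v.t();
    if (!v.is_finite() || norm(v) > 1e6)
      Rcpp::stop("numerical blow-up at step %d (state norm > 1e6)", (int)t);
  }
  return out;
}
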