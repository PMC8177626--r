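// Inner loop of the nonlinear eye-plant simulator.
//
// The R level owns the plant description (see plant_pack()); this file only
// advances the rigid-body state.  Integration: each 10 ms control tick is
// divided into `substeps` semi-implicit Euler substeps; the inertia tensor
// and muscle geometry are refreshed every substep, the cranial insertion
// points only when the motor command changes (once per tick).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Plant {
  mat Q0, X, rod_center, rod_offset, rod_axis, I0;
  uvec has_via, driver;
  vec rod_sense, kappa, l0;
  double chi_dyn, chi_stat, eps, dt;
  int substeps;
};

Plant unpack(const Rcpp::List& p) {
  Plant pl;
  pl.Q0 = Rcpp::as<mat>(p["Q0"]);
  pl.X = Rcpp::as<mat>(p["X"]);
  pl.has_via = Rcpp::as<uvec>(p["has_via"]);
  pl.rod_center = Rcpp::as<mat>(p["rod_center"]);
  pl.rod_offset = Rcpp::as<mat>(p["rod_offset"]);
  pl.rod_axis = Rcpp::as<mat>(p["rod_axis"]);
  pl.rod_sense = Rcpp::as<vec>(p["rod_sense"]);
  pl.driver = Rcpp::as<uvec>(p["driver"]);
  pl.kappa = Rcpp::as<vec>(p["kappa"]);
  pl.l0 = Rcpp::as<vec>(p["l0"]);
  pl.chi_dyn = p["chi_dyn"];
  pl.chi_stat = p["chi_stat"];
  pl.eps = p["eps"];
  pl.dt = p["dt"];
  pl.substeps = p["substeps"];
  pl.I0 = Rcpp::as<mat>(p["I0"]);
  return pl;
}

mat quat_matrix(const vec& q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat R(3, 3);
  R(0, 0) = 1 - 2 * (y * y + z * z); R(0, 1) = 2 * (x * y - w * z); R(0, 2) = 2 * (x * z + w * y);
  R(1, 0) = 2 * (x * y + w * z); R(1, 1) = 1 - 2 * (x * x + z * z); R(1, 2) = 2 * (y * z - w * x);
  R(2, 0) = 2 * (x * z - w * y); R(2, 1) = 2 * (y * z + w * x); R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

mat axis_angle(const vec& a, double ang) {
  mat K = {{0, -a(2), a(1)}, {a(2), 0, -a(0)}, {-a(1), a(0), 0}};
  return eye(3, 3) + std::sin(ang) * K + (1 - std::cos(ang)) * (K * K);
}

// cranial insertion points for motor command u (3) -> 3 x 6
mat insertions(const Plant& pl, const vec& u) {
  mat P(3, 6);
  for (int k = 0; k < 3; ++k) {
    mat R = axis_angle(pl.rod_axis.col(k), pl.rod_sense(k) * u(k));
    for (int i = 0; i < 6; ++i)
      if ((int)pl.driver(i) == k)
        P.col(i) = pl.rod_center.col(k) + R * pl.rod_offset.col(i);
  }
  return P;
}

// total elastic torque at orientation R with cranial points P; optionally
// accumulates the summed tension magnitude
vec elastic_torque(const Plant& pl, const mat& R, const mat& P,
                   double* tension_sum = nullptr) {
  vec tau(3, fill::zeros);
  for (int i = 0; i < 6; ++i) {
    vec Q = R * pl.Q0.col(i);
    vec anchor = pl.has_via(i) ? vec(pl.X.col(i)) : vec(P.col(i));
    vec seg1 = anchor - Q;
    double n1 = norm(seg1);
    double len = n1 + (pl.has_via(i) ? norm(P.col(i) - pl.X.col(i)) : 0.0);
    double mag = pl.kappa(i) * std::max(len - pl.l0(i), 0.0);
    if (tension_sum) *tension_sum += mag;
    tau += cross(Q, (mag / n1) * seg1);
  }
  return tau;
}

void normalize_quat(vec& q) {
  q /= norm(q);
  if (q(0) < 0) q = -q;
}

// one inner substep of duration h; returns false if the state went unstable
bool substep(const Plant& pl, const mat& P, vec& q, vec& w, double h,
             bool gyro) {
  mat R = quat_matrix(q);
  vec tel = elastic_torque(pl, R, P);
  vec tdyn = -pl.chi_dyn * w;
  vec tcomp = tel + tdyn;
  if (norm(w) < pl.eps && norm(tcomp) < pl.chi_stat) {
    w.zeros();  // stiction holds until the elastic torque exceeds the bound
    return true;
  }
  mat Iw = R * pl.I0 * R.t();
  vec tau = tcomp;
  if (gyro) tau -= cross(w, Iw * w);
  vec alpha = solve(Iw, tau, solve_opts::fast);
  w += h * alpha;                       // semi-implicit: new velocity ...
  vec wq = {0, w(0), w(1), w(2)};       // ... advances the orientation
  vec qdot = 0.5 * vec({wq(0) * q(0) - dot(wq.subvec(1, 3), q.subvec(1, 3)),
                        wq(0) * q(1) + q(0) * wq(1) + wq(2) * q(3) - wq(3) * q(2),
                        wq(0) * q(2) + q(0) * wq(2) + wq(3) * q(1) - wq(1) * q(3),
                        wq(0) * q(3) + q(0) * wq(3) + wq(1) * q(2) - wq(2) * q(1)});
  q += h * qdot;
  normalize_quat(q);
  return norm(w) <= 1e3;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_simulate(Rcpp::List plant, arma::mat U, arma::vec q0,
                        arma::vec w0, bool gyroscopic = false) {
  Plant pl = unpack(plant);
  int n = U.n_rows;
  double h = pl.dt / pl.substeps;
  mat qs(n + 1, 4), ws(n + 1, 3), rs(n + 1, 3);
  vec q = q0, w = w0;
  normalize_quat(q);
  auto record = [&](int t) {
    qs.row(t) = q.t();
    ws.row(t) = w.t();
    rs.row(t) = (q.subvec(1, 3) / q(0)).t();
  };
  record(0);
  for (int t = 0; t < n; ++t) {
    mat P = insertions(pl, U.row(t).t());
    for (int s = 0; s < pl.substeps; ++s)
      if (!substep(pl, P, q, w, h, gyroscopic))
        Rcpp::stop("simulation unstable at tick %d (|omega| > 1e3 rad/s); "
                   "check plant parameters/inputs", t + 1);
    record(t + 1);
  }
  return Rcpp::List::create(Rcpp::Named("q") = qs, Rcpp::Named("omega") = ws,
                            Rcpp::Named("r") = rs);
}

// Hold a constant motor command until the eye settles (|omega| below tol for
// hold_s seconds) or timeout; returns the final state and summed tension.
// [[Rcpp::export]]
Rcpp::List cpp_settle(Rcpp::List plant, arma::vec u, arma::vec q0,
                      arma::vec w0, double tol = 0.00872664625997165,
                      double hold_s = 0.1, double timeout_s = 5.0) {
  Plant pl = unpack(plant);
  double h = pl.dt / pl.substeps;
  vec q = q0, w = w0;
  normalize_quat(q);
  mat P = insertions(pl, u);
  int need = (int)std::round(hold_s / h);
  int maxit = (int)std::round(timeout_s / h);
  int quiet = 0, it = 0;
  for (; it < maxit; ++it) {
    if (!substep(pl, P, q, w, h, false))
      Rcpp::stop("settling unstable (|omega| > 1e3 rad/s)");
    quiet = (norm(w) < tol) ? quiet + 1 : 0;
    if (quiet >= need) break;
  }
  double tension = 0;
  elastic_torque(pl, quat_matrix(q), P, &tension);
  return Rcpp::List::create(
      Rcpp::Named("q") = q, Rcpp::Named("omega") = w,
      Rcpp::Named("r") = vec(q.subvec(1, 3) / q(0)),
      Rcpp::Named("settled") = (quiet >= need),
      Rcpp::Named("t") = (it + 1) * h, Rcpp::Named("tension") = tension);
}

// Settle a whole grid of motor commands with warm starts (each settle starts
// from the previous settled state); rows of Ugrid are motor commands.
// [[Rcpp::export]]
Rcpp::List cpp_settle_grid(Rcpp::List plant, arma::mat Ugrid,
                           double tol = 0.00872664625997165,
                           double hold_s = 0.1, double timeout_s = 5.0,
                           bool warm = true) {
  Plant pl = unpack(plant);
  double h = pl.dt / pl.substeps;
  int n = Ugrid.n_rows;
  mat rs(n, 3);
  vec tensions(n);
  uvec ok(n);
  vec q = {1, 0, 0, 0}, w(3, fill::zeros);
  int need = (int)std::round(hold_s / h);
  int maxit = (int)std::round(timeout_s / h);
  for (int g = 0; g < n; ++g) {
    if (!warm) { q = {1, 0, 0, 0}; w.zeros(); }
    mat P = insertions(pl, Ugrid.row(g).t());
    int quiet = 0, it = 0;
    for (; it < maxit; ++it) {
      if (!substep(pl, P, q, w, h, false))
        Rcpp::stop("settling unstable at grid row %d", g + 1);
      quiet = (norm(w) < tol) ? quiet + 1 : 0;
      if (quiet >= need) break;
    }
    double tension = 0;
    elastic_torque(pl, quat_matrix(q), P, &tension);
    rs.row(g) = (q.subvec(1, 3) / q(0)).t();
    tensions(g) = tension;
    ok(g) = (quiet >= need) ? 1 : 0;
  }
  return Rcpp::List::create(Rcpp::Named("r") = rs,
                            Rcpp::Named("tension") = tensions,
                            Rcpp::Named("settled") = ok);
}
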