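// Exact discretization of the three-compartment mammillary model under
// piecewise-constant infusion.  Between dose events the system is LTI, so the
// state is propagated with the matrix exponential of the augmented system
//
//   d/ds [x; w] = [A  b; 0  0] [x; w],  w(0) = 1,
//
// whose exponential holds both e^{A dt} and the zero-order-hold particular
// solution (Van Loan's trick; no inversion of A, so nearly singular rate
// configurations are safe).  The code is templated on the scalar type so the
// same path runs in complex arithmetic; parameter derivatives are obtained by
// the complex-step method, which is exact to machine precision because no
// subtractive cancellation occurs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

typedef std::complex<double> cplx;
typedef arma::Mat<double>::fixed<4, 4> mat44;

static double abs1(double v) { return std::abs(v); }
static double abs1(const cplx& v) { return std::abs(v); }

// Matrix exponential of a fixed 4x4 via scaling-and-squaring with a [13/13]
// Pade approximant (Higham 2005, single branch).  Fixed-size arithmetic
// avoids heap churn; templated so the complex-step path shares the code.
template <typename T>
static typename arma::Mat<T>::template fixed<4, 4> expm44(
    typename arma::Mat<T>::template fixed<4, 4> A) {
  typedef typename arma::Mat<T>::template fixed<4, 4> M44;
  static const double b[] = {
      64764752532480000.0, 32382376266240000.0, 7771770303897600.0,
      1187353796428800.0,  129060195264000.0,   10559470521600.0,
      670442572800.0,      33522128640.0,       1323241920.0,
      40840800.0,          960960.0,            16380.0,
      182.0,               1.0};
  const double theta13 = 5.371920351148152;

  double nrm = 0.0;  // 1-norm
  for (int j = 0; j < 4; ++j) {
    double c = 0.0;
    for (int i = 0; i < 4; ++i) c += abs1(A(i, j));
    nrm = std::max(nrm, c);
  }
  int s = 0;
  if (nrm > theta13) {
    s = (int)std::ceil(std::log2(nrm / theta13));
    A *= T(std::pow(2.0, -s));
  }
  M44 I(arma::fill::eye);
  M44 A2 = A * A, A4 = A2 * A2, A6 = A2 * A4;
  M44 U = A * (A6 * (T(b[13]) * A6 + T(b[11]) * A4 + T(b[9]) * A2) +
               T(b[7]) * A6 + T(b[5]) * A4 + T(b[3]) * A2 + T(b[1]) * I);
  M44 V = A6 * (T(b[12]) * A6 + T(b[10]) * A4 + T(b[8]) * A2) +
          T(b[6]) * A6 + T(b[4]) * A4 + T(b[2]) * A2 + T(b[0]) * I;
  M44 E = arma::solve(V - U, V + U);
  for (int k = 0; k < s; ++k) E = E * E;
  return E;
}

// State propagation over one interval of length dt with constant rate u.
template <typename T>
static void step_interval(arma::Col<T>& x, const arma::Mat<T>& A,
                          double u, const T& V1, double dt) {
  typename arma::Mat<T>::template fixed<4, 4> M(arma::fill::zeros);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) M(i, j) = A(i, j) * dt;
  M(0, 3) = T(u) / V1 * dt;
  typename arma::Mat<T>::template fixed<4, 4> E = expm44<T>(M);
  T xn[3];
  for (int i = 0; i < 3; ++i) {
    T acc = E(i, 3);
    for (int j = 0; j < 3; ++j) acc += E(i, j) * x(j);
    xn[i] = acc;
  }
  for (int i = 0; i < 3; ++i) x(i) = xn[i];
}

// Central-compartment concentration at each (sorted, non-negative) obs time.
// evt strictly increasing; rate evr[j] holds from evt[j] until the next event;
// rate is zero before the first event.  State starts at zero at t = 0.
template <typename T>
static arma::Col<T> simulate_T(const arma::Col<T>& p,
                               const arma::vec& evt, const arma::vec& evr,
                               const arma::vec& obst) {
  const T k10 = p(0), k12 = p(1), k13 = p(2), k21 = p(3), k31 = p(4),
          V1 = p(5);
  arma::Mat<T> A(3, 3, arma::fill::zeros);
  A(0, 0) = -(k10 + k12 + k13);
  A(0, 1) = k21;
  A(0, 2) = k31;
  A(1, 0) = k12;
  A(1, 1) = -k21;
  A(2, 0) = k13;
  A(2, 2) = -k31;

  const arma::uword ne = evt.n_elem, no = obst.n_elem;
  arma::Col<T> x(3, arma::fill::zeros), out(no, arma::fill::zeros);
  double t = 0.0, u = 0.0;
  arma::uword ie = 0, io = 0;

  while (io < no || ie < ne) {
    double tn;
    if (ie < ne && io < no)
      tn = std::min(evt(ie), obst(io));
    else if (ie < ne)
      tn = evt(ie);
    else
      tn = obst(io);
    if (tn > t) {
      step_interval(x, A, u, V1, tn - t);
      t = tn;
    }
    while (ie < ne && evt(ie) <= t) {
      u = evr(ie);
      ++ie;
    }
    while (io < no && obst(io) <= t) {
      out(io) = x(0);
      ++io;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".sim_cpp")]]
NumericVector sim_cpp(NumericVector p, NumericVector evt, NumericVector evr,
                      NumericVector obst) {
  arma::vec pv(p.begin(), p.size(), false);
  arma::vec ev(evt.begin(), evt.size(), false);
  arma::vec rv(evr.begin(), evr.size(), false);
  arma::vec ov(obst.begin(), obst.size(), false);
  arma::vec out = simulate_T<double>(pv, ev, rv, ov);
  return wrap(out);
}

static const double kCstep = 1e-20;  // complex-step size

static arma::mat jacobian_cstep(const arma::vec& p, const arma::vec& evt,
                                const arma::vec& evr, const arma::vec& obst) {
  arma::mat jac(obst.n_elem, 6);
  for (int k = 0; k < 6; ++k) {
    arma::Col<cplx> pc(6);
    for (int j = 0; j < 6; ++j) pc(j) = cplx(p(j), 0.0);
    pc(k) += cplx(0.0, kCstep);
    arma::Col<cplx> out = simulate_T<cplx>(pc, evt, evr, obst);
    jac.col(k) = arma::imag(out) / kCstep;
  }
  return jac;
}

// [[Rcpp::export(name = ".sim_jac_cpp")]]
List sim_jac_cpp(NumericVector p, NumericVector evt, NumericVector evr,
                 NumericVector obst) {
  arma::vec pv(p.begin(), p.size(), false);
  arma::vec ev(evt.begin(), evt.size(), false);
  arma::vec rv(evr.begin(), evr.size(), false);
  arma::vec ov(obst.begin(), obst.size(), false);
  arma::vec conc = simulate_T<double>(pv, ev, rv, ov);
  arma::mat jac = jacobian_cstep(pv, ev, rv, ov);
  return List::create(Named("conc") = conc, Named("jac") = jac);
}

// Median indices/weights following the mean-of-central-pair convention.
static void median_sel(const arma::vec& v, arma::uvec& idx, arma::vec& w) {
  arma::uvec ord = arma::stable_sort_index(v);
  arma::uword n = v.n_elem;
  if (n % 2 == 1) {
    idx.set_size(1);
    w.set_size(1);
    idx(0) = ord(n / 2);
    w(0) = 1.0;
  } else {
    idx.set_size(2);
    w.set_size(2);
    idx(0) = ord(n / 2 - 1);
    idx(1) = ord(n / 2);
    w(0) = w(1) = 0.5;
  }
}

static double mdale_one(const arma::vec& conc, const arma::vec& cobs,
                        double cmin) {
  arma::vec ale = arma::abs(arma::log(cobs / arma::clamp(conc, cmin,
                                                         arma::datum::inf)));
  return arma::median(ale);
}

// Per-individual MdALE for a population; theta is 6 x n (k10,...,V1 rows).
// [[Rcpp::export(name = ".pop_mdale_cpp")]]
NumericVector pop_mdale_cpp(NumericMatrix theta, List evt, List evr, List obst,
                            List cobs, double cmin = 1e-12) {
  const int n = theta.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    arma::vec p(6);
    for (int k = 0; k < 6; ++k) p(k) = theta(k, i);
    arma::vec ev = as<arma::vec>(evt[i]);
    arma::vec rv = as<arma::vec>(evr[i]);
    arma::vec ov = as<arma::vec>(obst[i]);
    arma::vec co = as<arma::vec>(cobs[i]);
    arma::vec conc = simulate_T<double>(p, ev, rv, ov);
    out[i] = mdale_one(conc, co, cmin);
  }
  return out;
}

// Smooth companion objective: per-individual mean squared log error and its
// exact parameter gradient.  Used by the baseline fitters to locate the basin
// before polishing the (nonsmooth) median loss.
// [[Rcpp::export(name = ".pop_sqlog_cpp")]]
List pop_sqlog_cpp(NumericMatrix theta, List evt, List evr, List obst,
                   List cobs, double cmin = 1e-12) {
  const int n = theta.ncol();
  NumericVector val(n);
  NumericMatrix dth(6, n);
  for (int i = 0; i < n; ++i) {
    arma::vec p(6);
    for (int k = 0; k < 6; ++k) p(k) = theta(k, i);
    arma::vec ev = as<arma::vec>(evt[i]);
    arma::vec rv = as<arma::vec>(evr[i]);
    arma::vec ov = as<arma::vec>(obst[i]);
    arma::vec co = as<arma::vec>(cobs[i]);
    arma::vec conc = simulate_T<double>(p, ev, rv, ov);
    arma::vec cp = arma::clamp(conc, cmin, arma::datum::inf);
    arma::vec le = arma::log(cp / co);
    val[i] = arma::mean(arma::square(le));
    arma::mat jac = jacobian_cstep(p, ev, rv, ov);
    arma::vec g(6, arma::fill::zeros);
    for (arma::uword j = 0; j < cp.n_elem; ++j) {
      if (conc(j) < cmin) continue;
      g += (2.0 / cp.n_elem) * le(j) / cp(j) * jac.row(j).t();
    }
    for (int k = 0; k < 6; ++k) dth(k, i) = g(k);
  }
  return List::create(Named("value") = val, Named("dtheta") = dth);
}

// Per-individual MdALE and its gradient w.r.t. the six PK parameters.
// The median is differentiated through its selected order statistic(s); for an
// even sample count the gradient splits 0.5/0.5 over the central pair.
// Predictions clamped below cmin contribute zero gradient.
// [[Rcpp::export(name = ".pop_grad_cpp")]]
List pop_grad_cpp(NumericMatrix theta, List evt, List evr, List obst,
                  List cobs, double cmin = 1e-12) {
  const int n = theta.ncol();
  NumericVector md(n);
  NumericMatrix dth(6, n);
  for (int i = 0; i < n; ++i) {
    arma::vec p(6);
    for (int k = 0; k < 6; ++k) p(k) = theta(k, i);
    arma::vec ev = as<arma::vec>(evt[i]);
    arma::vec rv = as<arma::vec>(evr[i]);
    arma::vec ov = as<arma::vec>(obst[i]);
    arma::vec co = as<arma::vec>(cobs[i]);
    arma::vec conc = simulate_T<double>(p, ev, rv, ov);
    arma::vec cp = arma::clamp(conc, cmin, arma::datum::inf);
    arma::vec le = arma::log(co / cp);
    arma::vec ale = arma::abs(le);
    md[i] = arma::median(ale);

    arma::uvec sel;
    arma::vec w;
    median_sel(ale, sel, w);
    arma::mat jac = jacobian_cstep(p, ev, rv, ov);
    arma::vec g(6, arma::fill::zeros);
    for (arma::uword s = 0; s < sel.n_elem; ++s) {
      arma::uword j = sel(s);
      if (conc(j) < cmin) continue;           // clamped: no gradient flow
      double sgn = (le(j) > 0) - (le(j) < 0);  // d ALE / d LE
      // d LE / d Cpred = -1 / Cpred
      g += w(s) * (-sgn / cp(j)) * jac.row(j).t();
    }
    for (int k = 0; k < 6; ++k) dth(k, i) = g(k);
  }
  return List::create(Named("mdale") = md, Named("dtheta") = dth);
}
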