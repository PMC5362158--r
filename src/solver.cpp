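// Stiff deterministic simulation of generalized mass-action systems.
//
// The integrator is a modified Rosenbrock pair of order 2(3) (the ode23s
// scheme of Shampine & Reichelt) with the analytic Jacobian of the
// mass-action rate law. Rosenbrock methods need only linear solves (no
// Newton iteration), are A/L-stable, and so cope with the rate-scale
// separations that arise here (fast annihilation eta >> gamma, integral
// gains of order 1e-8, binding rates up to 1e6).
//
// The system is dx/dt = Peff * f(x) where f_j(x) = k_j * prod x_s^ord_js.
// Peff is the stoichiometric matrix restricted to dynamic (non-clamped)
// species, optionally with per-(species, reaction) multipliers already
// folded in (used by the per-ODE-term perturbation machinery). Clamped
// species enter the rate law at fixed concentrations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

namespace {

struct Reactant {
  int idx;
  int ord;
};

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

class MassActionSystem {
public:
  MassActionSystem(const arma::mat& Peff, const IntegerMatrix& Ord,
                   const arma::vec& k, const IntegerVector& dynIdx, int nFull)
      : Peff_(Peff), k_(k), nFull_(nFull) {
    int m = Ord.nrow(), n = Ord.ncol();
    reactants_.resize(m);
    for (int j = 0; j < m; ++j)
      for (int s = 0; s < n; ++s)
        if (Ord(j, s) > 0) reactants_[j].push_back({s, Ord(j, s)});
    dyn_ = std::vector<int>(dynIdx.begin(), dynIdx.end());
    posOf_.assign(nFull, -1);
    for (size_t i = 0; i < dyn_.size(); ++i) posOf_[dyn_[i]] = (int)i;
  }

  int nDyn() const { return (int)dyn_.size(); }
  int nRxn() const { return (int)k_.n_elem; }

  void setFull(const arma::vec& xFull) { xFull_ = xFull; }
  void syncDyn(const arma::vec& y) {
    for (size_t i = 0; i < dyn_.size(); ++i) xFull_[dyn_[i]] = y[i];
  }

  arma::vec rates() const {
    arma::vec r(k_.n_elem);
    for (size_t j = 0; j < reactants_.size(); ++j) {
      double v = k_[j];
      for (const Reactant& rc : reactants_[j]) v *= ipow(xFull_[rc.idx], rc.ord);
      r[j] = v;
    }
    return r;
  }

  arma::vec f(const arma::vec& y) {
    syncDyn(y);
    return Peff_ * rates();
  }

  // Jacobian of Peff * f(x) w.r.t. dynamic species, at current xFull_.
  arma::mat jac(const arma::vec& y) {
    syncDyn(y);
    int nd = nDyn();
    arma::mat J(nd, nd, arma::fill::zeros);
    for (size_t j = 0; j < reactants_.size(); ++j) {
      for (const Reactant& rc : reactants_[j]) {
        int p = posOf_[rc.idx];
        if (p < 0) continue;  // derivative w.r.t. a clamped species: no state
        double d = k_[j] * rc.ord * ipow(xFull_[rc.idx], rc.ord - 1);
        for (const Reactant& other : reactants_[j]) {
          if (other.idx == rc.idx) continue;
          d *= ipow(xFull_[other.idx], other.ord);
        }
        J.col(p) += Peff_.col(j) * d;
      }
    }
    return J;
  }

  arma::vec xFull_;

private:
  arma::mat Peff_;
  arma::vec k_;
  std::vector<std::vector<Reactant>> reactants_;
  std::vector<int> dyn_;
  std::vector<int> posOf_;
  int nFull_;
};

inline void hermite(double theta, double h, const arma::vec& y0,
                    const arma::vec& y1, const arma::vec& f0,
                    const arma::vec& f1, arma::vec& out) {
  // cubic Hermite interpolant on one accepted step
  double t2 = theta * theta, t3 = t2 * theta;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  out = h00 * y0 + (h10 * h) * f0 + h01 * y1 + (h11 * h) * f1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericMatrix Peff, IntegerMatrix Ord, NumericVector k,
                  IntegerVector dynIdx, NumericVector x0Full,
                  NumericVector tout, double rtol, double atol, double hmax,
                  double maxSteps, NumericVector divergeBound) {
  // divergeBound: per-dynamic-species bound; non-positive entries disable
  // the check for that species
  bool anyBound = false;
  for (int i = 0; i < divergeBound.size(); ++i)
    if (divergeBound[i] > 0) anyBound = true;
  const int nFull = x0Full.size();
  const int nt = tout.size();
  arma::mat P(Peff.begin(), Peff.nrow(), Peff.ncol(), true);
  arma::vec kk(k.begin(), k.size(), true);
  MassActionSystem sys(P, Ord, kk, dynIdx, nFull);
  sys.setFull(arma::vec(x0Full.begin(), nFull, true));

  const int nd = sys.nDyn();
  NumericMatrix X(nt, nFull);
  // clamped / constant columns keep their initial values throughout
  for (int i = 0; i < nt; ++i)
    for (int s = 0; s < nFull; ++s) X(i, s) = x0Full[s];

  double t0 = tout[0], tEnd = tout[nt - 1];
  int status = 0;
  double tLast = t0;
  long nsteps = 0, nrej = 0;

  arma::vec y(nd);
  for (int i = 0; i < nd; ++i) y[i] = x0Full[dynIdx[i]];

  int iout = 0;
  auto emit = [&](int row, const arma::vec& yv) {
    for (int i = 0; i < nd; ++i) X(row, dynIdx[i]) = yv[i];
  };
  if (nt > 0) {
    emit(0, y);
    iout = 1;
  }

  if (nd > 0 && tEnd > t0) {
    const double d = 1.0 / (2.0 + std::sqrt(2.0));
    const double e32 = 6.0 + std::sqrt(2.0);
    if (hmax <= 0) hmax = (tEnd - t0) / 2.0;

    arma::vec F0 = sys.f(y);
    // initial step from derivative scale
    double h = hmax;
    {
      double d1 = 0;
      for (int i = 0; i < nd; ++i) {
        double sc = atol + rtol * std::fabs(y[i]);
        d1 = std::max(d1, std::fabs(F0[i]) / sc);
      }
      if (d1 > 0) h = std::min(h, 0.01 / d1);
      // never start below a small fraction of the span: the Rosenbrock
      // scheme is A-stable, so an over-large guess is only rejected and
      // shrunk by the error controller, while an underflow-small guess
      // would abort at once
      h = std::max(h, 1e-9 * (tEnd - t0));
      h = std::min(h, tEnd - t0);
    }

    double t = t0;
    arma::mat I = arma::eye(nd, nd);
    arma::vec ynew(nd), k1(nd), k2(nd), k3(nd), F1(nd), F2(nd), err(nd),
        yint(nd);

    while (t < tEnd) {
      if (nsteps + nrej > maxSteps) {
        status = 2;
        break;
      }
      double hmin = 16.0 * std::numeric_limits<double>::epsilon() *
                    std::max(std::fabs(t), 1.0);
      if (h < hmin) {
        status = 1;
        break;
      }
      if (t + h > tEnd) h = tEnd - t;

      arma::mat J = sys.jac(y);
      arma::mat W = I - (h * d) * J;
      arma::mat L, U, Pm;
      bool ok = arma::lu(L, U, Pm, W);
      if (ok) {
        double dmax = arma::abs(U.diag()).max();
        double dmin = arma::abs(U.diag()).min();
        if (!(dmax > 0) || dmin < 1e-14 * dmax) ok = false;
      }
      if (!ok) {
        h *= 0.5;
        ++nrej;
        continue;
      }
      auto wsolve = [&](const arma::vec& b) {
        arma::vec z = arma::solve(arma::trimatl(L), Pm * b,
                                  arma::solve_opts::fast);
        return arma::vec(arma::solve(arma::trimatu(U), z,
                                     arma::solve_opts::fast));
      };

      k1 = wsolve(F0);
      F1 = sys.f(y + 0.5 * h * k1);
      k2 = wsolve(F1 - k1) + k1;
      ynew = y + h * k2;
      bool finite = ynew.is_finite();
      double errnorm = 2.0;
      if (finite) {
        F2 = sys.f(ynew);
        finite = F2.is_finite();
      }
      if (finite) {
        k3 = wsolve(F2 - e32 * (k2 - F1) - 2.0 * (k1 - F0));
        err = (h / 6.0) * (k1 - 2.0 * k2 + k3);
        errnorm = 0;
        for (int i = 0; i < nd; ++i) {
          double sc =
              atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
          errnorm = std::max(errnorm, std::fabs(err[i]) / sc);
        }
        if (!std::isfinite(errnorm)) errnorm = 2.0;
      }

      if (errnorm <= 1.0) {
        // accepted: dense output for any grid point inside this step
        double tnew = t + h;
        while (iout < nt && tout[iout] <= tnew + 1e-12 * std::fabs(tnew)) {
          double theta = (tout[iout] - t) / h;
          theta = std::min(std::max(theta, 0.0), 1.0);
          hermite(theta, h, y, ynew, F0, F2, yint);
          emit(iout, yint);
          ++iout;
        }
        t = tnew;
        y = ynew;
        F0 = F2;
        ++nsteps;
        tLast = t;
        if (anyBound) {
          for (int i = 0; i < nd; ++i) {
            if (divergeBound[i] > 0 && std::fabs(y[i]) > divergeBound[i]) {
              status = 3;
              break;
            }
          }
          if (status == 3) break;
        }
        double fac = 0.8 * std::pow(std::max(errnorm, 1e-10), -1.0 / 3.0);
        h *= std::min(5.0, std::max(0.2, fac));
        h = std::min(h, hmax);
      } else {
        ++nrej;
        double fac = 0.8 * std::pow(errnorm, -1.0 / 3.0);
        h *= std::min(0.9, std::max(0.1, fac));
      }
    }
    // grid points past the failure time are left at the last emitted state
    if (status != 0) {
      for (int i = iout; i < nt; ++i) emit(i, y);
    }
  } else {
    // nothing dynamic: state is constant
    for (int i = 1; i < nt; ++i) emit(i, y);
    tLast = tEnd;
  }

  return List::create(_["x"] = X, _["status"] = status, _["t_last"] = tLast,
                      _["nsteps"] = (double)nsteps, _["nrej"] = (double)nrej,
                      _["n_out"] = iout);
}
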