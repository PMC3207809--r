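#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Penalized Cox partial-likelihood solver: cyclic coordinate descent on the
// IRLS quadratic approximation with active-set sweeps, warm-started along a
// decreasing lambda grid, with an objective-decrease safeguard per outer
// step and stagnation detection on the KKT residual.
//
// Data layout (prepared on the R side):
//   X        : n x p matrix, rows sorted by ascending follow-up time
//   isEvent  : 0/1 per sample (sorted order)
//   grpFirst : for each distinct event time t_k (ascending), the 0-based index
//              of the first sample with y >= t_k (risk set = suffix from here)
//   grpD     : number of events at t_k (Breslow tie handling)
//   nGrpLE   : per sample, number of distinct event times <= its own time
//
// Objective: f(beta) = -logPL(beta) + lambda * ||beta||_1 + lambda2 * ||beta||_2^2

namespace {

struct CoxWork {
  std::vector<double> r;   // exp(eta - M), shifted for stability
  std::vector<double> w;   // diagonal Hessian weights
  std::vector<double> u;   // score residuals: delta_j - mu_j
  double nloglik;
};

void cox_quantities(const std::vector<double>& eta, const IntegerVector& isEvent,
                    const IntegerVector& grpFirst, const IntegerVector& grpD,
                    const IntegerVector& nGrpLE, CoxWork& wk) {
  const int n = (int)eta.size();
  const int m = grpFirst.size();
  double M = eta[0];
  for (int j = 1; j < n; ++j) if (eta[j] > M) M = eta[j];

  wk.r.assign(n, 0.0);
  for (int j = 0; j < n; ++j) wk.r[j] = std::exp(eta[j] - M);

  std::vector<double> suff(n + 1, 0.0);
  for (int j = n - 1; j >= 0; --j) suff[j] = suff[j + 1] + wk.r[j];

  std::vector<double> cumA(m + 1, 0.0), cumB(m + 1, 0.0);
  double nll = 0.0;
  for (int k = 0; k < m; ++k) {
    const double s0 = suff[grpFirst[k]];
    cumA[k + 1] = cumA[k] + grpD[k] / s0;
    cumB[k + 1] = cumB[k] + grpD[k] / (s0 * s0);
    nll += grpD[k] * (M + std::log(s0));
  }
  for (int j = 0; j < n; ++j) if (isEvent[j]) nll -= eta[j];

  wk.w.assign(n, 0.0);
  wk.u.assign(n, 0.0);
  for (int j = 0; j < n; ++j) {
    const int g = nGrpLE[j];
    const double mu = wk.r[j] * cumA[g];
    double wj = mu - wk.r[j] * wk.r[j] * cumB[g];
    if (wj < 0.0) wj = 0.0;  // guards rounding; true value is nonnegative
    wk.w[j] = wj;
    wk.u[j] = (isEvent[j] ? 1.0 : 0.0) - mu;
  }
  wk.nloglik = nll;
}

inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".cox_cd_path")]]
List cox_cd_path(NumericMatrix X, IntegerVector isEvent, IntegerVector grpFirst,
                 IntegerVector grpD, IntegerVector nGrpLE, NumericVector lambdas,
                 double lambda2, NumericVector betaInit, double tolInner,
                 double tolKKT, int maxOuter, int maxInner) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix betaPath(p, L);
  NumericVector nll(L);
  LogicalVector converged(L);

  std::vector<double> beta(p), betaOld(p);
  for (int l = 0; l < p; ++l) beta[l] = betaInit[l];

  std::vector<double> eta(n), e(n), vden(p);
  CoxWork wk;

  auto computeEta = [&](const std::vector<double>& b) {
    for (int j = 0; j < n; ++j) eta[j] = 0.0;
    for (int l = 0; l < p; ++l) {
      const double bl = b[l];
      if (bl != 0.0)
        for (int j = 0; j < n; ++j) eta[j] += X(j, l) * bl;
    }
  };

  // one coordinate-descent sweep over the given feature indices; returns the
  // largest absolute coefficient change
  auto sweep = [&](const std::vector<int>& idx, double lambda) {
    double maxd = 0.0;
    const double* u = wk.u.data();
    const double* w = wk.w.data();
    for (int l : idx) {
      if (vden[l] <= 0.0) continue;  // all-zero weights and no ridge
      const double* x = &X(0, l);
      double num = 0.0;
      for (int j = 0; j < n; ++j)
        num += x[j] * (u[j] - w[j] * e[j]);
      num += beta[l] * (vden[l] - 2.0 * lambda2);
      const double bnew = soft(num, lambda) / vden[l];
      const double d = bnew - beta[l];
      if (d != 0.0) {
        for (int j = 0; j < n; ++j) e[j] += x[j] * d;
        beta[l] = bnew;
        const double ad = std::fabs(d);
        if (ad > maxd) maxd = ad;
      }
    }
    return maxd;
  };

  auto kktResidual = [&](double lambda) {
    double viol = 0.0;
    const double* u = wk.u.data();
    for (int l = 0; l < p; ++l) {
      const double* x = &X(0, l);
      double g = 0.0;
      for (int j = 0; j < n; ++j) g -= x[j] * u[j];
      double v;
      if (beta[l] != 0.0) {
        v = std::fabs(g + 2.0 * lambda2 * beta[l] +
                      (beta[l] > 0 ? lambda : -lambda));
      } else {
        v = std::fabs(g) - lambda;
        if (v < 0.0) v = 0.0;
      }
      if (v > viol) viol = v;
    }
    return viol;
  };

  auto penalty = [&](const std::vector<double>& b, double lambda) {
    double s = 0.0;
    for (int l = 0; l < p; ++l)
      s += lambda * std::fabs(b[l]) + lambda2 * b[l] * b[l];
    return s;
  };

  // per-feature gradient of -logPL at the current working quantities
  auto gradAt = [&](int l) {
    const double* x = &X(0, l);
    const double* u = wk.u.data();
    double g = 0.0;
    for (int j = 0; j < n; ++j) g -= x[j] * u[j];
    return g;
  };

  std::vector<bool> everActive(p, false);
  for (int l = 0; l < p; ++l) if (beta[l] != 0.0) everActive[l] = true;

  for (int li = 0; li < L; ++li) {
    const double lambda = lambdas[li];
    const double lambdaPrev = (li > 0) ? lambdas[li - 1] : lambda;
    bool ok = false;

    computeEta(beta);
    cox_quantities(eta, isEvent, grpFirst, grpD, nGrpLE, wk);
    double fCur = wk.nloglik + penalty(beta, lambda);

    // sequential strong rule on the warm-start gradient, plus the ever-active
    // set; violators of the full KKT check are swept back in below
    std::vector<bool> inS(p, false);
    const double strongCut = 2.0 * lambda - lambdaPrev;
    for (int l = 0; l < p; ++l)
      if (everActive[l] || std::fabs(gradAt(l)) >= strongCut) inS[l] = true;

    for (int round = 0; round < 5 && !ok; ++round) {
      std::vector<int> idxS;
      idxS.reserve(p);
      for (int l = 0; l < p; ++l) if (inS[l]) idxS.push_back(l);

      double bestViol = R_PosInf;
      int stall = 0;
      for (int outer = 0; outer < maxOuter; ++outer) {
        // KKT residual restricted to the screened set
        double viol = 0.0;
        for (int l : idxS) {
          const double g = gradAt(l);
          double v;
          if (beta[l] != 0.0)
            v = std::fabs(g + 2.0 * lambda2 * beta[l] +
                          (beta[l] > 0 ? lambda : -lambda));
          else {
            v = std::fabs(g) - lambda;
            if (v < 0.0) v = 0.0;
          }
          if (v > viol) viol = v;
        }
        if (viol <= tolKKT) break;
        if (viol < bestViol) { bestViol = viol; stall = 0; }
        else if (++stall >= 4) break;  // residual stagnating under the caps

        for (int l : idxS) {
          const double* x = &X(0, l);
          double s = 0.0;
          for (int j = 0; j < n; ++j) s += wk.w[j] * x[j] * x[j];
          vden[l] = s + 2.0 * lambda2;
        }
        betaOld = beta;
        std::fill(e.begin(), e.end(), 0.0);

        // solve the quadratic on the screened set, loosely at first
        const double tolEff = std::max(tolInner, viol * 1e-4);
        int sweeps = 0;
        while (sweeps < maxInner) {
          const double dFull = sweep(idxS, lambda);
          ++sweeps;
          if (dFull < tolEff) break;
          std::vector<int> act;
          act.reserve(idxS.size());
          for (int l : idxS) if (beta[l] != 0.0) act.push_back(l);
          while (sweeps < maxInner) {
            const double d = sweep(act, lambda);
            ++sweeps;
            if (d < tolEff) break;
          }
        }

        // objective-decrease safeguard: halve the step if the quadratic
        // model overshot the true objective
        computeEta(beta);
        cox_quantities(eta, isEvent, grpFirst, grpD, nGrpLE, wk);
        double fNew = wk.nloglik + penalty(beta, lambda);
        for (int half = 0; half < 12 && fNew > fCur + 1e-12; ++half) {
          for (int l = 0; l < p; ++l)
            beta[l] = 0.5 * (beta[l] + betaOld[l]);
          computeEta(beta);
          cox_quantities(eta, isEvent, grpFirst, grpD, nGrpLE, wk);
          fNew = wk.nloglik + penalty(beta, lambda);
        }
        fCur = fNew;
      }

      // full KKT check; screened-out violators re-enter
      const double viol = kktResidual(lambda);
      if (viol <= tolKKT) { ok = true; break; }
      bool added = false;
      for (int l = 0; l < p; ++l) {
        if (!inS[l] && std::fabs(gradAt(l)) > lambda + tolKKT) {
          inS[l] = true;
          added = true;
        }
      }
      if (!added) break;  // residual is within the screened set; caps hit
    }

    for (int l = 0; l < p; ++l) {
      betaPath(l, li) = beta[l];
      if (beta[l] != 0.0) everActive[l] = true;
    }
    nll[li] = wk.nloglik;
    converged[li] = ok;
  }

  return List::create(_["beta"] = betaPath, _["nloglik"] = nll,
                      _["converged"] = converged);
}

// Exact negative log partial likelihood and gradient (Breslow ties), used by
// the R front end; shares the risk-set bookkeeping above.
// [[Rcpp::export(name = ".cox_nll_grad")]]
List cox_nll_grad(NumericMatrix X, NumericVector beta, IntegerVector isEvent,
                  IntegerVector grpFirst, IntegerVector grpD,
                  IntegerVector nGrpLE) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int l = 0; l < p; ++l) s += X(j, l) * beta[l];
    eta[j] = s;
  }
  CoxWork wk;
  cox_quantities(eta, isEvent, grpFirst, grpD, nGrpLE, wk);
  NumericVector grad(p);
  for (int l = 0; l < p; ++l) {
    double g = 0.0;
    for (int j = 0; j < n; ++j) g -= X(j, l) * wk.u[j];
    grad[l] = g;
  }
  return List::create(_["value"] = wk.nloglik, _["gradient"] = grad);
}
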