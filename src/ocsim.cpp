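// Compiled core for the receding-horizon optimal-control simulations.
// The two-link arm + second-order muscle dynamics, an RK4 one-step flow,
// central finite-difference linearizations, an iterative LQR (iLQR) solver in
// regulator form, and the closed loop (controller + delay-aware estimator +
// plant) live here because a single study-scale analysis needs on the order of
// 10^4 closed-loop simulations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Plant {
  double d1, d2, d3;          // inertia constants (kg m^2)
  double l1, l2;              // link lengths (m)
  double nu, g1, g2;          // muscle time constant (s) and gains (N m)
  double D00, D01, D10, D11;  // hand-space force-field matrix (N s/m)
  bool field;
};

Plant makePlant(const arma::vec& par, const arma::mat& D) {
  Plant P;
  P.d1 = par(0); P.d2 = par(1); P.d3 = par(2);
  P.nu = par(3); P.g1 = par(4); P.g2 = par(5);
  P.l1 = par(6); P.l2 = par(7);
  P.D00 = D(0, 0); P.D01 = D(0, 1); P.D10 = D(1, 0); P.D11 = D(1, 1);
  P.field = (std::fabs(P.D00) + std::fabs(P.D01) +
             std::fabs(P.D10) + std::fabs(P.D11)) > 0.0;
  return P;
}

// Full-state derivative: X = [th1, th2, w1, w2, a1, a2, e1, e2].
inline void dyn(const Plant& P, const double* X, const double* u, double* dX) {
  const double th1 = X[0], th2 = X[1], w1 = X[2], w2 = X[3];
  const double a1 = X[4], a2 = X[5], e1 = X[6], e2 = X[7];
  const double c2 = std::cos(th2), s2 = std::sin(th2);
  const double M11 = P.d1 + 2.0 * P.d2 * c2;
  const double M12 = P.d3 + P.d2 * c2;
  const double M22 = P.d3;
  const double C1 = P.d2 * (2.0 * w1 * w2 + w2 * w2) * s2;
  const double C2 = -P.d2 * w1 * w1 * s2;
  double t1 = P.g1 * a1 - C1;
  double t2 = P.g2 * a2 - C2;
  if (P.field) {
    const double s1 = std::sin(th1), c1 = std::cos(th1);
    const double s12 = std::sin(th1 + th2), c12 = std::cos(th1 + th2);
    const double J11 = -P.l1 * s1 - P.l2 * s12, J12 = -P.l2 * s12;
    const double J21 = P.l1 * c1 + P.l2 * c12, J22 = P.l2 * c12;
    const double vx = J11 * w1 + J12 * w2, vy = J21 * w1 + J22 * w2;
    const double fx = P.D00 * vx + P.D01 * vy;
    const double fy = P.D10 * vx + P.D11 * vy;
    t1 += J11 * fx + J21 * fy;
    t2 += J12 * fx + J22 * fy;
  }
  const double det = M11 * M22 - M12 * M12;
  dX[0] = w1;
  dX[1] = w2;
  dX[2] = (M22 * t1 - M12 * t2) / det;
  dX[3] = (-M12 * t1 + M11 * t2) / det;
  dX[4] = (-a1 + e1) / P.nu;
  dX[5] = (-a2 + e2) / P.nu;
  dX[6] = (-e1 + u[0]) / P.nu;
  dX[7] = (-e2 + u[1]) / P.nu;
}

// Fixed-step RK4 flow over h (split into nsub substeps), zero-order-hold u.
inline void rk4(const Plant& P, const double* X, const double* u, double h,
                int nsub, double* out) {
  double x[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  std::copy(X, X + 8, x);
  const double hs = h / nsub;
  for (int s = 0; s < nsub; ++s) {
    dyn(P, x, u, k1);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + 0.5 * hs * k1[i];
    dyn(P, tmp, u, k2);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + 0.5 * hs * k2[i];
    dyn(P, tmp, u, k3);
    for (int i = 0; i < 8; ++i) tmp[i] = x[i] + hs * k3[i];
    dyn(P, tmp, u, k4);
    for (int i = 0; i < 8; ++i)
      x[i] += hs / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
  std::copy(x, x + 8, out);
}

// Central finite differences of the one-step flow: A_d (8x8), B_d (8x2).
void linDiscrete(const Plant& P, const double* X, const double* u, double dt,
                 arma::mat& A, arma::mat& B) {
  double xp[8], xm[8], fp[8], fm[8], uu[2];
  const double h = 1e-5;
  for (int j = 0; j < 8; ++j) {
    std::copy(X, X + 8, xp);
    std::copy(X, X + 8, xm);
    xp[j] += h; xm[j] -= h;
    rk4(P, xp, u, dt, 1, fp);
    rk4(P, xm, u, dt, 1, fm);
    for (int i = 0; i < 8; ++i) A(i, j) = (fp[i] - fm[i]) / (2.0 * h);
  }
  for (int j = 0; j < 2; ++j) {
    uu[0] = u[0]; uu[1] = u[1];
    uu[j] += h;
    rk4(P, X, uu, dt, 1, fp);
    uu[j] -= 2.0 * h;
    rk4(P, X, uu, dt, 1, fm);
    for (int i = 0; i < 8; ++i) B(i, j) = (fp[i] - fm[i]) / (2.0 * h);
  }
}

// Central finite differences of the continuous derivative field dX/dt.
void linContinuous(const Plant& P, const double* X, const double* u,
                   arma::mat& A) {
  double xp[8], xm[8], fp[8], fm[8];
  const double h = 1e-6;
  for (int j = 0; j < 8; ++j) {
    std::copy(X, X + 8, xp);
    std::copy(X, X + 8, xm);
    xp[j] += h; xm[j] -= h;
    dyn(P, xp, u, fp);
    dyn(P, xm, u, fm);
    for (int i = 0; i < 8; ++i) A(i, j) = (fp[i] - fm[i]) / (2.0 * h);
  }
}

inline void handPos(const Plant& P, const double* X, double* xy) {
  xy[0] = P.l1 * std::cos(X[0]) + P.l2 * std::cos(X[0] + X[1]);
  xy[1] = P.l1 * std::sin(X[0]) + P.l2 * std::sin(X[0] + X[1]);
}

// state-cost schedule within one horizon: quadratic penalties
// (x_i - goal_j)' diag(w_j) (x_i - goal_j) applied at specific steps
struct CostSchedule {
  std::vector<int> step;        // horizon step index (1..N)
  std::vector<arma::vec> goal;  // 8-vectors
  std::vector<arma::vec> w;     // 8-vectors of weights
};

double rolloutCost(const Plant& P, const arma::vec& x0, const arma::mat& U,
                   double dt, const CostSchedule& cs, double wu,
                   arma::mat& X) {
  const int N = U.n_cols;
  double cost = 0.0;
  X.col(0) = x0;
  for (int i = 0; i < N; ++i) {
    const double* u = U.colptr(i);
    cost += wu * (u[0] * u[0] + u[1] * u[1]) * dt;
    rk4(P, X.colptr(i), u, dt, 1, X.colptr(i + 1));
  }
  for (size_t j = 0; j < cs.step.size(); ++j) {
    arma::vec e = X.col(cs.step[j]) - cs.goal[j];
    cost += arma::dot(e, cs.w[j] % e);
  }
  return cost;
}

struct IlqrResult {
  arma::mat X;   // 8 x (N+1)
  arma::mat U;   // 2 x N
  arma::cube K;  // 2 x 8 x N feedback gains
  double cost;
  int iters;
  bool converged;
};

IlqrResult ilqrCore(const Plant& P, const arma::vec& x0,
                    const CostSchedule& cs, double wu, int N, double dt,
                    arma::mat U, int maxit, double tol) {
  arma::mat X(8, N + 1), Xtry(8, N + 1), Utry(2, N);
  double cost = rolloutCost(P, x0, U, dt, cs, wu, X);
  std::vector<arma::mat> A(N, arma::mat(8, 8)), B(N, arma::mat(8, 2));
  arma::mat kff(2, N);
  arma::cube K(2, 8, N, arma::fill::zeros);
  double lambda = 1e-6;
  bool converged = false;
  int iter = 0;
  while (iter < maxit) {
    ++iter;
    for (int i = 0; i < N; ++i)
      linDiscrete(P, X.colptr(i), U.colptr(i), dt, A[i], B[i]);
    // state-cost gradient/Hessian per horizon step at the current nominal
    arma::mat lx(8, N + 1, arma::fill::zeros);
    arma::mat lxx(8, N + 1, arma::fill::zeros);  // diagonal entries
    for (size_t j = 0; j < cs.step.size(); ++j) {
      const int s = cs.step[j];
      lx.col(s) += 2.0 * (cs.w[j] % (X.col(s) - cs.goal[j]));
      lxx.col(s) += 2.0 * cs.w[j];
    }
    bool accepted = false;
    while (!accepted && lambda < 1e9) {
      // backward pass
      arma::vec Vx = lx.col(N);
      arma::mat Vxx = arma::diagmat(lxx.col(N));
      bool ok = true;
      for (int i = N - 1; i >= 0; --i) {
        arma::vec Qu = 2.0 * wu * dt * U.col(i) + B[i].t() * Vx;
        arma::vec Qx = A[i].t() * Vx;
        arma::mat Qxx = A[i].t() * Vxx * A[i];
        arma::mat Qraw = B[i].t() * Vxx * B[i];
        arma::mat Quu = 0.5 * (Qraw + Qraw.t());
        Quu.diag() += 2.0 * wu * dt + lambda;
        if (!Quu.is_finite()) { ok = false; break; }
        arma::mat Qux = B[i].t() * Vxx * A[i];
        arma::mat Qinv(2, 2);
        if (!arma::inv_sympd(Qinv, Quu)) { ok = false; break; }
        arma::vec kf = -Qinv * Qu;
        arma::mat Ki = -Qinv * Qux;
        kff.col(i) = kf;
        K.slice(i) = Ki;
        Vx = Qx + Ki.t() * Quu * kf + Ki.t() * Qu + Qux.t() * kf;
        Vxx = Qxx + Ki.t() * Quu * Ki + Ki.t() * Qux + Qux.t() * Ki;
        Vxx = 0.5 * (Vxx + Vxx.t());
        Vx += lx.col(i);
        Vxx.diag() += lxx.col(i);
      }
      if (ok) {
        // backtracking line search on the feedforward step
        double alpha = 1.0;
        for (int ls = 0; ls < 11; ++ls, alpha *= 0.5) {
          Xtry.col(0) = x0;
          double ctry = 0.0;
          for (int i = 0; i < N; ++i) {
            arma::vec du = alpha * kff.col(i) +
                           K.slice(i) * (Xtry.col(i) - X.col(i));
            Utry.col(i) = U.col(i) + du;
            const double* u = Utry.colptr(i);
            ctry += wu * (u[0] * u[0] + u[1] * u[1]) * dt;
            rk4(P, Xtry.colptr(i), u, dt, 1, Xtry.colptr(i + 1));
          }
          for (size_t j = 0; j < cs.step.size(); ++j) {
            arma::vec e = Xtry.col(cs.step[j]) - cs.goal[j];
            ctry += arma::dot(e, cs.w[j] % e);
          }
          if (std::isfinite(ctry) && ctry < cost) {
            const double rel = (cost - ctry) / std::max(1.0, std::fabs(cost));
            X = Xtry; U = Utry; cost = ctry;
            accepted = true;
            lambda = std::max(lambda * 0.5, 1e-9);
            if (rel < tol) converged = true;
            break;
          }
        }
      }
      if (!accepted) lambda *= 10.0;
    }
    if (!accepted) {  // regularization exhausted: keep best-so-far
      break;
    }
    if (converged) break;
  }
  // a fixed point of the accepted iteration also counts as converged
  if (!converged && iter < maxit) converged = true;
  IlqrResult out;
  out.X = X; out.U = U; out.K = K;
  out.cost = cost; out.iters = iter; out.converged = converged;
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".armDynamicsCpp")]]
arma::vec armDynamicsCpp(const arma::vec& X, const arma::vec& u,
                         const arma::vec& par, const arma::mat& D) {
  Plant P = makePlant(par, D);
  arma::vec dX(8);
  dyn(P, X.memptr(), u.memptr(), dX.memptr());
  return dX;
}

// [[Rcpp::export(name = ".stepDynamicsCpp")]]
arma::vec stepDynamicsCpp(const arma::vec& X, const arma::vec& u,
                          const arma::vec& par, const arma::mat& D,
                          double dt, int substeps) {
  Plant P = makePlant(par, D);
  arma::vec out(8);
  rk4(P, X.memptr(), u.memptr(), dt, substeps, out.memptr());
  return out;
}

// [[Rcpp::export(name = ".linearizeCpp")]]
List linearizeCpp(const arma::vec& X, const arma::vec& u, const arma::vec& par,
                  const arma::mat& D, double dt) {
  Plant P = makePlant(par, D);
  arma::mat A(8, 8), B(8, 2);
  linDiscrete(P, X.memptr(), u.memptr(), dt, A, B);
  return List::create(_["A"] = A, _["B"] = B);
}

// [[Rcpp::export(name = ".contJacobianCpp")]]
arma::mat contJacobianCpp(const arma::vec& X, const arma::vec& u,
                          const arma::vec& par, const arma::mat& D) {
  Plant P = makePlant(par, D);
  arma::mat A(8, 8);
  linContinuous(P, X.memptr(), u.memptr(), A);
  return A;
}

// [[Rcpp::export(name = ".ilqrCpp")]]
List ilqrCpp(const arma::vec& x0, const arma::vec& goal, const arma::vec& w,
             double wu, int N, double dt, const arma::vec& par,
             const arma::mat& D, const arma::mat& Uinit, int maxit,
             double tol) {
  Plant P = makePlant(par, D);
  CostSchedule cs;
  cs.step.push_back(N);
  cs.goal.push_back(goal);
  cs.w.push_back(w);
  IlqrResult r = ilqrCore(P, x0, cs, wu, N, dt, Uinit, maxit, tol);
  return List::create(_["X"] = r.X, _["U"] = r.U, _["K"] = r.K,
                      _["cost"] = r.cost, _["iters"] = r.iters,
                      _["converged"] = r.converged);
}

// Closed loop: at every control step, estimate the state (perfect / literal
// delayed innovation / delay-compensated), re-solve iLQR toward the scheduled
// goals with the controller's internal model, apply the first control to the
// plant.
// estMode: 0 = perfect state feedback, 1 = literal delayed innovation,
//          2 = delay-compensated (lagged filter + forward prediction).
// scheduleMode: 0 = fixed arrival deadlines (goal designated at j*T_G is due
//               at j*T_G + T_H; all pending deadlines inside the horizon are
//               penalized; the final goal keeps a receding horizon-end cost
//               once designated), 1 = single current goal at the horizon end.
// [[Rcpp::export(name = ".closedLoopCpp")]]
List closedLoopCpp(const arma::vec& x0, const arma::mat& goals,
                   const arma::vec& wVia, const arma::vec& wFinal, double wu,
                   int stepsPerGoal, int NH, double dt, int nSteps,
                   const arma::vec& par, const arma::mat& Dplant,
                   const arma::mat& Dctrl, const arma::mat& Dest, int estMode,
                   int delaySteps, const arma::vec& omegaW,
                   const arma::vec& omegaXi, int replanEvery, int maxit,
                   double tol, int plantSubsteps, int scheduleMode) {
  const Plant Pplant = makePlant(par, Dplant);
  const Plant Pctrl = makePlant(par, Dctrl);
  const Plant Pest = makePlant(par, Dest);
  const int nGoals = goals.n_cols;

  arma::mat Xtrue(8, nSteps + 1), Xhat(8, nSteps + 1), U(2, nSteps);
  arma::mat ybuf(4, nSteps, arma::fill::zeros);
  Xtrue.col(0) = x0;

  // hand path at plant substep resolution
  const int nRec = nSteps * plantSubsteps + 1;
  arma::vec recX(nRec), recY(nRec), recT(nRec);
  double xy[2];
  handPos(Pplant, x0.memptr(), xy);
  recX(0) = xy[0]; recY(0) = xy[1]; recT(0) = 0.0;

  // estimator state
  arma::vec xhatLit = x0;          // literal mode running estimate
  arma::vec xlag = x0;             // delay-compensated lagged filter
  arma::mat Pcov = arma::diagmat(omegaXi);
  arma::mat Plag = arma::diagmat(omegaXi);
  const arma::mat Ww = arma::diagmat(omegaW);
  const arma::mat Wxi = arma::diagmat(omegaXi);

  arma::mat Uws(2, NH, arma::fill::zeros);  // warm start
  arma::mat Ucur(2, NH, arma::fill::zeros);
  int lastReplan = -1;
  int totalIters = 0, nNotConverged = 0;
  arma::ivec goalIdx(nSteps);
  const double u0[2] = {0.0, 0.0};

  for (int k = 0; k < nSteps; ++k) {
    // observation of the true state (noise-free simulations)
    ybuf.col(k) = Xtrue.submat(0, k, 3, k);

    // ---- state estimate at step k ----
    arma::vec xhat(8);
    if (estMode == 0) {
      xhat = Xtrue.col(k);
    } else if (estMode == 1) {
      xhat = xhatLit;
    } else {
      // one lagged-filter update per control step; during the first Delta
      // the primed resting history drives it (zero innovation), so the
      // gain/covariance recursion runs from t = 0
      if (k >= 1) {
        const int jsrc = k - 1 - delaySteps;
        const double uZero[2] = {0.0, 0.0};
        const double* usrc = (jsrc >= 0) ? U.colptr(jsrc) : uZero;
        arma::vec ysrc = (jsrc >= 0) ? arma::vec(ybuf.col(jsrc))
                                     : arma::vec(x0.subvec(0, 3));
        arma::mat A(8, 8), Bdum(8, 2);
        linDiscrete(Pest, xlag.memptr(), usrc, dt, A, Bdum);
        arma::mat PH = Plag.cols(0, 3);           // P H^T
        arma::mat S = PH.rows(0, 3) + Ww;         // H P H^T + Omega_w
        arma::mat Kg = A * PH * arma::inv(S);     // 8 x 4
        arma::vec innov = ysrc - xlag.subvec(0, 3);
        arma::vec xnew(8);
        rk4(Pest, xlag.memptr(), usrc, dt, 1, xnew.memptr());
        xlag = xnew + Kg * innov;
        arma::mat AmKH = A;
        AmKH.cols(0, 3) -= Kg;
        Plag = Wxi + AmKH * Plag * A.t();
        Plag = 0.5 * (Plag + Plag.t());
      }
      xhat = xlag;
      for (int j = std::max(k - delaySteps, 0); j < k; ++j) {
        arma::vec xnew(8);
        rk4(Pest, xhat.memptr(), U.colptr(j), dt, 1, xnew.memptr());
        xhat = xnew;
      }
    }
    Xhat.col(k) = xhat;

    // ---- receding-horizon replanning ----
    const int gi = std::min(k / stepsPerGoal, nGoals - 1);
    goalIdx(k) = gi;
    if (lastReplan < 0 || (k - lastReplan) >= replanEvery) {
      CostSchedule cs;
      int Nk = NH;
      if (scheduleMode == 1) {
        // single current goal, penalized at the horizon end (receding)
        cs.step.push_back(NH);
        cs.goal.push_back(goals.col(gi));
        cs.w.push_back((gi < nGoals - 1) ? wVia : wFinal);
      } else if (scheduleMode == 2) {
        // single current goal, arrival fixed at designation + T_H
        // (contracting horizon); the final goal recedes (flexible time)
        if (gi < nGoals - 1)
          Nk = std::max(gi * stepsPerGoal + NH - k, 1);
        cs.step.push_back(Nk);
        cs.goal.push_back(goals.col(gi));
        cs.w.push_back((gi < nGoals - 1) ? wVia : wFinal);
      } else {
        // fixed arrival deadlines: goal j due at step j*stepsPerGoal + NH
        for (int j = 0; j < nGoals - 1; ++j) {
          const int i = j * stepsPerGoal + NH - k;
          if (i >= 1 && i <= NH) {
            cs.step.push_back(i);
            cs.goal.push_back(goals.col(j));
            cs.w.push_back(wVia);
          }
        }
        if (k >= (nGoals - 1) * stepsPerGoal) {
          // final goal designated: receding horizon-end cost (flexible time)
          cs.step.push_back(NH);
          cs.goal.push_back(goals.col(nGoals - 1));
          cs.w.push_back(wFinal);
        }
      }
      if (cs.step.empty()) {  // cannot happen with NH > stepsPerGoal
        cs.step.push_back(NH);
        cs.goal.push_back(goals.col(nGoals - 1));
        cs.w.push_back(wFinal);
      }
      IlqrResult r = ilqrCore(Pctrl, xhat, cs, wu, Nk, dt,
                              Uws.cols(0, Nk - 1), maxit, tol);
      totalIters += r.iters;
      if (!r.converged) ++nNotConverged;
      Ucur.zeros();
      Ucur.cols(0, Nk - 1) = r.U;
      lastReplan = k;
      // shift warm start by one control step for the next solve
      Uws.zeros();
      if (Nk > 1) Uws.cols(0, Nk - 2) = r.U.cols(1, Nk - 1);
      Uws.col(std::max(Nk - 1, 0)) = r.U.col(Nk - 1);
    }
    const int off = std::min(k - lastReplan, NH - 1);
    U.col(k) = Ucur.col(off);

    // ---- advance the true plant (with optional substeps for recording) ----
    arma::vec xk = Xtrue.col(k);
    for (int s = 0; s < plantSubsteps; ++s) {
      arma::vec xn(8);
      rk4(Pplant, xk.memptr(), U.colptr(k), dt / plantSubsteps, 1,
          xn.memptr());
      xk = xn;
      handPos(Pplant, xk.memptr(), xy);
      const int idx = k * plantSubsteps + s + 1;
      recX(idx) = xy[0]; recY(idx) = xy[1];
      recT(idx) = (k + (s + 1.0) / plantSubsteps) * dt;
    }
    Xtrue.col(k + 1) = xk;

    // ---- advance the literal-mode estimator ----
    if (estMode == 1) {
      arma::mat A(8, 8), Bdum(8, 2);
      linDiscrete(Pest, xhatLit.memptr(), U.colptr(k), dt, A, Bdum);
      arma::mat PH = Pcov.cols(0, 3);
      arma::mat S = PH.rows(0, 3) + Ww;
      arma::mat Kg = A * PH * arma::inv(S);
      const int kd = k - delaySteps;
      arma::vec ydel = (kd >= 0) ? ybuf.col(kd)
                                 : arma::vec(x0.subvec(0, 3));
      arma::vec innov = ydel - xhatLit.subvec(0, 3);
      arma::vec xnew(8);
      rk4(Pest, xhatLit.memptr(), U.colptr(k), dt, 1, xnew.memptr());
      xhatLit = xnew + Kg * innov;
      arma::mat AmKH = A;
      AmKH.cols(0, 3) -= Kg;
      Pcov = Wxi + AmKH * Pcov * A.t();
      Pcov = 0.5 * (Pcov + Pcov.t());
      if (!Pcov.is_finite())
        stop("estimator covariance became non-finite at step %d", k);
    }
    (void)u0;
  }
  // final estimate column (propagate once more for completeness)
  Xhat.col(nSteps) = (estMode == 0) ? Xtrue.col(nSteps) : Xhat.col(nSteps - 1);

  arma::vec tgrid = arma::regspace(0, nSteps) * dt;
  return List::create(
      _["t"] = tgrid, _["X"] = Xtrue.t(), _["Xhat"] = Xhat.t(),
      _["U"] = U.t(), _["goalIndex"] = goalIdx,
      _["handT"] = recT, _["handX"] = recX, _["handY"] = recY,
      _["ilqrIters"] = totalIters, _["notConverged"] = nNotConverged);
}
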