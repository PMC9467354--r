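test_that("muscle model equilibrium, ordering and gain", {
  p <- armParams(g_sh = 2, g_el = 1)
  st <- muscleStep(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), p, 0.01)
  expect_equal(st$alpha, c(0.5, 0.5))
  expect_equal(st$epsilon, c(0.5, 0.5))
  expect_equal(muscleStep(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5), p)$tau,
               c(1.0, 0.5))

  # a step input excites epsilon before alpha (second-order cascade)
  st <- muscleStep(c(0, 0), c(0, 0), c(1, 1), p, 0.01)
  expect_gt(st$epsilon[1], st$alpha[1])
  expect_gt(st$alpha[1], 0)
})

test_that("assembled dynamics stack the arm over the muscles", {
  p <- armParams()
  F0 <- assembleDynamics("F0", p)
  Fphi <- assembleDynamics("Fphi", p, fieldSpec(2, 90))
  rest <- c(deg2rad(c(45, 90)), rep(0, 6))
  expect_equal(F0(rest, c(0, 0)), rep(0, 8))

  X <- c(deg2rad(c(50, 80)), 0.8, -0.3, 0.1, 0.05, 0.2, 0)
  u <- c(0.3, -0.1)
  dd <- Fphi(X, u) - F0(X, u)
  expect_equal(dd[c(1, 2, 5, 6, 7, 8)], rep(0, 6))
  Minv_tau <- solve(inertiaMatrix(X[1:2], p),
                    fieldTorque(X[1:2], X[3:4], fieldSpec(2, 90), p))
  expect_equal(dd[3:4], drop(Minv_tau), tolerance = 1e-10)

  Fzero <- assembleDynamics("Fphi", p, fieldSpec(0, 90))
  expect_equal(Fzero(X, u), F0(X, u))
})

test_that("discrete linearization is accurate and exact on the muscle block", {
  p <- armParams()
  F0 <- assembleDynamics("F0", p)
  X <- c(deg2rad(c(45, 90)), 0.5, -0.2, 0.1, 0, 0.05, 0.1)
  lin <- linearizeDynamics(F0, X, c(0.2, 0.1), 0.01)

  # muscle sub-block: closed-form matrix exponential of the lag cascade
  e <- exp(-0.01 / p$nu)
  for (j in 1:2) {
    idx <- c(4 + j, 6 + j)
    expect_equal(lin$A[idx, idx],
                 matrix(c(e, 0, 0.01 / p$nu * e, e), 2, 2),
                 tolerance = 2e-4)  # RK4 flow vs exact exponential
    expect_equal(lin$A[idx, setdiff(5:8, idx)], matrix(0, 2, 2),
                 tolerance = 1e-9)
  }
  # first-order structure: A = I + delta dF/dX + O(delta^2)
  h <- 1e-6
  Acont <- reachadapt:::.contJacobianCpp(X, c(0.2, 0.1),
                                         reachadapt:::parVec(p),
                                         reachadapt:::zeroField())
  expect_lt(max(abs(lin$A - (diag(8) + 0.01 * Acont))), 0.05)

  # independent R finite differences of the one-step flow
  par <- reachadapt:::parVec(p)
  D <- reachadapt:::zeroField()
  fd <- sapply(1:8, function(j) {
    dx <- rep(0, 8); dx[j] <- h
    (reachadapt:::.stepDynamicsCpp(X + dx, c(0.2, 0.1), par, D, 0.01, 1L) -
       reachadapt:::.stepDynamicsCpp(X - dx, c(0.2, 0.1), par, D, 0.01, 1L)) /
      (2 * h)
  })
  expect_lt(max(abs(lin$A - fd)), 1e-6)
})

test_that("iLQR reproduces the finite-horizon LQR solution near rest", {
  p <- armParams()
  F0 <- assembleDynamics("F0", p)
  x0 <- c(deg2rad(c(45, 90)), rep(0, 6))
  w <- c(10, 10, 0.1, 0.1, 0.01, 0.01, 0.01, 0.01)
  wu <- 1e-5; dt <- 0.01; N <- 28

  # already at the goal: no control
  pol0 <- ilqrSolve(x0, x0, w, N, F0, wu, dt)
  expect_lt(max(abs(pol0$U)), 1e-6)
  expect_true(pol0$converged)

  # small displacement (so the plant is effectively linear): discrete
  # Riccati recursion as an independent oracle
  goal <- x0 + c(1e-4, 1e-4, rep(0, 6))
  lin <- linearizeDynamics(F0, x0, c(0, 0), dt)
  A <- lin$A; B <- lin$B
  P <- diag(w); r <- -diag(w) %*% (goal - x0)
  Ks <- vector("list", N); ks <- vector("list", N)
  for (i in N:1) {
    Quu <- wu * dt * diag(2) + t(B) %*% P %*% B
    Ki <- -solve(Quu, t(B) %*% P %*% A)
    ki <- -solve(Quu, t(B) %*% r)
    Ks[[i]] <- Ki; ks[[i]] <- ki
    P2 <- t(A) %*% P %*% (A + B %*% Ki)
    r2 <- t(A + B %*% Ki) %*% r
    P <- (P2 + t(P2)) / 2; r <- r2
  }
  z <- rep(0, 8); cost <- 0
  Xlqr <- matrix(0, 8, N + 1); Ulqr <- matrix(0, 2, N)
  for (i in 1:N) {
    u <- drop(Ks[[i]] %*% z + ks[[i]])
    cost <- cost + wu * sum(u^2) * dt
    z <- drop(A %*% z + B %*% u)
    Ulqr[, i] <- u
    Xlqr[, i + 1] <- z
  }
  cost <- cost + sum(diag(w) %*% (z - (goal - x0))^2)

  pol <- ilqrSolve(x0, goal, w, N, F0, wu, dt)
  expect_true(pol$converged)
  expect_equal(pol$cost, cost, tolerance = 1e-3)
  expect_lt(max(abs(t(pol$X) - (Xlqr + x0))), 1e-6)

  # a perturbed warm start converges to the same cost and endpoint (the
  # cheap-control objective is nearly flat along some control directions,
  # so intermediate states are not unique to high precision)
  set.seed(3)
  pol2 <- ilqrSolve(x0, goal, w, N, F0, wu, dt,
                    Uinit = matrix(rnorm(2 * N, sd = 0.01), 2, N))
  expect_equal(pol2$cost, pol$cost, tolerance = 1e-6)
  expect_lt(max(abs(pol2$X[N + 1, ] - pol$X[N + 1, ])), 1e-4)
})

test_that("baseline closed loop reaches the target inside the speed window", {
  r <- fx("loop_baseline", function()
    runClosedLoop(viaPointSeries(), ofcParams()))
  tr <- r$trial
  endErr <- sqrt(sum((c(tail(tr$x, 1), tail(tr$y, 1)) -
                        attr(tr, "target"))^2))
  expect_lt(endErr, 0.005)
  pr <- processTrial(tr)
  expect_gte(max(pr$speed), 0.25)
  expect_lte(max(pr$speed), 0.35)
  expect_equal(r$notConverged, 0)

  # goal switching exactly at T_G, 2 T_G, 3 T_G
  expect_equal(which(diff(r$goalIndex) != 0), c(13, 26, 39))

  # determinism: bit-identical repetition
  r2 <- runClosedLoop(viaPointSeries(), ofcParams())
  expect_identical(r$states, r2$states)
  expect_identical(r$controls, r2$controls)
})

test_that("the horizon persists past the last switch (time flexibility)", {
  tr <- fxCondition("reoptimization", "before_effect", phi = 2)
  endErr <- sqrt(sum((c(tail(tr$x, 1), tail(tr$y, 1)) -
                        attr(tr, "target"))^2))
  expect_lt(endErr, 0.01)
})

test_that("position-only via constraints give the lowest jerk content", {
  jf <- function(boundary) {
    r <- runClosedLoop(viaPointSeries(), ofcParams(boundary = boundary))
    pr <- processTrial(r$trial)
    jerk <- sqrt(pr$jx^2 + pr$jy^2)
    mean(jerk[pr$t < 0.6])
  }
  jP <- jf("p")
  jOthers <- c(jf("pv"), jf("pva"), jf("pvae"))
  expect_true(all(jP < jOthers))
})
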