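test_that("noise covariances follow the printed diagonal patterns", {
  ns <- noiseSpec(2, 3, units = "rad")
  expect_equal(diag(ns$Omega_w), 2 * c(1, 1, 10, 10))
  expect_equal(diag(ns$Omega_xi), 3 * c(1, 1, 10, 10, 100, 100, 1000, 1000))
  expect_true(all(ns$Omega_w[upper.tri(ns$Omega_w)] == 0))

  nd <- noiseSpec(2, 3, units = "deg")
  sc <- (pi / 180)^2
  expect_equal(diag(nd$Omega_w), 2 * sc * c(1, 1, 10, 10))
  expect_equal(diag(nd$Omega_xi)[5:8], 3 * c(100, 100, 1000, 1000))

  expect_error(noiseSpec(0), "sigma_w")
  expect_error(noiseSpec(1, -1), "sigma_xi")
})

test_that("observations read position and velocity, optionally with noise", {
  X <- c(0.7, 1.5, 0.2, -0.1, 0.3, 0.1, 0, 0)
  expect_equal(observeState(X), X[1:4])

  ns <- noiseSpec(1, 1, units = "rad")
  set.seed(123)
  draws <- t(replicate(1e5, observeState(X, ns)))
  sampVar <- apply(draws, 2, var)
  expect_equal(sampVar, diag(ns$Omega_w), tolerance = 0.05)
  expect_equal(colMeans(draws), X[1:4], tolerance = 0.05)
})

test_that("delay buffers are primed with the resting history", {
  F0 <- assembleDynamics("F0")
  x0 <- c(deg2rad(c(45, 90)), rep(0, 6))
  est <- estimatorInit(x0, F0, delay = 0.12, delta = 0.01)
  expect_equal(ncol(est$ybuf), 12)
  expect_equal(ncol(est$ubuf), 12)
  # at rest the innovation vanishes and the estimate stays put
  est2 <- estimatorStep(est, c(0, 0), observeState(x0))
  expect_equal(est2$Xhat, x0, tolerance = 1e-12)
})

test_that("with no delay, matched model and no noise the filter tracks", {
  p <- armParams()
  F0 <- assembleDynamics("F0", p)
  x0 <- c(deg2rad(c(45, 90)), rep(0, 6))
  est <- estimatorInit(x0, F0, delay = 0, delta = 0.01)
  X <- x0
  par <- reachadapt:::parVec(p); D <- reachadapt:::zeroField()
  set.seed(8)
  for (k in 1:40) {
    u <- c(0.2, 0.1) * sin(k / 5)
    est <- estimatorStep(est, u, observeState(X))
    X <- as.numeric(reachadapt:::.stepDynamicsCpp(X, u, par, D, 0.01, 1L))
    expect_lt(max(abs(est$Xhat - X)), 1e-8)
  }
})

test_that("huge sensory noise shuts the Kalman gain down", {
  F0 <- assembleDynamics("F0")
  x0 <- c(deg2rad(c(45, 90)), rep(0, 6))
  up <- reachadapt:::kalmanUpdate(x0, noiseSpec(1e6)$Omega_xi, c(0, 0),
                                  attr(F0, "par"), attr(F0, "D"),
                                  noiseSpec(1e6), 0.01)
  upSmall <- reachadapt:::kalmanUpdate(x0, noiseSpec(1)$Omega_xi, c(0, 0),
                                       attr(F0, "par"), attr(F0, "D"),
                                       noiseSpec(1), 0.01)
  expect_lt(norm(up$K, "F"), 1e-3 * norm(upSmall$K, "F"))
})

test_that("steady-state gain grows with the motor-to-sensory noise ratio", {
  F0 <- assembleDynamics("F0")
  x0 <- c(deg2rad(c(45, 90)), rep(0, 6))
  gains <- sapply(c(0.1, 1, 10, 100), function(ratio) {
    ns <- noiseSpec(1, ratio)
    P <- ns$Omega_xi
    for (k in 1:60) {
      up <- reachadapt:::kalmanUpdate(x0, P, c(0, 0), attr(F0, "par"),
                                      attr(F0, "D"), ns, 0.01)
      P <- up$P
    }
    norm(up$K, "F")
  })
  expect_true(all(diff(gains) > 0))
})

test_that("R estimator reproduces the compiled closed-loop estimates", {
  p <- armParams()
  params <- ofcParams()
  S <- viaPointSeries()
  for (mode in c("delay", "literal")) {
    pm <- params; pm$estMode <- mode
    r <- runClosedLoop(S, pm, p, phiPlant = 2)  # before-effect wiring
    Fhat <- assembleDynamics("F0", p)
    est <- estimatorInit(r$states[1, ], Fhat, delay = pm$delay,
                         delta = pm$delta, mode = mode,
                         noise = noiseSpec(pm$sigma_w, pm$sigma_xi,
                                           pm$noiseUnits))
    # the literal mode is dynamically unstable, so rounding differences
    # between the two implementations amplify exponentially; the comparison
    # covers the window where they remain far below the state scale
    kMax <- if (mode == "literal") 25 else 60
    for (k in 1:kMax) {
      est <- estimatorStep(est, r$controls[k, ], r$states[k, 1:4])
      expect_equal(est$Xhat, unname(r$estimates[k + 1, ]),
                   tolerance = 1e-5)
    }
  }
})

test_that("before-effect estimation error peaks before movement end", {
  r <- attr(fxCondition("reoptimization", "before_effect", phi = 2), "loop")
  p <- armParams()
  handErr <- sapply(seq_len(nrow(r$states)), function(i)
    sqrt(sum((forwardKinematics(r$states[i, 1:2], p) -
                forwardKinematics(r$estimates[i, 1:2], p))^2)))
  midIdx <- which.min(abs(r$t - 0.35))
  expect_gt(handErr[midIdx], handErr[length(handErr)])
  expect_gt(max(handErr), 1e-4)  # the model mismatch is visible
})

test_that("covariance stays symmetric with non-negative diagonal", {
  for (est in c(0, 2)) {
    F <- if (est == 0) assembleDynamics("F0")
         else assembleDynamics("Fphi", f = fieldSpec(2, 90))
    ns <- noiseSpec()
    P <- ns$Omega_xi
    x <- c(deg2rad(c(45, 90)), 0.3, -0.2, 0.05, 0.02, 0.05, 0)
    for (k in 1:50) {
      up <- reachadapt:::kalmanUpdate(x, P, c(0.1, 0), attr(F, "par"),
                                      attr(F, "D"), ns, 0.01)
      P <- up$P
      expect_equal(P, t(P))
      expect_true(all(diag(P) >= 0))
    }
  }
})
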