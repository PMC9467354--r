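test_that("inertia matrix matches the closed form and stays SPD", {
  p <- armParams()
  expect_equal(p$d1, 0.169)
  expect_equal(p$d2, 0.0528)
  expect_equal(p$d3, 0.045)

  M90 <- inertiaMatrix(deg2rad(c(45, 90)), p)
  expect_equal(M90, matrix(c(0.169, 0.045, 0.045, 0.045), 2, 2),
               tolerance = 1e-12)

  M0 <- inertiaMatrix(c(0.3, 0), p)
  expect_equal(M0[1, 1], p$d1 + 2 * p$d2)
  expect_equal(M0[1, 2], p$d3 + p$d2)
  expect_equal(M0[2, 2], p$d3)

  for (el in seq(1, 179, by = 1)) {
    M <- inertiaMatrix(deg2rad(c(30, el)), p)
    expect_equal(M[1, 2], M[2, 1])
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("velocity-dependent torques follow the printed formula", {
  p <- armParams()
  expect_equal(coriolisVector(deg2rad(c(45, 90)), c(0, 0), p), c(0, 0))
  expect_equal(coriolisVector(c(1, 0), c(2, 3), p), c(0, 0))
  expect_equal(coriolisVector(deg2rad(c(45, 90)), c(1, 0), p),
               c(0, -0.0528), tolerance = 1e-12)
})

test_that("Jacobian matches hand kinematics by finite differences", {
  p <- armParams()
  expect_equal(armJacobian(deg2rad(c(45, 90)), p),
               matrix(c(-0.4454773, -0.0212132, -0.2333452, -0.2333452),
                      2, 2), tolerance = 1e-6)
  expect_equal(armJacobian(c(0, 0), p),
               matrix(c(0, p$l_sh + p$l_el, 0, p$l_el), 2, 2))

  set.seed(11)
  h <- 1e-7
  for (i in 1:20) {
    th <- deg2rad(c(runif(1, 10, 80), runif(1, 30, 150)))
    thd <- runif(2, -2, 2)
    J <- armJacobian(th, p)
    fd <- (forwardKinematics(th + h * thd, p) -
             forwardKinematics(th - h * thd, p)) / (2 * h)
    expect_lt(max(abs(J %*% thd - fd)), 1e-6)
  }
})

test_that("forward and inverse kinematics are mutually consistent", {
  p <- armParams()
  expect_equal(forwardKinematics(deg2rad(c(45, 90)), p),
               c(-0.0212132, 0.4454773), tolerance = 1e-6)
  expect_equal(forwardKinematics(c(0, 0), p), c(0.63, 0))

  # the standard 0.1-m forward reach goal
  goal <- inverseKinematics(forwardKinematics(deg2rad(c(45, 90)), p) +
                              c(0, 0.1), p)
  expect_equal(rad2deg(goal), c(60.7, 60.0), tolerance = 0.1)

  set.seed(5)
  for (i in 1:20) {
    th <- deg2rad(c(runif(1, -30, 100), runif(1, 10, 170)))
    back <- inverseKinematics(forwardKinematics(th, p), p)
    expect_lt(max(abs(back - th)), 1e-9)
  }
  expect_equal(inverseKinematics(c(p$l_sh + p$l_el, 0), p), c(0, 0),
               tolerance = 1e-6)
  expect_error(inverseKinematics(c(0, 2), p), "unreachable")
})

test_that("field matrix rotates the curl force correctly", {
  expect_equal(fieldMatrix(fieldSpec(0, 37)), matrix(0, 2, 2))
  D <- fieldMatrix(fieldSpec(2, 90))
  expect_equal(D, matrix(c(0, 0, -2, 0), 2, 2), tolerance = 1e-12)
  # along-psi velocity: force perpendicular with magnitude |phi| * speed
  for (psi in c(0, 30, 90, 135)) {
    Dp <- fieldMatrix(fieldSpec(2, psi))
    v <- 0.3 * c(cos(deg2rad(psi)), sin(deg2rad(psi)))
    f <- Dp %*% v
    expect_lt(abs(sum(f * v)), 1e-12)
    expect_equal(sqrt(sum(f^2)), 2 * 0.3, tolerance = 1e-12)
  }
  # mirror antisymmetry in the field level
  expect_equal(fieldMatrix(fieldSpec(-2, 63)),
               -fieldMatrix(fieldSpec(2, 63)), tolerance = 1e-12)
})

test_that("field torque is the Jacobian-transposed hand force", {
  p <- armParams()
  f <- fieldSpec(2, 90)
  expect_equal(fieldTorque(deg2rad(c(45, 90)), c(0, 0), f, p), c(0, 0))
  expect_equal(fieldTorque(deg2rad(c(45, 90)), c(1, 2), fieldSpec(0, 90), p),
               c(0, 0))
  th <- deg2rad(c(50, 80)); thd <- c(0.7, -0.4)
  J <- armJacobian(th, p)
  handForce <- fieldMatrix(f) %*% (J %*% thd)
  expect_equal(fieldTorque(th, thd, f, p), drop(t(J) %*% handForce),
               tolerance = 1e-12)
})

test_that("joint accelerations and the compiled integrator agree", {
  p <- armParams()
  expect_equal(armAccel(deg2rad(c(45, 90)), c(0, 0), p = p), c(0, 0))
  th <- deg2rad(c(45, 90)); thd <- c(1, -0.5)
  tau <- coriolisVector(th, thd, p)
  expect_equal(armAccel(th, thd, tau_u = tau, p = p), c(0, 0),
               tolerance = 1e-12)

  # R dynamics vs compiled dynamics at random states
  D <- fieldMatrix(fieldSpec(2, 90))
  set.seed(2)
  for (i in 1:10) {
    X <- c(deg2rad(c(runif(1, 20, 70), runif(1, 40, 140))),
           runif(2, -3, 3), runif(2, -1, 1), runif(2, -1, 1))
    u <- runif(2, -1, 1)
    dX <- reachadapt:::.armDynamicsCpp(X, u, reachadapt:::parVec(p), D)
    tau_e <- fieldTorque(X[1:2], X[3:4], fieldSpec(2, 90), p)
    acc <- armAccel(X[1:2], X[3:4],
                    tau_u = c(p$g_sh, p$g_el) * X[5:6], tau_e = tau_e, p = p)
    expect_equal(dX[1:2], X[3:4])
    expect_equal(dX[3:4], acc, tolerance = 1e-10)
    expect_equal(dX[5:6], (-X[5:6] + X[7:8]) / p$nu)
    expect_equal(dX[7:8], (-X[7:8] + u) / p$nu)
  }

  # Richardson check: halving the RK4 step changes a 0.1-s ballistic
  # segment by < 1e-6
  X0 <- c(deg2rad(c(45, 90)), 1, -0.5, rep(0, 4))
  par <- reachadapt:::parVec(p)
  coarse <- reachadapt:::.stepDynamicsCpp(X0, c(0, 0), par, D, 0.1, 10L)
  fine <- reachadapt:::.stepDynamicsCpp(X0, c(0, 0), par, D, 0.1, 20L)
  expect_lt(max(abs(coarse - fine)), 1e-6)
})
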