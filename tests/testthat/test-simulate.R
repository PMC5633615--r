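test_that("linear simulation matches closed forms and conserves the state sum", {
  # K = 0: constant trajectory
  traj0 <- simulateLinear(matrix(0, 3, 3), c(1, -2, 0.5), 2)
  expect_equal(max(abs(sweep(trajStates(traj0), 2, c(1, -2, 0.5)))), 0)

  # 2-node consensus: x(t) = (1 +- exp(-2t)) / 2
  K <- matrix(c(-1, 1, 1, -1), 2)
  traj <- simulateLinear(K, c(1, 0), 3, dtOut = 0.05)
  t <- trajTimes(traj)
  expect_equal(trajStates(traj)[, 1], (1 + exp(-2 * t)) / 2,
               tolerance = 1e-6)
  expect_equal(trajStates(traj)[, 2], (1 - exp(-2 * t)) / 2,
               tolerance = 1e-6)

  # conservation for zero-row-sum K across seeded runs
  for (seed in 1:3) {
    g <- generateClusteredNetwork(2, c(4, 4), seed = seed)
    x0 <- withr::with_seed(seed, rnorm(8))
    tr <- simulateLinear(connMatrix(g), x0, 10)
    drift <- abs(rowSums(trajStates(tr)) - sum(x0))
    expect_lt(max(drift) / max(1, abs(sum(x0))), 1e-6)
  }
})

test_that("inter-area mean difference decays at the reduced slow rate", {
  net <- example1Network()
  x0 <- withr::with_seed(1, rnorm(8))
  traj <- simulateLinear(connMatrix(net), x0, 8, dtOut = 0.02)
  sys <- singularPerturbedSystem(net)
  y <- trajStates(traj) %*% t(sys@transform@G)
  dmean <- abs(y[, 1] - y[, 2])
  # fit after the fast transient has died away
  keep <- trajTimes(traj) > 1 & dmean > 1e-12
  fit <- lm(log(dmean[keep]) ~ trajTimes(traj)[keep])
  rateSlowUnits <- -coef(fit)[[2]] / (sys@cI * sys@delta)
  expect_equal(rateSlowUnits, 1.5267, tolerance = 0.1 * 1.5267)
})

test_that("flow network reduces to the linear case and synchronizes", {
  # identity flow on one link = the 2-node linear Laplacian
  K <- matrix(c(-1, 1, 1, -1), 2)
  inc <- buildIncidence(connectivityNetwork(K, c(1, 1)))
  trajF <- simulateFlowNetwork(inc, identity, 0, c(1, 0), 3, dtOut = 0.05)
  trajL <- simulateLinear(K, c(1, 0), 3, dtOut = 0.05)
  expect_equal(trajStates(trajF), trajStates(trajL), tolerance = 1e-6)

  # constant reference velocity: the mean advances at exactly v
  incE <- buildIncidence(example1Network())
  v <- 0.3
  x0 <- withr::with_seed(2, rnorm(8))
  trajV <- simulateFlowNetwork(incE, tanh, v, x0, 5, dtOut = 0.1)
  meanTraj <- rowMeans(trajStates(trajV))
  expect_equal(meanTraj, mean(x0) + v * trajTimes(trajV),
               tolerance = 1e-6)

  # synchronization objective: pairwise spread collapses
  trajS <- simulateFlowNetwork(incE, tanh, 0, x0, 50, dtOut = 0.5)
  finalSpread <- diff(range(trajStates(trajS)[nrow(trajStates(trajS)), ]))
  expect_lt(finalSpread, 1e-4)

  # sector violation is caught before integrating
  expect_error(simulateFlowNetwork(incE, function(th) -th, 0, x0, 1),
               "sector")
})

test_that("slow/fast coordinates of a full trajectory obey the block dynamics", {
  net <- example1Network()
  sys <- singularPerturbedSystem(net)
  x0 <- withr::with_seed(3, rnorm(8))
  traj <- simulateLinear(connMatrix(net), x0, 2, dtOut = 0.001)
  yz <- transformTrajectory(traj, sys@transform)
  t <- yz$times
  mid <- 2:(length(t) - 1)
  dt <- t[2] - t[1]
  ydot <- (yz$y[mid + 1, ] - yz$y[mid - 1, ]) / (2 * dt)
  zdot <- (yz$z[mid + 1, ] - yz$z[mid - 1, ]) / (2 * dt)
  resY <- ydot - (yz$y[mid, ] %*% t(sys@A11t) + yz$z[mid, ] %*% t(sys@A12t))
  resZ <- zdot - (yz$y[mid, ] %*% t(sys@A21t) + yz$z[mid, ] %*% t(sys@A22t))
  expect_lt(max(abs(resY)), 1e-5)
  expect_lt(max(abs(resZ)), 1e-5)
})

test_that("reduced and full simulations agree as the theory predicts", {
  # decoupled areas: the slow variable is exactly constant, error at
  # integrator accuracy
  net0 <- generateClusteredNetwork(2, c(4, 4), nExternal = 0, seed = 1)
  out0 <- reducedVsFullError(net0, withr::with_seed(8, rnorm(8)), 10)
  expect_lt(out0$maxError, 1e-6)

  net <- example1Network()
  # area-constant start: the fast component starts at exactly zero (no
  # fast transient); the residual error is the O(d) reduction error fed
  # by the uneven distribution of external links within each area
  x0 <- rep(c(2, -1), each = 4)
  out <- reducedVsFullError(net, x0, 10)
  expect_true(is.na(out$fastTransient))
  expect_lt(out$maxError, 0.1 * max(abs(x0)))

  # generic start: error bounded, fast transient reported
  x1 <- withr::with_seed(4, rnorm(8))
  out1 <- reducedVsFullError(net, x1, 10)
  expect_true(is.finite(out1$maxError))
  expect_gt(out1$fastTransient, 0)

  # weakening the external coupling shrinks the reduction error
  g <- generateClusteredNetwork(2, c(5, 5), internalMinDegree = 3,
                                seed = 21)
  x2 <- withr::with_seed(4, rnorm(10))
  errs <- vapply(c(1, 1 / 2, 1 / 4, 1 / 8), function(eps)
    reducedVsFullError(scaleExternal(g, eps), x2, 10)$maxError,
    numeric(1))
  expect_true(all(diff(errs) < 0))

  # non-aggregable input is refused with the offending reasons
  K2 <- matrix(c(-1, 1, 1, -1), 2)
  Kbad <- rbind(cbind(K2, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), 0 * K2))
  Kbad[1, 3] <- Kbad[3, 1] <- Kbad[2, 4] <- Kbad[4, 2] <- 1
  diag(Kbad) <- 0; diag(Kbad) <- -rowSums(Kbad)
  expect_error(reducedVsFullError(connectivityNetwork(Kbad, c(1, 1, 2, 2)),
                                  rnorm(4), 5),
               "not aggregable")
})

test_that("pinned observer pair: identical starts stay identical, certified gains contract V", {
  net <- example3Network()
  plan <- pinningPlan(N = 3, pin = 3, gain = 1.5)

  x0 <- c(1, -1, 2)
  same <- simulatePinnedPair(net, plan, x0, x0, 5)
  expect_equal(max(abs(trajStates(same$error))), 0)
  expect_equal(max(same$V), 0)

  # global condition holds at gain 1.5, so V must be non-increasing and
  # vanish; 20 seeded initial pairs
  expect_true(globalSyncCondition(net, plan)$satisfied)
  set.seed(6)
  for (run in 1:20) {
    x0 <- rnorm(3); xt0 <- rnorm(3)
    out <- simulatePinnedPair(net, plan, x0, xt0, 40, dtOut = 0.2)
    expect_true(all(diff(out$V) <= 1e-9))
    expect_lt(out$V[length(out$V)], 1e-6 * max(out$V[1], 1e-12))
  }

  # without any gain, synchronization is not guaranteed: some runs keep a
  # macroscopic error
  set.seed(6)
  worst <- 0
  for (run in 1:20) {
    x0 <- rnorm(3); xt0 <- rnorm(3)
    out0 <- simulatePinnedPair(net, pinningPlan(N = 3), x0, xt0, 40,
                               dtOut = 0.5)
    if (out0$V[1] > 0)
      worst <- max(worst, out0$V[length(out0$V)] / out0$V[1])
  }
  expect_gt(worst, 1e-2)
})

test_that("trajectories export to TSV with labelled columns", {
  K <- matrix(c(-1, 1, 1, -1), 2)
  traj <- simulateLinear(K, c(1, 0), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTrajectoryTSV(traj, path, labels = c("a", "b"))
  df <- read.delim(path)
  expect_equal(names(df), c("time", "a", "b"))
  expect_equal(nrow(df), length(trajTimes(traj)))
})
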