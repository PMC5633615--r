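test_that("orthonormal difference matrices are orthonormal with null vector 1", {
  expect_equal(orthonormalDifferenceMatrix(2),
               matrix(c(-1, 1) / sqrt(2), 1, 2))
  for (n in 2:20) {
    Q <- orthonormalDifferenceMatrix(n)
    expect_lt(max(abs(Q %*% t(Q) - diag(n - 1))), 1e-12)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
  }
  expect_error(orthonormalDifferenceMatrix(1), ">= 2")
})

test_that("the slow/fast transform is invertible with inverse [U | Q^T]", {
  tr <- buildTransform(areaPartition(sizes = c(4, 4)))
  expect_equal(dim(tr@U), c(8L, 2L))
  expect_equal(diag(tr@Ma), c(4, 4))
  expect_equal(dim(tr@Q), c(6L, 8L))
  expect_equal(tr@R, matrix(c(-1, 1) / sqrt(2), 1, 2))
  for (sizes in list(c(4, 4), c(2, 3, 5), c(3, 3, 3, 3), c(2, 7))) {
    tr <- buildTransform(areaPartition(sizes = sizes))
    N <- sum(sizes)
    expect_lt(max(abs(tr@U %*% tr@G + t(tr@Q) %*% tr@Q - diag(N))), 1e-12)
    expect_lt(max(abs(tr@Q %*% t(tr@Q) - diag(N - length(sizes)))), 1e-12)
    expect_lt(max(abs(tr@Q %*% rep(1, N))), 1e-12)
    expect_lt(max(abs(tr@R %*% rep(1, length(sizes)))), 1e-12)
  }
})

test_that("difference-dialect transform uses the pseudoinverse consistently", {
  net <- example1Network()
  sysO <- singularPerturbedSystem(net, dialect = "orthonormal")
  sysD <- singularPerturbedSystem(net, dialect = "difference")
  # block forms differ, but both must reproduce the full spectrum:
  # eig([A11t A12t; A21t A22t]) = eig of (y,z) dynamics = eig(K) minus
  # nothing (similarity transform), for each dialect
  full <- function(s) rbind(cbind(s@A11t, s@A12t), cbind(s@A21t, s@A22t))
  eigK <- sort(Re(eigen(connMatrix(net), only.values = TRUE)$values))
  expect_equal(sort(Re(eigen(full(sysO), only.values = TRUE)$values)),
               eigK, tolerance = 1e-10)
  expect_equal(sort(Re(eigen(full(sysD), only.values = TRUE)$values)),
               eigK, tolerance = 1e-10)
})

test_that("the worked 8-node network reproduces every printed reduction quantity", {
  net <- example1Network()
  sys <- singularPerturbedSystem(net)
  expect_equal(sys@cI, 2)
  expect_equal(sys@d, 0.5)
  expect_equal(sys@delta, 0.25)
  expect_equal(sys@A11, matrix(c(-1, 1, 1, -1), 2), tolerance = 1e-12)
  expect_equal(sort(Re(eigen(sys@A11)$values)), c(-2, 0),
               tolerance = 1e-12)
  # rescaling identities
  expect_equal(sys@A11, sys@A11t / (sys@cI * sys@delta))
  expect_equal(sys@A12, sys@A12t / (sys@cI * sys@delta))
  expect_equal(sys@A21, sys@A21t / (sys@cI * sys@d))
  expect_equal(sys@A22, sys@A22t / sys@cI)

  red <- slowFastSubsystems(sys)
  expect_true(red@aggregable)
  expect_lt(max(abs(red@A0 - matrix(c(-1, 1, 1, -1) * 0.7634, 2))), 5e-5)
  expect_equal(sort(Re(red@slowEigs)), c(-1.5267, 0), tolerance = 1e-3)
  expect_equal(red@Ka, matrix(c(-2, 2, 2, -2), 2))
  expect_equal(sort(Re(red@aggregateEigs)), c(-1, 0), tolerance = 1e-12)
  # fast block strictly Hurwitz
  expect_lt(max(Re(red@fastEigs)), 0)
})

test_that("a network without external coupling has no slow dynamics", {
  K2 <- matrix(c(-1, 1, 1, -1), 2)
  K0 <- rbind(cbind(K2, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), K2))
  net0 <- connectivityNetwork(K0, c(1, 1, 2, 2))
  # d = delta = 0: the rescaling divides by them, so this is an error ...
  expect_error(singularPerturbedSystem(net0), "positive")
  # ... but with user-supplied scales the external blocks are exactly zero
  sys <- singularPerturbedSystem(net0, cI = 1, d = 0.5, delta = 0.5)
  expect_equal(sys@A11t, matrix(0, 2, 2))
  expect_equal(sys@A12t, matrix(0, 2, 2))
  expect_equal(sys@A21t, matrix(0, 2, 2))
  red <- slowFastSubsystems(sys)
  expect_equal(red@A0, matrix(0, 2, 2))
  expect_equal(red@Ka, matrix(0, 2, 2))
})

test_that("fast block matches an independently assembled dense product", {
  g <- generateClusteredNetwork(2, c(5, 4), seed = 3,
                                weightRange = c(0.5, 1.5))
  sys <- singularPerturbedSystem(g)
  sp <- splitConnectionMatrix(g)
  sizes <- areaSizes(g)
  Qblocks <- lapply(sizes, orthonormalDifferenceMatrix)
  Q <- matrix(0, sum(sizes) - 2, sum(sizes))
  Q[1:(sizes[1] - 1), 1:sizes[1]] <- Qblocks[[1]]
  Q[sizes[1]:(sum(sizes) - 2), (sizes[1] + 1):sum(sizes)] <- Qblocks[[2]]
  expect_equal(sys@A22t, Q %*% (sp$KI + sp$KE) %*% t(Q),
               tolerance = 1e-12)
})

test_that("fast initial condition applies the slow-coupling correction", {
  net <- example1Network()
  sys <- singularPerturbedSystem(net)
  x0 <- withr::with_seed(10, rnorm(8))
  ic <- fastInitialCondition(sys, x0)
  expect_equal(ic$y0, drop(sys@transform@G %*% x0))
  expect_equal(ic$zf0,
               ic$z0 + sys@d * drop(solve(sys@A22) %*% sys@A21 %*% ic$y0))
})

test_that("aggregability verdicts cover the failure taxonomy", {
  expect_true(checkAggregability(example1Network())$aggregable)

  # an area with no internal links at all
  K2 <- matrix(c(-1, 1, 1, -1), 2)
  Kbad <- rbind(cbind(K2, diag(2) * 0), cbind(diag(2) * 0, 0 * K2))
  Kbad[1, 3] <- Kbad[3, 1] <- 1
  Kbad[2, 4] <- Kbad[4, 2] <- 1
  diag(Kbad) <- 0
  diag(Kbad) <- -rowSums(Kbad)
  chk <- checkAggregability(connectivityNetwork(Kbad, c(1, 1, 2, 2)))
  expect_false(chk$aggregable)
  expect_match(paste(chk$reasons, collapse = "; "),
               "zero internal links in area 2")

  # disconnected area interior: area 2 is two separate triangles with no
  # external link touching it, so its component-difference vector lies in
  # the kernel of K and the fast block is exactly singular; areas 1 and 3
  # carry the external coupling so d and delta stay positive and below 1
  tri <- matrix(1, 3, 3) - 3 * diag(3)
  adj <- matrix(0, 12, 12)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1       # area 1; area 2 part a
  adj[7:9, 7:9] <- 1; adj[10:12, 10:12] <- 1   # area 2 part b; area 3
  diag(adj) <- 0
  adj[1, 10] <- adj[10, 1] <- 1                # external area1-area3
  adj[2, 11] <- adj[11, 2] <- 1
  K <- adj - diag(rowSums(adj))
  netDis <- connectivityNetwork(K, rep(1:3, times = c(3, 6, 3)))
  chk2 <- checkAggregability(netDis)
  expect_false(chk2$aggregable)
  expect_true("fast subsystem singular" %in% chk2$reasons)

  red2 <- slowFastSubsystems(singularPerturbedSystem(netDis))
  expect_false(red2@aggregable)
  expect_equal(red2@reasons, "fast subsystem singular")
})

test_that("slow eigenvalues of the full system converge to the reduced spectrum as coupling weakens", {
  g <- generateClusteredNetwork(2, c(5, 5), internalMinDegree = 3,
                                seed = 21)
  errsExact <- errsAggregate <- numeric(4)
  epss <- c(1, 1 / 2, 1 / 4, 1 / 8)
  for (k in seq_along(epss)) {
    gk <- scaleExternal(g, epss[k])
    sys <- singularPerturbedSystem(gk)
    red <- slowFastSubsystems(sys)
    eigFull <- eigen(connMatrix(gk), only.values = TRUE)$values
    slowFull <- sort(Re(eigFull))[c(length(eigFull) - 1, length(eigFull))]
    # A0 lives in slow time units; undo the rescaling for comparison
    slowRed <- sort(Re(red@slowEigs)) * sys@cI * sys@delta
    slowAgg <- sort(Re(red@aggregateEigs))
    errsExact[k] <- max(abs(sort(slowFull) - sort(slowRed)))
    errsAggregate[k] <- max(abs(sort(slowFull) - sort(slowAgg)))
  }
  expect_true(all(diff(errsExact) < 0))       # monotone in eps
  expect_true(all(diff(errsAggregate) < 0))
  # proportional shrinkage: halving eps at least halves the error (with slack)
  expect_lt(errsExact[4], errsExact[1] / 4)
})

test_that("zero is always an eigenvalue of A0, Ka and K for conservative networks", {
  for (seed in c(2, 13)) {
    g <- generateClusteredNetwork(3, c(4, 4, 5), seed = seed,
                                  externalPerAreaMax = 2)
    red <- slowFastSubsystems(singularPerturbedSystem(g))
    expect_lt(min(abs(Re(red@slowEigs))), 1e-9)
    expect_lt(min(abs(Re(red@aggregateEigs))), 1e-9)
    expect_lt(min(abs(eigen(connMatrix(g), only.values = TRUE)$values)),
              1e-9)
    expect_lt(max(abs(rowSums(red@A0))), 1e-9)
  }
})

test_that("aggregation report carries the documented fields", {
  rep <- aggregationReport(example1Network())
  expect_named(rep, c("d", "d_ave", "delta", "cI", "cE", "gammaE",
                      "aggregable", "reasons", "aggregate_eigs", "Ka",
                      "Ma", "slow_eigs_exact", "fast_eigs", "A0"),
               ignore.order = TRUE)
  expect_equal(rep$d, 0.5)
  slowRe <- sort(vapply(rep$slow_eigs_exact, `[[`, numeric(1), "re"))
  expect_equal(slowRe, c(-1.5267, 0), tolerance = 1e-3)
})
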