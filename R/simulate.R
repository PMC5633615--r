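# Numerical integration of the full linear, nonlinear-flow, reduced and
# pinned systems. All integrators use deSolve's adaptive lsoda with tight
# tolerances and report states on a uniform output grid.

.DIVERGENCE_LIMIT <- 1e12

.integrate <- function(deriv, x0, tEnd, dtOut, rtol, atol, meta = list()) {
  times <- seq(0, tEnd, by = dtOut)
  if (times[length(times)] < tEnd) times <- c(times, tEnd)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  if (any(!is.finite(states)) || max(abs(states)) > .DIVERGENCE_LIMIT)
    stop("trajectory diverged (|state| > 1e12 or non-finite)")
  new("Trajectory", times = sol[, 1], states = states,
      meta = c(list(method = "lsoda", rtol = rtol, atol = atol), meta))
}

#' Simulate the full linear network
#'
#' Integrates \eqn{\dot x = K x}. For a zero-row-sum (negative Laplacian)
#' \eqn{K}, the state sum \eqn{\sum_i x_i(t)} is a conserved quantity.
#'
#' @param K square numeric matrix.
#' @param x0 initial state vector.
#' @param tEnd end time.
#' @param dtOut output grid spacing (default tEnd/200).
#' @param rtol,atol integrator tolerances.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' K <- matrix(c(-1, 1, 1, -1), 2)
#' traj <- simulateLinear(K, c(1, 0), 2)
#' @export
simulateLinear <- function(K, x0, tEnd, dtOut = tEnd / 200,
                           rtol = 1e-8, atol = 1e-10) {
  K <- as.matrix(K)
  stopifnot(all(is.finite(K)), all(is.finite(x0)),
            nrow(K) == length(x0))
  .integrate(function(t, x, p) list(drop(K %*% x)),
             as.numeric(x0), tEnd, dtOut, rtol, atol,
             meta = list(system = "linear"))
}

# resolve a velocity spec (constant or function of t) to a function
.velocityFun <- function(velocity) {
  if (is.function(velocity)) velocity
  else { v <- as.numeric(velocity); function(t) v }
}

# resolve f spec: one function applied to all links, or list of M functions
.linkFlows <- function(f, M) {
  if (is.function(f)) rep(list(f), M)
  else if (is.list(f) && length(f) == M) f
  else stop("f must be a function or a list of one function per link")
}

#' Simulate the nonlinear flow network
#'
#' Integrates \eqn{\dot x = -D f(D^T x) + 1_N \upsilon(t)} where \eqn{D}
#' is the oriented incidence matrix, \eqn{f} applies a monotone sector
#' nonlinearity (\eqn{f_k(\theta) \theta > 0}) to each link difference
#' \eqn{\theta = D^T x}, and \eqn{\upsilon(t)} is a common reference
#' velocity. Each \eqn{f_k} is validated on a sample grid before
#' integration. On a connected graph with \eqn{\upsilon = 0} all pairwise
#' differences contract (synchronization).
#'
#' @param incidence an \linkS4class{IncidenceDecomposition}.
#' @param f a sector nonlinearity (function) applied to every link, or a
#'   list with one function per link.
#' @param velocity constant or function of time (default 0).
#' @param x0 initial state vector.
#' @param tEnd end time.
#' @param dtOut output grid spacing.
#' @param rtol,atol integrator tolerances.
#' @return a \linkS4class{Trajectory}.
#' @examples
#' inc <- buildIncidence(example1Network())
#' traj <- simulateFlowNetwork(inc, tanh, 0, rnorm(8), 5)
#' @export
simulateFlowNetwork <- function(incidence, f = tanh, velocity = 0, x0,
                                tEnd, dtOut = tEnd / 200,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(incidence, "IncidenceDecomposition"))
  D <- incidenceMatrix(incidence)
  M <- ncol(D)
  flows <- .linkFlows(f, M)
  grid <- c(-10^seq(1, -3, length.out = 12), 10^seq(-3, 1, length.out = 12))
  for (k in seq_len(M)) {
    vals <- vapply(grid, flows[[k]], numeric(1))
    if (any(vals * grid <= 0))
      stop("link ", k, " nonlinearity violates the sector condition ",
           "f(theta) * theta > 0")
  }
  vel <- .velocityFun(velocity)
  ones <- rep(1, nrow(D))
  deriv <- function(t, x, p) {
    theta <- drop(crossprod(D, x))
    fx <- vapply(seq_len(M), function(k) flows[[k]](theta[k]), numeric(1))
    list(drop(-D %*% fx) + ones * vel(t))
  }
  .integrate(deriv, as.numeric(x0), tEnd, dtOut, rtol, atol,
             meta = list(system = "flow"))
}

#' Compare the full network with its reduced slow model
#'
#' Simulates the full linear system \eqn{\dot x = K x} and the reduced
#' slow subsystem (in original time units,
#' \eqn{\dot y_s = c^I \delta A_0 y_s}) from matched initial conditions
#' \eqn{y_s(0) = G x_0}, and reports the largest deviation over time
#' between the full system's area means and the reduced trajectory, plus
#' the fast-transient duration (first time \eqn{|Q x(t)|} falls below 5\%
#' of its initial norm).
#'
#' @param network an aggregable \linkS4class{ConnectivityNetwork}.
#' @param x0 initial node-state vector.
#' @param tEnd end time.
#' @param dtOut output grid spacing.
#' @param rtol,atol integrator tolerances.
#' @return list: \code{maxError}, \code{fastTransient} (NA when the fast
#'   component starts at zero), \code{times}, \code{areaMeans} (full),
#'   \code{ys} (reduced).
#' @export
reducedVsFullError <- function(network, x0, tEnd, dtOut = tEnd / 400,
                               rtol = 1e-8, atol = 1e-10) {
  check <- checkAggregability(network)
  if (!check$aggregable)
    stop("network is not aggregable: ",
         paste(check$reasons, collapse = "; "))
  if (nodeParameter(network) == 0) {
    # decoupled areas: the slow variable is constant
    tr <- buildTransform(partition(network))
    full <- simulateLinear(connMatrix(network), x0, tEnd, dtOut, rtol,
                           atol)
    y0 <- drop(tr@G %*% x0)
    areaMeans <- trajStates(full) %*% t(tr@G)
    return(list(maxError = max(abs(sweep(areaMeans, 2, y0))),
                fastTransient = NA_real_, times = trajTimes(full),
                areaMeans = areaMeans,
                ys = matrix(y0, length(trajTimes(full)),
                            length(y0), byrow = TRUE)))
  }
  sys <- singularPerturbedSystem(network)
  red <- slowFastSubsystems(sys)
  tr <- sys@transform
  full <- simulateLinear(connMatrix(network), x0, tEnd, dtOut, rtol, atol)
  Aslow <- sys@cI * sys@delta * red@A0     # slow matrix in original time
  y0 <- drop(tr@G %*% x0)
  slow <- simulateLinear(Aslow, y0, tEnd, dtOut, rtol, atol)
  areaMeans <- trajStates(full) %*% t(tr@G)
  ys <- trajStates(slow)
  z <- trajStates(full) %*% t(tr@Q)
  znorm <- sqrt(rowSums(z^2))
  fastTransient <- if (znorm[1] == 0) NA_real_ else {
    below <- which(znorm < 0.05 * znorm[1])
    if (length(below)) trajTimes(full)[below[1]] else NA_real_
  }
  list(maxError = max(abs(areaMeans - ys)),
       fastTransient = fastTransient,
       times = trajTimes(full), areaMeans = areaMeans, ys = ys)
}

#' Simulate the original and pinned observer networks jointly
#'
#' Integrates the heterogeneous network
#' \eqn{\dot x_i = A_i x_i + \sum_j \tilde d_{ij} \bar f(x_j)} together
#' with its observer copy carrying the pinning feedback
#' \eqn{u_i = -d_i (\tilde x_i - x_i)}, and returns the error trajectory
#' \eqn{e = \tilde x - x} with the Lyapunov series
#' \eqn{V(t) = \frac12 \sum_i e_i^T e_i}. When the global synchronization
#' condition holds, \eqn{V} is non-increasing.
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @param plan a \linkS4class{PinningPlan}.
#' @param x0 initial state of the original network (length N*n, node-major).
#' @param xt0 initial state of the observer copy.
#' @param tEnd end time.
#' @param dtOut output grid spacing.
#' @param rtol,atol integrator tolerances.
#' @return list: \code{error} (a \linkS4class{Trajectory} of e(t)),
#'   \code{V} (numeric vector), \code{times}.
#' @examples
#' net <- example3Network()
#' plan <- pinningPlan(N = 3, pin = 3, gain = 1.5)
#' out <- simulatePinnedPair(net, plan, c(1, -1, 2), c(0, 0, 0), 10)
#' @export
simulatePinnedPair <- function(net, plan, x0, xt0, tEnd,
                               dtOut = tEnd / 200,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(net, "HeterogeneousNetwork"), is(plan, "PinningPlan"))
  N <- nNodes(net)
  n <- stateDim(net)
  stopifnot(length(x0) == N * n, length(xt0) == N * n,
            length(gains(plan)) == N)
  fbar <- outputNonlinearity(net)
  Ablk <- .blockDiag(net@AList)
  DtI <- kronecker(net@Dtilde, diag(n))
  gainVec <- rep(gains(plan), each = n)
  deriv <- function(t, s, p) {
    x <- s[seq_len(N * n)]
    xt <- s[N * n + seq_len(N * n)]
    dx <- drop(Ablk %*% x) + drop(DtI %*% fbar(x))
    dxt <- drop(Ablk %*% xt) + drop(DtI %*% fbar(xt)) -
      gainVec * (xt - x)
    list(c(dx, dxt))
  }
  traj <- .integrate(deriv, c(as.numeric(x0), as.numeric(xt0)), tEnd,
                     dtOut, rtol, atol, meta = list(system = "pinned"))
  S <- trajStates(traj)
  e <- S[, N * n + seq_len(N * n), drop = FALSE] -
    S[, seq_len(N * n), drop = FALSE]
  V <- rowSums(e^2) / 2
  list(error = new("Trajectory", times = trajTimes(traj), states = e,
                   meta = traj@meta),
       V = V, times = trajTimes(traj))
}

#' Slow/fast coordinates of a full trajectory
#'
#' Applies the slow/fast transform to a simulated node-state trajectory,
#' returning \eqn{y(t) = G x(t)} and \eqn{z(t) = Q x(t)}. Used to verify
#' that a full simulation satisfies the block dynamics of the singularly
#' perturbed form.
#'
#' @param trajectory a \linkS4class{Trajectory} of the full system.
#' @param transform a \linkS4class{SlowFastTransform}.
#' @return list with matrices \code{y} and \code{z} (rows follow the time
#'   grid) and \code{times}.
#' @export
transformTrajectory <- function(trajectory, transform) {
  X <- trajStates(trajectory)
  list(y = X %*% t(transform@G), z = X %*% t(transform@Q),
       times = trajTimes(trajectory))
}

#' Write a trajectory to TSV
#'
#' @param trajectory a \linkS4class{Trajectory}.
#' @param path output file.
#' @param labels optional state column labels.
#' @return the path, invisibly.
#' @export
writeTrajectoryTSV <- function(trajectory, path, labels = NULL) {
  df <- as.data.frame(trajectory)
  if (!is.null(labels)) names(df)[-1] <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
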