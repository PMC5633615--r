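# Central S4 containers. Nodes are always stored grouped by area (area 1
# first), which is what gives U, Q and D^I their block-diagonal structure;
# constructors reorder their inputs when needed.

#' AreaPartition: grouping of network nodes into areas
#'
#' Stores the node-to-area assignment of a clustered network with \eqn{r}
#' areas of sizes \eqn{m_\alpha}. Nodes must be grouped contiguously by area
#' (area 1 first); \code{\link{connectivityNetwork}} reorders its input to
#' satisfy this.
#'
#' @slot assignment integer vector, node index to area index (1..r),
#'   non-decreasing.
#' @slot sizes integer vector of area sizes \eqn{m_\alpha}.
#' @slot r integer, number of areas.
#' @export
setClass("AreaPartition",
  representation(assignment = "integer", sizes = "integer", r = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@r < 1L) msg <- c(msg, "r must be >= 1")
    if (length(object@sizes) != object@r)
      msg <- c(msg, "length(sizes) != r")
    if (any(object@sizes < 1L)) msg <- c(msg, "every area must be non-empty")
    if (sum(object@sizes) != length(object@assignment))
      msg <- c(msg, "sum(sizes) must equal the number of nodes")
    if (is.unsorted(object@assignment))
      msg <- c(msg, "nodes must be grouped contiguously by area")
    if (!identical(as.integer(tabulate(object@assignment, object@r)),
                   object@sizes))
      msg <- c(msg, "assignment counts disagree with sizes")
    if (length(msg)) msg else TRUE
  })

#' Construct an AreaPartition
#'
#' @param assignment integer vector mapping each node to an area in
#'   \code{1..r}; nodes must be grouped by area. Alternatively omit it and
#'   give \code{sizes} only.
#' @param sizes optional integer vector of area sizes; derived from
#'   \code{assignment} when missing.
#' @return an \linkS4class{AreaPartition}.
#' @examples
#' areaPartition(sizes = c(4, 4))
#' @export
areaPartition <- function(assignment = NULL, sizes = NULL) {
  if (is.null(assignment)) {
    if (is.null(sizes)) stop("give 'assignment' or 'sizes'")
    assignment <- rep(seq_along(sizes), times = sizes)
  }
  assignment <- as.integer(assignment)
  r <- max(assignment)
  if (is.null(sizes)) sizes <- tabulate(assignment, r)
  new("AreaPartition", assignment = assignment, sizes = as.integer(sizes),
      r = as.integer(r))
}

#' @describeIn nAreas number of areas of a partition
#' @export
setMethod("nAreas", "AreaPartition", function(x) x@r)
#' @describeIn areaSizes sizes of a partition's areas
#' @export
setMethod("areaSizes", "AreaPartition", function(x) x@sizes)
#' @describeIn areaAssignment assignment vector of a partition
#' @export
setMethod("areaAssignment", "AreaPartition", function(x) x@assignment)
#' @describeIn nNodes number of nodes covered by a partition
#' @export
setMethod("nNodes", "AreaPartition", function(x) length(x@assignment))

setMethod("show", "AreaPartition", function(object) {
  cat("AreaPartition:", length(object@assignment), "nodes in", object@r,
      "areas (sizes", paste(object@sizes, collapse = "/"), ")\n")
})

#' ConnectivityNetwork: weighted clustered network
#'
#' A symmetric \eqn{N \times N} total connection matrix \eqn{K} together
#' with an \linkS4class{AreaPartition}. \eqn{K} is expected to be a negative
#' weighted graph Laplacian (zero row sums); a violation beyond 1e-9 is
#' allowed but flagged, and aggregation then refuses to certify the
#' time-scale reduction.
#'
#' @slot K numeric matrix, the total connection matrix.
#' @slot partition an \linkS4class{AreaPartition}.
#' @slot nodeLabels character vector of node names.
#' @slot conservative logical; TRUE when all row sums of K are zero within
#'   1e-9.
#' @export
setClass("ConnectivityNetwork",
  representation(K = "matrix", partition = "AreaPartition",
                 nodeLabels = "character", conservative = "logical"),
  validity = function(object) {
    msg <- character()
    N <- nrow(object@K)
    if (ncol(object@K) != N) msg <- c(msg, "K must be square")
    if (!is.numeric(object@K) || any(!is.finite(object@K)))
      msg <- c(msg, "K must be finite numeric")
    else if (max(abs(object@K - t(object@K))) > 1e-9)
      msg <- c(msg, "K must be symmetric (directed networks unsupported)")
    if (nNodes(object@partition) != N)
      msg <- c(msg, "partition covers a different number of nodes")
    if (length(object@nodeLabels) != N)
      msg <- c(msg, "need one label per node")
    if (anyDuplicated(object@nodeLabels))
      msg <- c(msg, "node labels must be unique")
    if (length(msg)) msg else TRUE
  })

#' Construct a ConnectivityNetwork
#'
#' Nodes are reordered so that areas are contiguous (area 1 first); row and
#' column order of \code{K} and \code{nodeLabels} follow. Asymmetric input
#' is an error; nonzero row sums only warn (empirical weighted graphs may be
#' non-conservative) but block certification of aggregability downstream.
#'
#' @param K symmetric numeric matrix of connection weights (off-diagonal)
#'   and self terms (diagonal); typically a negative weighted Laplacian.
#' @param partition an \linkS4class{AreaPartition} or an assignment vector.
#' @param nodeLabels optional character labels; defaults to n1..nN.
#' @param rowSumTol absolute tolerance for the zero-row-sum check.
#' @return a \linkS4class{ConnectivityNetwork}.
#' @examples
#' net <- example1Network()
#' nNodes(net)
#' @export
connectivityNetwork <- function(K, partition, nodeLabels = NULL,
                                rowSumTol = 1e-9) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (is.null(nodeLabels)) nodeLabels <- paste0("n", seq_len(N))
  assignment <- if (is(partition, "AreaPartition"))
    areaAssignment(partition) else as.integer(partition)
  if (length(assignment) != N)
    stop("partition covers ", length(assignment), " nodes, K has ", N)
  ord <- order(assignment)
  if (is.unsorted(assignment)) {
    K <- K[ord, ord, drop = FALSE]
    nodeLabels <- nodeLabels[ord]
    assignment <- assignment[ord]
  }
  conservative <- max(abs(rowSums(K))) <= rowSumTol
  if (!conservative)
    warning("connection matrix row sums are not zero (max |rowsum| = ",
            format(max(abs(rowSums(K)))),
            "); network flagged non-conservative", call. = FALSE)
  new("ConnectivityNetwork", K = unname(K),
      partition = areaPartition(assignment),
      nodeLabels = as.character(nodeLabels), conservative = conservative)
}

#' @describeIn nNodes node count of a network
#' @export
setMethod("nNodes", "ConnectivityNetwork", function(x) nrow(x@K))
#' @describeIn nAreas area count of a network
#' @export
setMethod("nAreas", "ConnectivityNetwork", function(x) x@partition@r)
#' @describeIn areaSizes area sizes of a network
#' @export
setMethod("areaSizes", "ConnectivityNetwork", function(x) x@partition@sizes)
#' @describeIn areaAssignment assignment vector of a network
#' @export
setMethod("areaAssignment", "ConnectivityNetwork",
          function(x) x@partition@assignment)
#' @describeIn connMatrix total connection matrix of a network
#' @export
setMethod("connMatrix", "ConnectivityNetwork", function(x) x@K)
#' @describeIn nodeLabels labels of a network's nodes
#' @export
setMethod("nodeLabels", "ConnectivityNetwork", function(x) x@nodeLabels)
#' @describeIn partition partition of a network
#' @export
setMethod("partition", "ConnectivityNetwork", function(x) x@partition)

setMethod("show", "ConnectivityNetwork", function(object) {
  cat("ConnectivityNetwork:", nNodes(object), "nodes,", nAreas(object),
      "areas (sizes", paste(areaSizes(object), collapse = "/"), ")\n")
  cat("  conservative (zero row sums):", object@conservative, "\n")
})

#' IncidenceDecomposition: oriented incidence matrix, internal links first
#'
#' The oriented incidence matrix \eqn{D} of the undirected link set of a
#' clustered network, reordered as \eqn{[D^I | D^E]}: internal links (both
#' endpoints in one area) first, grouped by area so that
#' \eqn{D^I = diag(D^I_1, ..., D^I_r)}, then external links. For link
#' \eqn{\{i, j\}} with \eqn{i < j}, node \eqn{i} is the positive end.
#'
#' @slot D integer matrix with entries in \{-1, 0, +1\}, one column per link.
#' @slot MInternal integer, number of internal links.
#' @slot MExternal integer, number of external links.
#' @slot links data.frame with columns pos, neg (node indices) and area
#'   (area index for internal links, NA for external).
#' @export
setClass("IncidenceDecomposition",
  representation(D = "matrix", MInternal = "integer", MExternal = "integer",
                 links = "data.frame"),
  validity = function(object) {
    msg <- character()
    M <- ncol(object@D)
    if (M != object@MInternal + object@MExternal)
      msg <- c(msg, "column count != MInternal + MExternal")
    if (M > 0) {
      if (!all(object@D %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "entries must be in {-1, 0, +1}")
      if (!all(colSums(object@D == 1L) == 1L) ||
          !all(colSums(object@D == -1L) == 1L))
        msg <- c(msg, "each column needs exactly one +1 and one -1")
    }
    if (nrow(object@links) != M) msg <- c(msg, "link registry length != M")
    if (length(msg)) msg else TRUE
  })

#' @describeIn incidenceMatrix oriented incidence matrix
#' @export
setMethod("incidenceMatrix", "IncidenceDecomposition", function(x) x@D)
#' @describeIn nNodes node count of an incidence decomposition
#' @export
setMethod("nNodes", "IncidenceDecomposition", function(x) nrow(x@D))

setMethod("show", "IncidenceDecomposition", function(object) {
  cat("IncidenceDecomposition:", nrow(object@D), "nodes,",
      object@MInternal, "internal +", object@MExternal, "external links\n")
})

#' SlowFastTransform: aggregate/difference coordinate change
#'
#' The invertible change of coordinates from node states \eqn{x} to the
#' slow area averages \eqn{y = M_a^{-1} U^T x} and the fast within-area
#' differences \eqn{z = Q x}. With the orthonormal dialect,
#' \eqn{Q Q^T = I}, \eqn{Q 1 = 0} and \eqn{U G + Q^T Q = I}.
#'
#' @slot U \eqn{N \times r} block indicator matrix of ones-vectors.
#' @slot Ma \eqn{r \times r} diagonal matrix of area sizes.
#' @slot G \eqn{r \times N} averaging matrix \eqn{M_a^{-1} U^T}.
#' @slot Q \eqn{(N-r) \times N} block-diagonal difference matrix.
#' @slot R \eqn{(r-1) \times r} orthonormal inter-area difference matrix
#'   (zero rows when \eqn{r = 1}).
#' @slot C \eqn{(r-1) \times (r-1)} matrix \eqn{R M_a^{-1} R^T}.
#' @slot dialect "orthonormal" or "difference" (plain -1/+1 rows, for which
#'   the pseudoinverse replaces \eqn{Q^T}).
#' @export
setClass("SlowFastTransform",
  representation(U = "matrix", Ma = "matrix", G = "matrix", Q = "matrix",
                 R = "matrix", C = "matrix", dialect = "character"))

setMethod("show", "SlowFastTransform", function(object) {
  cat("SlowFastTransform (", object@dialect, "): N =", ncol(object@Q),
      ", r =", ncol(object@U), "\n")
})

#' TwoTimeScaleSystem: singularly perturbed block form
#'
#' The linear dynamics \eqn{\dot x = K x} expressed in slow/fast
#' coordinates as unscaled blocks \eqn{\tilde A_{ij}} and the rescaled
#' blocks \eqn{A_{11} = \tilde A_{11}/(c^I \delta)},
#' \eqn{A_{12} = \tilde A_{12}/(c^I \delta)},
#' \eqn{A_{21} = \tilde A_{21}/(c^I d)}, \eqn{A_{22} = \tilde A_{22}/c^I}.
#'
#' @slot A11t,A12t,A21t,A22t unscaled blocks.
#' @slot A11,A12,A21,A22 rescaled blocks.
#' @slot cI integer, minimum internal link count (fast time unit).
#' @slot d,delta the node and area sparsity parameters used.
#' @slot network the source \linkS4class{ConnectivityNetwork}.
#' @slot transform the \linkS4class{SlowFastTransform} used.
#' @export
setClass("TwoTimeScaleSystem",
  representation(A11t = "matrix", A12t = "matrix", A21t = "matrix",
                 A22t = "matrix", A11 = "matrix", A12 = "matrix",
                 A21 = "matrix", A22 = "matrix", cI = "numeric",
                 d = "numeric", delta = "numeric",
                 network = "ConnectivityNetwork",
                 transform = "SlowFastTransform"))

setMethod("show", "TwoTimeScaleSystem", function(object) {
  cat("TwoTimeScaleSystem: r =", nrow(object@A11), "slow x",
      nrow(object@A22), "fast; cI =", object@cI, ", d =", object@d,
      ", delta =", object@delta, "\n")
})

#' ReducedModels: slow, fast and rigid aggregate reductions
#'
#' Holds the exact slow subsystem \eqn{A_0 = A_{11} - d A_{12} A_{22}^{-1}
#' A_{21}}, the fast subsystem \eqn{A_{22}}, and the rigid aggregate model
#' \eqn{M_a \dot y_s = K_a y_s} with \eqn{K_a = U^T K^E U}, together with
#' their spectra (sorted by decreasing real part).
#'
#' @slot A0 \eqn{r \times r} slow matrix (slow time units).
#' @slot A22 \eqn{(N-r) \times (N-r)} fast matrix.
#' @slot Ka,Ma rigid aggregate coupling and size matrices.
#' @slot slowEigs,fastEigs,aggregateEigs complex spectra.
#' @slot aggregable logical; FALSE when the reduction is not certified.
#' @slot reasons character, failed checks when not aggregable.
#' @export
setClass("ReducedModels",
  representation(A0 = "matrix", A22 = "matrix", Ka = "matrix", Ma = "matrix",
                 slowEigs = "complex", fastEigs = "complex",
                 aggregateEigs = "complex", aggregable = "logical",
                 reasons = "character"))

setMethod("show", "ReducedModels", function(object) {
  cat("ReducedModels: r =", nrow(object@A0), "slow modes,",
      nrow(object@A22), "fast modes\n")
  cat("  slow eigenvalues:",
      paste(format(object@slowEigs, digits = 5), collapse = ", "), "\n")
  cat("  aggregable:", object@aggregable,
      if (!object@aggregable)
        paste0("(", paste(object@reasons, collapse = "; "), ")") else "",
      "\n")
})

#' HeterogeneousNetwork: per-node linear dynamics with nonlinear coupling
#'
#' Network of \eqn{N} nodes with heterogeneous state matrices \eqn{A_i}
#' (common state dimension \eqn{n}), coupling matrix
#' \eqn{\tilde D = (\tilde d_{ij})} acting through an output nonlinearity
#' \eqn{\bar f}, and a symmetric matrix \eqn{\Gamma} bounding the coupling
#' (Lipschitz-type bound used by the synchronization criteria).
#'
#' @slot AList list of \eqn{n \times n} numeric matrices \eqn{A_i}.
#' @slot Dtilde \eqn{N \times N} coupling matrix.
#' @slot Gamma symmetric \eqn{n \times n} bound matrix.
#' @slot fName output nonlinearity name ("tanh" or "identity").
#' @slot fGain slope/gain K of the nonlinearity.
#' @export
setClass("HeterogeneousNetwork",
  representation(AList = "list", Dtilde = "matrix", Gamma = "matrix",
                 fName = "character", fGain = "numeric"),
  validity = function(object) {
    msg <- character()
    N <- length(object@AList)
    dims <- vapply(object@AList, function(A) dim(as.matrix(A)), integer(2))
    if (N == 0) msg <- c(msg, "need at least one node")
    else {
      if (any(dims[1, ] != dims[2, ]) || length(unique(dims[1, ])) != 1)
        msg <- c(msg, "all A_i must be square with a common dimension")
      n <- dims[1, 1]
      if (!all(dim(object@Gamma) == n))
        msg <- c(msg, "Gamma dimension must match the node state dimension")
      else if (max(abs(object@Gamma - t(object@Gamma))) > 1e-12)
        msg <- c(msg, "Gamma must be symmetric")
    }
    if (!all(dim(object@Dtilde) == N))
      msg <- c(msg, "coupling matrix must be N x N")
    if (!object@fName %in% c("tanh", "identity"))
      msg <- c(msg, "unsupported output nonlinearity")
    if (length(msg)) msg else TRUE
  })

#' Construct a HeterogeneousNetwork
#'
#' @param AList list of per-node state matrices (scalars accepted for
#'   \eqn{n = 1}).
#' @param Dtilde \eqn{N \times N} coupling matrix.
#' @param Gamma symmetric bound matrix; a scalar K is expanded to
#'   \eqn{K I_n} (the Lipschitz bound of \code{tanh(K x)}).
#' @param fName output nonlinearity: "tanh" (default) or "identity".
#' @param fGain gain K of the nonlinearity.
#' @return a \linkS4class{HeterogeneousNetwork}.
#' @examples
#' heterogeneousNetwork(list(-2, -1.6, -0.5), diag(3) * 0.5)
#' @export
heterogeneousNetwork <- function(AList, Dtilde, Gamma = NULL,
                                 fName = "tanh", fGain = 1) {
  AList <- lapply(AList, function(A) unname(as.matrix(A)))
  n <- nrow(AList[[1]])
  if (is.null(Gamma)) Gamma <- fGain * diag(n)
  else if (length(Gamma) == 1) Gamma <- as.numeric(Gamma) * diag(n)
  new("HeterogeneousNetwork", AList = AList,
      Dtilde = unname(as.matrix(Dtilde)), Gamma = unname(as.matrix(Gamma)),
      fName = fName, fGain = as.numeric(fGain))
}

#' @describeIn nNodes node count of a heterogeneous network
#' @export
setMethod("nNodes", "HeterogeneousNetwork", function(x) length(x@AList))

#' State dimension of a heterogeneous network
#'
#' @param net a \linkS4class{HeterogeneousNetwork}.
#' @return integer, common per-node state dimension \eqn{n}.
#' @export
stateDim <- function(net) nrow(net@AList[[1]])

setMethod("show", "HeterogeneousNetwork", function(object) {
  cat("HeterogeneousNetwork:", nNodes(object), "nodes, state dim",
      stateDim(object), ", coupling", object@fName,
      "(gain", object@fGain, ")\n")
})

#' PinningPlan: per-node observer feedback gains
#'
#' Nonnegative gains \eqn{d_i} of the pinning controllers
#' \eqn{u_i = -d_i (\tilde x_i - x_i)}; nodes with zero gain are unpinned.
#' \code{c} is the positive constant of the decoupled per-node criterion.
#'
#' @slot gains numeric vector of nonnegative gains.
#' @slot c positive constant used in the decoupled condition.
#' @export
setClass("PinningPlan",
  representation(gains = "numeric", c = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@gains < 0)) msg <- c(msg, "gains must be nonnegative")
    if (length(object@c) != 1 || object@c <= 0)
      msg <- c(msg, "c must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a PinningPlan
#'
#' @param gains numeric vector of nonnegative per-node gains, or a named
#'   subset via \code{pin} + \code{gain} below.
#' @param N network size (needed when \code{gains} is not full length).
#' @param pin optional node indices to pin.
#' @param gain gain applied to each pinned node when using \code{pin}.
#' @param c positive constant for the decoupled condition.
#' @return a \linkS4class{PinningPlan}.
#' @examples
#' pinningPlan(N = 3, pin = 3, gain = 1.5)
#' @export
pinningPlan <- function(gains = NULL, N = length(gains), pin = integer(),
                        gain = 1, c = 1) {
  if (is.null(gains)) {
    gains <- numeric(N)
    gains[pin] <- gain
  }
  new("PinningPlan", gains = as.numeric(gains), c = as.numeric(c))
}

#' @describeIn pinnedSet indices with positive gain
#' @export
setMethod("pinnedSet", "PinningPlan", function(x) which(x@gains > 0))
#' @describeIn gains gain vector of a plan
#' @export
setMethod("gains", "PinningPlan", function(x) x@gains)

setMethod("show", "PinningPlan", function(object) {
  ps <- pinnedSet(object)
  cat("PinningPlan:", length(object@gains), "nodes,",
      length(ps), "pinned", if (length(ps))
        paste0("(", paste(ps, collapse = ","), ")") else "", "\n")
})

#' Trajectory: simulated time course
#'
#' Output of the numerical integrators: a strictly increasing time grid and
#' the state matrix (one row per time, one column per state component).
#'
#' @slot times numeric vector, strictly increasing.
#' @slot states numeric matrix, time by state dimension.
#' @slot meta list of integrator settings (method, rtol, atol, seed, ...).
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (nrow(object@states) != length(object@times))
      msg <- c(msg, "one state row per time point required")
    if (any(!is.finite(object@states)))
      msg <- c(msg, "non-finite states (divergence)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn trajTimes time grid of a trajectory
#' @export
setMethod("trajTimes", "Trajectory", function(x) x@times)
#' @describeIn trajStates state matrix of a trajectory
#' @export
setMethod("trajStates", "Trajectory", function(x) x@states)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points x",
      ncol(object@states), "states, t in [",
      object@times[1], ",", object@times[length(object@times)], "]\n")
})

#' Coerce a Trajectory to a data.frame
#'
#' @param x a \linkS4class{Trajectory}.
#' @param row.names,optional,... passed through for compatibility.
#' @return data.frame with a \code{time} column and one column per state.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  df <- data.frame(time = x@times, x@states)
  cn <- colnames(x@states)
  names(df) <- c("time", if (is.null(cn))
    paste0("x", seq_len(ncol(x@states))) else cn)
  df
}
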